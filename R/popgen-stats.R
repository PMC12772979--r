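# Core population-genetic statistics: allele frequencies, Weir-Cockerham
# per-locus FST, Hardy-Weinberg exact tests, and a permutation linkage screen.

#' Observed allele frequencies per collection and locus
#'
#' Frequencies are computed from observed alleles only: missing genotype
#' cells are excluded from denominators. Strata (collection x locus) with no
#' called individuals are not zero-filled; they are reported in the
#' `missing_strata` attribute.
#'
#' @param genotypes long genotype tibble (`indiv`, `collection`, `locus`,
#'   `allele_1`, `allele_2`; missing cells have both alleles `NA`).
#' @return tibble `collection`, `locus`, `allele`, `count`, `freq`,
#'   `n_called` (diploid individuals contributing); frequency vectors sum to
#'   1 per stratum. Attribute `missing_strata` lists fully missing strata.
#' @export
allele_freqs <- function(genotypes) {
  validate_genotypes(genotypes)
  called <- genotypes |> filter(!is.na(.data$allele_1))
  long <- bind_rows(
    called |> select("collection", "locus", allele = "allele_1"),
    called |> select("collection", "locus", allele = "allele_2"))
  counts <- long |>
    count(.data$collection, .data$locus, .data$allele, name = "count")
  ns <- called |>
    count(.data$collection, .data$locus, name = "n_called")
  out <- counts |>
    left_join(ns, by = c("collection", "locus")) |>
    mutate(freq = .data$count / (2 * .data$n_called)) |>
    select("collection", "locus", "allele", "count", "freq", "n_called") |>
    arrange(.data$collection, .data$locus, .data$allele)
  all_strata <- crossing(collection = unique(genotypes$collection),
                         locus = unique(genotypes$locus))
  attr(out, "missing_strata") <- anti_join(
    all_strata, ns, by = c("collection", "locus"))
  out
}

# Per-(collection, locus, allele) summaries used by the theta estimator:
# allele count, count of heterozygous carriers, and called sample size.
wc_locus_stats <- function(genotypes) {
  called <- genotypes |> filter(!is.na(.data$allele_1))
  per_allele <- bind_rows(
    called |> select("collection", "locus", allele = "allele_1"),
    called |> select("collection", "locus", allele = "allele_2")) |>
    count(.data$collection, .data$locus, .data$allele, name = "count")
  het_ind <- called |> filter(.data$allele_1 != .data$allele_2)
  hets <- bind_rows(
    het_ind |> select("collection", "locus", allele = "allele_1"),
    het_ind |> select("collection", "locus", allele = "allele_2")) |>
    count(.data$collection, .data$locus, .data$allele, name = "n_het")
  per_allele <- per_allele |>
    left_join(hets, by = c("collection", "locus", "allele")) |>
    mutate(n_het = coalesce(.data$n_het, 0L))
  list(per_allele = per_allele,
       ns = called |> count(.data$collection, .data$locus, name = "n"))
}

#' Per-locus pairwise FST (Weir & Cockerham 1984 theta)
#'
#' Computes the WC84 theta estimator per locus for every requested pair of
#' collections, extended to multi-allelic loci by summing the a, b and c
#' variance components over alleles before taking the ratio
#' \eqn{\theta = \sum_a a / \sum_a (a + b + c)}. Small negative estimates
#' are retained (not clamped); they are informative for ranking. The
#' estimate is undefined (`NA`) when either collection has fewer than two
#' called individuals at the locus or when the locus is monomorphic across
#' both collections.
#'
#' @param genotypes long genotype tibble covering at least the collections
#'   named in `pairs`.
#' @param pairs optional tibble from [collection_pairs()] (columns
#'   `collection_1`, `collection_2`, `pair_id`); defaults to all pairs.
#' @param loci_info optional tibble (`locus`, `chrom`, `pos`) merged onto
#'   the result so it can feed panel selection directly.
#' @return tibble `locus`, `pair_id`, `fst` (plus `chrom`, `pos` when
#'   `loci_info` is given), one row per locus per pair.
#' @export
pairwise_fst <- function(genotypes, pairs = NULL, loci_info = NULL) {
  validate_genotypes(genotypes)
  if (is.null(pairs)) pairs <- collection_pairs(genotypes$collection)
  stats_tbl <- wc_locus_stats(genotypes)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    merged <- pair_merged_stats(stats_tbl, pairs$collection_1[i],
                                pairs$collection_2[i])
    out[[i]] <- wc_theta(merged) |> mutate(pair_id = pairs$pair_id[i])
  }
  res <- bind_rows(out) |> select("locus", "pair_id", "fst")
  if (!is.null(loci_info)) {
    res <- res |> left_join(loci_info |> select("locus", "chrom", "pos"),
                            by = "locus")
  }
  res
}

#' Genome-wide pairwise FST (ratio of averages)
#'
#' Multi-locus Weir-Cockerham estimate: the a and (a + b + c) variance
#' components are summed over all alleles and loci before taking the ratio,
#' the standard way to combine loci (averaging per-locus ratios is biased).
#'
#' @inheritParams pairwise_fst
#' @return tibble `pair_id`, `fst`, `n_loci`.
#' @export
genomewide_fst <- function(genotypes, pairs = NULL) {
  validate_genotypes(genotypes)
  if (is.null(pairs)) pairs <- collection_pairs(genotypes$collection)
  stats_tbl <- wc_locus_stats(genotypes)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    merged <- pair_merged_stats(stats_tbl, pairs$collection_1[i],
                                pairs$collection_2[i])
    comp <- wc_components(merged)
    tibble(pair_id = pairs$pair_id[i],
           fst = sum(comp$a) / sum(comp$d),
           n_loci = length(unique(comp$locus)))
  })
  bind_rows(rows)
}

pair_merged_stats <- function(stats_tbl, c1, c2) {
  s1 <- stats_tbl$per_allele |> filter(.data$collection == c1)
  s2 <- stats_tbl$per_allele |> filter(.data$collection == c2)
  full_join(
    s1 |> select("locus", "allele", count1 = "count", het1 = "n_het"),
    s2 |> select("locus", "allele", count2 = "count", het2 = "n_het"),
    by = c("locus", "allele")) |>
    mutate(across(c("count1", "het1", "count2", "het2"),
                  ~ coalesce(.x, 0L))) |>
    inner_join(stats_tbl$ns |> filter(.data$collection == c1) |>
                 select("locus", n1 = "n"), by = "locus") |>
    inner_join(stats_tbl$ns |> filter(.data$collection == c2) |>
                 select("locus", n2 = "n"), by = "locus")
}

# WC84 theta components for r = 2 samples, vectorised over locus x allele.
wc_theta <- function(m) {
  comp <- wc_components(m)
  comp |>
    group_by(.data$locus) |>
    summarise(fst = ifelse(min(.data$n1) < 2 || min(.data$n2) < 2 ||
                             all(.data$mono) || sum(.data$d) == 0,
                           NA_real_, sum(.data$a) / sum(.data$d)),
              .groups = "drop")
}

wc_components <- function(m) {
  r <- 2
  n1 <- m$n1; n2 <- m$n2
  p1 <- m$count1 / (2 * n1); p2 <- m$count2 / (2 * n2)
  h1 <- m$het1 / n1;         h2 <- m$het2 / n2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tibble(locus = m$locus, n1 = n1, n2 = n2,
         a = a, d = a + b + cc, mono = pbar %in% c(0, 1))
}

#' Exact test of Hardy-Weinberg equilibrium at one locus
#'
#' Biallelic loci use the exact conditional test: conditional on the
#' observed allele counts, the probability of every attainable heterozygote
#' count is enumerated and the two-sided p-value sums all outcomes whose
#' probability does not exceed that of the observed configuration. As in
#' any exact conditional test the p-value is discrete and conservative.
#'
#' Loci with three or more alleles use a Monte-Carlo exact test: the
#' observed 2n alleles are randomly re-paired into diploids `n_perm` times
#' and the conditional probability of each permuted genotype configuration
#' is compared with that of the observed one, with the add-one rule
#' `p = (1 + b) / (n_perm + 1)`.
#'
#' Monomorphic loci return `p = 1` by convention.
#'
#' @param a1,a2 character (or integer) vectors: the two alleles of each
#'   individual. `NA` pairs are dropped.
#' @param n_perm Monte-Carlo permutations for multi-allelic loci.
#' @param seed optional integer seed for the Monte-Carlo path.
#' @return a single p-value.
#' @export
hwe_test <- function(a1, a2, n_perm = 10000, seed = NULL) {
  keep <- !is.na(a1) & !is.na(a2)
  a1 <- as.character(a1[keep]); a2 <- as.character(a2[keep])
  if (length(a1) < 1) abort("need at least one genotyped individual")
  alle <- sort(unique(c(a1, a2)))
  if (length(alle) < 2) return(1)
  if (length(alle) == 2) {
    nAA <- sum(a1 == alle[1] & a2 == alle[1])
    naa <- sum(a1 == alle[2] & a2 == alle[2])
    nAa <- length(a1) - nAA - naa
    return(hwe_exact_biallelic(nAA, nAa, naa))
  }
  x1 <- match(a1, alle); x2 <- match(a2, alle)
  run <- function() hwe_mc_p(x1, x2, length(alle), n_perm)
  if (is.null(seed)) run() else withr::with_seed(check_scalar_seed(seed), run())
}

# Exact conditional biallelic test (two-sided, probability ordering).
hwe_exact_biallelic <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  lp <- lfactorial(n) - lfactorial((nA - hs) / 2) - lfactorial(hs) -
    lfactorial((na - hs) / 2) + hs * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# The permutation-varying part of log P(genotype table | allele counts):
# n_het * log 2 - sum(lfactorial(genotype counts)).
hwe_table_stat <- function(u, v, K) {
  g <- pmin(u, v) * (K + 1L) + pmax(u, v)
  tab <- tabulate(match(g, unique(g)))
  sum(u != v) * log(2) - sum(lfactorial(tab))
}

hwe_mc_p <- function(x1, x2, K, n_perm) {
  n <- length(x1)
  s_obs <- hwe_table_stat(x1, x2, K)
  pool <- c(x1, x2)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    s <- sample(pool)
    if (hwe_table_stat(s[seq_len(n)], s[n + seq_len(n)], K) <= s_obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  (1 + hits) / (n_perm + 1)
}

#' Squared dosage correlation between two loci
#'
#' The association statistic of the linkage screen: each locus is reduced to
#' the per-individual dosage (0/1/2 copies) of its most frequent allele and
#' the squared Pearson correlation of the two dosage vectors is returned.
#' Undefined (`NA`) when either dosage vector is constant.
#'
#' @param d1,d2 numeric dosage vectors of equal length.
#' @return squared correlation in `[0, 1]`, or `NA`.
#' @export
dosage_r2 <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  d1 <- d1[ok]; d2 <- d2[ok]
  if (length(d1) < 3 || sd(d1) == 0 || sd(d2) == 0) return(NA_real_)
  cor(d1, d2)^2
}

# Dosage of the most frequent allele per individual for one locus.
major_dosage <- function(a1, a2) {
  tab <- sort(table(c(a1, a2)), decreasing = TRUE)
  major <- names(tab)[1]
  (a1 == major) + (a2 == major)
}

#' Permutation screen for linked locus pairs on the same chromosome
#'
#' For every same-chromosome locus pair, computes the squared dosage
#' correlation ([dosage_r2()]) and a permutation p-value obtained by
#' shuffling one locus's dosages across individuals (`n_perm` shuffles,
#' add-one rule). Pairs with `p < alpha` are flagged linked. Pairs with a
#' monomorphic member are skipped.
#'
#' @param genotypes long genotype tibble with >= 20 individuals.
#' @param loci_info tibble (`locus`, `chrom`) used to restrict testing to
#'   same-chromosome pairs; if `NULL` all pairs are tested.
#' @param n_perm permutation count (default 999).
#' @param alpha flagging level.
#' @param seed optional integer seed.
#' @return tibble `locus_1`, `locus_2`, `chrom`, `r2`, `p_value`, `linked`.
#' @export
linkage_screen <- function(genotypes, loci_info = NULL, n_perm = 999,
                           alpha = 0.05, seed = NULL) {
  validate_genotypes(genotypes)
  n_ind <- length(unique(genotypes$indiv))
  if (n_ind < 20) abort("linkage screen needs >= 20 individuals")
  run <- function() {
    wide1 <- genotypes |> select("indiv", "locus", "allele_1") |>
      pivot_wider(names_from = "locus", values_from = "allele_1")
    wide2 <- genotypes |> select("indiv", "locus", "allele_2") |>
      pivot_wider(names_from = "locus", values_from = "allele_2")
    loci <- setdiff(names(wide1), "indiv")
    dosages <- lapply(loci, function(l) {
      a1 <- wide1[[l]]; a2 <- wide2[[l]]
      ok <- !is.na(a1)
      if (!any(ok) || length(unique(c(a1[ok], a2[ok]))) < 2) return(NULL)
      d <- rep(NA_real_, length(a1))
      d[ok] <- major_dosage(a1[ok], a2[ok])
      d
    })
    names(dosages) <- loci
    poly <- names(dosages)[!vapply(dosages, is.null, TRUE)]
    empty <- tibble(locus_1 = character(), locus_2 = character(),
                    chrom = character(), r2 = double(), p_value = double(),
                    linked = logical())
    if (length(poly) < 2) return(empty)
    cand <- combn(poly, 2)
    if (!is.null(loci_info)) {
      ch <- setNames(loci_info$chrom, loci_info$locus)
      same <- ch[cand[1, ]] == ch[cand[2, ]]
      cand <- cand[, which(same), drop = FALSE]
    }
    if (ncol(cand) == 0) return(empty)
    res <- lapply(seq_len(ncol(cand)), function(j) {
      l1 <- cand[1, j]; l2 <- cand[2, j]
      d1 <- dosages[[l1]]; d2 <- dosages[[l2]]
      ok <- !is.na(d1) & !is.na(d2)
      r2 <- dosage_r2(d1[ok], d2[ok])
      if (is.na(r2)) return(NULL)
      perm <- vapply(seq_len(n_perm),
                     function(b) dosage_r2(d1[ok], sample(d2[ok])), 0)
      p <- (1 + sum(perm >= r2 - 1e-12, na.rm = TRUE)) / (n_perm + 1)
      tibble(locus_1 = l1, locus_2 = l2,
             chrom = if (is.null(loci_info)) NA_character_ else
               unname(setNames(loci_info$chrom, loci_info$locus)[l1]),
             r2 = r2, p_value = p, linked = p < alpha)
    })
    bind_rows(res)
  }
  if (is.null(seed)) run() else withr::with_seed(check_scalar_seed(seed), run())
}
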