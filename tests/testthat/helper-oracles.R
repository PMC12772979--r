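# Independent oracles used to freeze expected values. These deliberately
# re-derive each quantity by a different route than the package code.

# Exact conditional HWE p-value by direct enumeration with binomial
# coefficients: P(h het | allele counts) =
#   choose(n, nAA) choose(n - nAA, h) 2^h / choose(2n, nA).
oracle_hwe_exact <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(nA %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    aa <- (nA - h) / 2
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) - lchoose(2 * n, nA))
  }, 0)
  pr <- pr / sum(pr)
  p_obs <- pr[match(nAa, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Literal transcription of the Weir & Cockerham (1984) per-allele variance
# components for two samples, written as explicit scalar loops.
oracle_wc_theta <- function(geno1, geno2) {
  # genoX: two-column matrices of allele labels, one row per individual
  alleles <- sort(unique(c(geno1, geno2)))
  n1 <- nrow(geno1); n2 <- nrow(geno2)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  num <- 0; den <- 0
  for (al in alleles) {
    p1 <- sum(geno1 == al) / (2 * n1)
    p2 <- sum(geno2 == al) / (2 * n2)
    h1 <- sum(geno1[, 1] != geno1[, 2] &
                (geno1[, 1] == al | geno1[, 2] == al)) / n1
    h2 <- sum(geno2[, 1] != geno2[, 2] &
                (geno2[, 1] == al | geno2[, 2] == al)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Brute-force two-pass missingness filter: literal recount with loops.
oracle_missingness <- function(wide, thr_ind, thr_loc) {
  # wide: logical matrix individuals x loci, TRUE = called
  keep_i <- rownames(wide)[rowMeans(wide) > thr_ind]
  w2 <- wide[keep_i, , drop = FALSE]
  keep_l <- colnames(w2)[colMeans(w2) > thr_loc]
  list(indivs = keep_i, loci = keep_l)
}

# Exhaustive search for the best feasible window selection on a tiny
# instance: maximise total score subject to per-window quotas and the
# one-pair-per-chromosome constraint (single chromosome).
oracle_window_select <- function(cand, loci_per_window) {
  # cand: tibble locus, window, score, attributed_pair
  n <- nrow(cand)
  best <- list(score = -Inf, loci = character())
  for (k in 0:n) {
    for (sel in utils::combn(n, k, simplify = FALSE)) {
      s <- cand[sel, , drop = FALSE]
      if (any(table(s$window) > loci_per_window)) next
      if (anyDuplicated(s$attributed_pair)) next
      tot <- sum(s$score)
      if (tot > best$score) best <- list(score = tot, loci = s$locus)
    }
  }
  best
}

# Small genotype-table builder: one locus, explicit genotype strings "A/B".
geno_fixture <- function(genos, collection = "c1", locus = "L1",
                         prefix = "i") {
  parts <- strsplit(genos, "/", fixed = TRUE)
  tibble::tibble(
    indiv = sprintf("%s%03d", prefix, seq_along(genos)),
    collection = collection, repunit = collection, locus = locus,
    allele_1 = vapply(parts, `[`, "", 1),
    allele_2 = vapply(parts, `[`, "", 2))
}

# Expand biallelic genotype counts into allele vectors for hwe_test().
counts_to_alleles <- function(nAA, nAa, naa, a = "A", b = "a") {
  list(a1 = c(rep(a, nAA), rep(a, nAa), rep(b, naa)),
       a2 = c(rep(a, nAA), rep(b, nAa), rep(b, naa)))
}

# Standard small synthetic baseline shared by several GSI tests.
make_test_baseline <- function(n_loci = 60, n_pops = 4, fst = 0.05,
                               n_per_pop = 30, seed = 42) {
  model <- random_population_model(n_loci = n_loci, n_pops = n_pops,
                                   fst = fst, seed = seed)
  freqs <- draw_population_freqs(model, seed = seed + 1)
  geno <- simulate_baseline(freqs, n_per_pop, seed = seed + 2)
  list(model = model, freqs = freqs, genotypes = geno,
       baseline = gsi_baseline(geno))
}
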