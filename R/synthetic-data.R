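# Synthetic baselines, mixtures, amplicon read counts and FST landscapes.
#
# Every generator takes an explicit integer seed and is bit-reproducible:
# identical arguments + seed give identical output.

#' Describe a set of diverged populations under the Balding-Nichols model
#'
#' A population model couples a locus map (chromosome, position) with
#' ancestral allele-frequency vectors and a divergence parameter. Each
#' population's locus-wise allele frequencies are later drawn from a
#' Dirichlet distribution centred on the ancestral vector with concentration
#' \eqn{(1 - F_{ST}) / F_{ST}} — the standard Balding-Nichols
#' parameterisation, under which the expected across-population variance of
#' a biallelic frequency is \eqn{p (1 - p) F_{ST}}.
#'
#' @param loci tibble with columns `locus`, `chrom`, `pos` (base pairs,
#'   non-negative, unique within a chromosome).
#' @param ancestral_freqs tibble with columns `locus`, `allele`, `freq`;
#'   frequencies must sum to 1 per locus (tolerance 1e-9) and every locus
#'   must carry at least two alleles.
#' @param n_pops number of populations.
#' @param fst divergence parameter in `[0, 1)`; either a scalar shared by
#'   all populations or one value per population. `fst = 1` is rejected.
#' @return an object of class `population_model`.
#' @export
population_model <- function(loci, ancestral_freqs, n_pops = 4, fst = 0.05) {
  stopifnot(is.data.frame(loci), is.data.frame(ancestral_freqs))
  if (!all(c("locus", "chrom", "pos") %in% names(loci))) {
    abort("`loci` needs columns locus, chrom, pos")
  }
  if (any(loci$pos < 0)) abort("locus positions must be non-negative")
  if (anyDuplicated(loci[c("chrom", "pos")])) {
    abort("locus positions must be unique within a chromosome")
  }
  if (n_pops < 1) abort("`n_pops` must be >= 1")
  if (!length(fst) %in% c(1L, as.integer(n_pops))) {
    abort("`fst` must be a scalar or one value per population")
  }
  if (any(fst < 0) || any(fst >= 1)) {
    abort("`fst` must lie in [0, 1); fst = 1 is not a valid divergence")
  }
  by_locus <- split(ancestral_freqs$freq, ancestral_freqs$locus)
  sums <- vapply(by_locus, sum, 0)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("ancestral frequency vectors must sum to 1 within 1e-9")
  }
  if (any(lengths(by_locus) < 2)) abort("every locus needs >= 2 alleles")
  if (!setequal(names(by_locus), loci$locus)) {
    abort("`loci` and `ancestral_freqs` must cover the same loci")
  }
  structure(
    list(loci = as_tibble(loci), ancestral_freqs = as_tibble(ancestral_freqs),
         n_pops = as.integer(n_pops),
         fst = rep_len(as.numeric(fst), n_pops)),
    class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("population_model: %d populations, %d loci, fst = %s\n",
              x$n_pops, nrow(x$loci),
              paste(format(unique(x$fst)), collapse = "/")))
  invisible(x)
}

#' Generate a random multi-allelic population model
#'
#' Convenience constructor emulating a microhaplotype panel: loci are spread
#' across `n_chroms` chromosomes at unique random positions, each locus has
#' 2-8 alleles (geometric weights giving a mean of roughly 3.5 alleles per
#' locus, matching typical amplicon microhaplotype panels), and ancestral
#' frequencies are drawn from a Dirichlet with geometrically decaying
#' concentration so that most loci have one or two common and several rare
#' haplotypes.
#'
#' @param n_loci number of loci.
#' @param n_pops,fst forwarded to [population_model()].
#' @param allele_range integer range `c(min, max)` of alleles per locus.
#' @param n_chroms,chrom_length genome layout used to place loci.
#' @param seed integer seed.
#' @return a `population_model`.
#' @export
random_population_model <- function(n_loci = 178, n_pops = 4, fst = 0.05,
                                    allele_range = c(2, 8), n_chroms = 23,
                                    chrom_length = 1.2e7, seed = 1) {
  seed <- check_scalar_seed(seed)
  withr::with_seed(seed, {
    chroms <- sprintf("chr%02d", rep_len(seq_len(n_chroms), n_loci))
    pos <- integer(n_loci)
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      pos[idx] <- sort(sample.int(chrom_length, length(idx)))
    }
    loci <- tibble(locus = sprintf("mhap%04d", seq_len(n_loci)),
                   chrom = chroms, pos = pos)
    ks <- allele_range[1]:allele_range[2]
    n_alleles <- sample(ks, n_loci, replace = TRUE, prob = 0.65^(ks - min(ks)))
    anc <- lapply(seq_len(n_loci), function(i) {
      a <- n_alleles[i]
      f <- drop(rdirichlet(1, 8 * 0.5^(0:(a - 1))))
      tibble(locus = loci$locus[i], allele = sprintf("h%d", seq_len(a)), freq = f)
    })
    population_model(loci, bind_rows(anc), n_pops = n_pops, fst = fst)
  })
}

#' Draw per-population allele frequencies under Balding-Nichols divergence
#'
#' For each population and locus, frequencies are drawn from
#' `Dirichlet(ancestral * (1 - F) / F)`. With `F = 0` the ancestral vector is
#' returned verbatim (the infinite-concentration limit handled explicitly).
#'
#' @param model a [population_model()].
#' @param seed integer seed.
#' @return tibble with columns `collection`, `locus`, `allele`, `freq`;
#'   frequency vectors sum to 1 per collection and locus.
#' @export
draw_population_freqs <- function(model, seed = 1) {
  stopifnot(inherits(model, "population_model"))
  seed <- check_scalar_seed(seed)
  pops <- sprintf("pop%02d", seq_len(model$n_pops))
  anc <- split(model$ancestral_freqs, model$ancestral_freqs$locus)
  withr::with_seed(seed, {
    out <- lapply(seq_along(pops), function(k) {
      f <- model$fst[k]
      per_locus <- lapply(anc, function(tb) {
        if (f == 0) {
          fr <- tb$freq
        } else {
          conc <- (1 - f) / f
          fr <- drop(rdirichlet(1, tb$freq * conc))
        }
        tibble(collection = pops[k], locus = tb$locus[1],
               allele = tb$allele, freq = fr)
      })
      bind_rows(per_locus)
    })
    bind_rows(out)
  })
}

# Draw 2n alleles per (collection, locus) stratum under Hardy-Weinberg.
draw_genotypes_for <- function(freqs, indivs, collection_of) {
  # freqs: collection/locus/allele/freq; indivs: tibble(indiv, collection)
  strata <- split(freqs, list(freqs$collection, freqs$locus), drop = TRUE)
  rows <- lapply(strata, function(tb) {
    ids <- indivs$indiv[indivs$collection == tb$collection[1]]
    n <- length(ids)
    if (n == 0) return(NULL)
    draws <- sample(tb$allele, 2 * n, replace = TRUE, prob = tb$freq)
    tibble(indiv = ids, collection = tb$collection[1], locus = tb$locus[1],
           allele_1 = draws[seq_len(n)], allele_2 = draws[n + seq_len(n)])
  })
  bind_rows(rows)
}

#' Simulate a diploid baseline under Hardy-Weinberg equilibrium
#'
#' Each individual's two alleles at each locus are drawn independently from
#' its population's frequency vector.
#'
#' @param freqs frequency table from [draw_population_freqs()] (columns
#'   `collection`, `locus`, `allele`, `freq`).
#' @param n_per_pop diploid individuals per population (>= 1).
#' @param seed integer seed.
#' @param repunit_map optional tibble (`collection`, `repunit`) assigning
#'   collections to reporting units; defaults to one unit per collection.
#' @return long genotype tibble with columns `indiv`, `collection`,
#'   `repunit`, `locus`, `allele_1`, `allele_2`.
#' @export
simulate_baseline <- function(freqs, n_per_pop, seed = 1, repunit_map = NULL) {
  if (n_per_pop < 1) abort("`n_per_pop` must be >= 1")
  seed <- check_scalar_seed(seed)
  pops <- sort(unique(freqs$collection))
  if (is.null(repunit_map)) {
    repunit_map <- tibble(collection = pops, repunit = pops)
  }
  indivs <- tibble(
    collection = rep(pops, each = n_per_pop),
    indiv = paste(rep(pops, each = n_per_pop),
                  sprintf("%03d", sequence(rep(n_per_pop, length(pops)))),
                  sep = "_"))
  geno <- withr::with_seed(seed, draw_genotypes_for(freqs, indivs, pops))
  geno |>
    left_join(repunit_map, by = "collection") |>
    select("indiv", "collection", "repunit", "locus", "allele_1", "allele_2") |>
    arrange(.data$indiv, .data$locus)
}

#' Simulate a mixture sample with known true origins
#'
#' Each individual's reporting unit of origin is drawn from
#' `true_proportions`; a source collection is then drawn uniformly among the
#' unit's collections and the genotype is simulated from that collection's
#' frequencies. True origins are returned separately so downstream
#' assignment accuracy can be scored.
#'
#' @param freqs frequency table (`collection`, `locus`, `allele`, `freq`).
#' @param true_proportions named probability vector over reporting units
#'   (must sum to 1 within 1e-9).
#' @param n_individuals mixture sample size (>= 1).
#' @param seed integer seed.
#' @param repunit_map tibble (`collection`, `repunit`); defaults to one unit
#'   per collection.
#' @return list with `genotypes` (long genotype tibble, collection label
#'   `"mixture"`, repunit `NA`) and `truth` (tibble `indiv`,
#'   `true_collection`, `true_repunit`).
#' @export
simulate_mixture <- function(freqs, true_proportions, n_individuals, seed = 1,
                             repunit_map = NULL) {
  if (n_individuals < 1) abort("`n_individuals` must be >= 1")
  seed <- check_scalar_seed(seed)
  check_prob_vector(true_proportions, "true_proportions")
  pops <- sort(unique(freqs$collection))
  if (is.null(repunit_map)) {
    repunit_map <- tibble(collection = pops, repunit = pops)
  }
  units <- names(true_proportions)
  if (is.null(units) || !all(units %in% repunit_map$repunit)) {
    abort("`true_proportions` must be named by reporting units present in `repunit_map`")
  }
  withr::with_seed(seed, {
    origin_unit <- sample(units, n_individuals, replace = TRUE,
                          prob = true_proportions)
    origin_coll <- vapply(origin_unit, function(u) {
      cands <- repunit_map$collection[repunit_map$repunit == u]
      if (length(cands) == 1) cands else sample(cands, 1)
    }, "")
    truth <- tibble(indiv = sprintf("mix_%04d", seq_len(n_individuals)),
                    true_collection = unname(origin_coll),
                    true_repunit = origin_unit)
    indivs <- tibble(indiv = truth$indiv, collection = truth$true_collection)
    geno <- draw_genotypes_for(freqs, indivs, pops)
    geno <- geno |>
      mutate(collection = "mixture", repunit = NA_character_) |>
      select("indiv", "collection", "repunit", "locus",
             "allele_1", "allele_2") |>
      arrange(.data$indiv, .data$locus)
    list(genotypes = geno, truth = truth)
  })
}

#' Simulate amplicon haplotype read counts for genotyped individuals
#'
#' Per individual and locus, a total read depth is drawn from a negative
#' binomial with the stated mean and dispersion (`depth_dispersion = Inf`
#' gives Poisson depths). Reads are then allocated by a single multinomial
#' draw: each read comes from one of the two true haplotypes with equal
#' probability and is mis-assigned, with probability `error_rate`, to a
#' haplotype drawn uniformly from the locus's other known haplotypes.
#' Haplotype counts therefore sum exactly to the drawn total depth.
#'
#' @param genotypes long genotype tibble (missing cells are skipped).
#' @param mean_depth expected reads per locus per individual (> 0).
#' @param depth_dispersion negative-binomial size parameter; `Inf` = Poisson.
#' @param error_rate per-read probability of reporting a wrong haplotype,
#'   in `[0, 0.5)`.
#' @param seed integer seed.
#' @param locus_alleles optional tibble (`locus`, `allele`) giving the
#'   haplotype universe per locus; defaults to the alleles observed in
#'   `genotypes`.
#' @return tibble `indiv`, `locus`, `haplotype`, `depth` (zero-depth
#'   haplotypes omitted).
#' @export
simulate_reads <- function(genotypes, mean_depth = 100, depth_dispersion = 5,
                           error_rate = 0.005, seed = 1, locus_alleles = NULL) {
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) abort("`error_rate` must be in [0, 0.5)")
  seed <- check_scalar_seed(seed)
  validate_genotypes(genotypes)
  g <- genotypes |> filter(!is.na(.data$allele_1))
  if (is.null(locus_alleles)) {
    locus_alleles <- bind_rows(
      tibble(locus = g$locus, allele = g$allele_1),
      tibble(locus = g$locus, allele = g$allele_2)) |>
      distinct() |> arrange(.data$locus, .data$allele)
  }
  universe <- split(locus_alleles$allele, locus_alleles$locus)
  withr::with_seed(seed, {
    depth_tot <- if (is.infinite(depth_dispersion)) {
      rpois(nrow(g), mean_depth)
    } else {
      rnbinom(nrow(g), size = depth_dispersion, mu = mean_depth)
    }
    per_locus <- split(seq_len(nrow(g)), g$locus)
    out <- vector("list", length(per_locus))
    names(out) <- names(per_locus)
    for (loc in names(per_locus)) {
      alle <- universe[[loc]]
      A <- length(alle)
      idx <- per_locus[[loc]]
      a1 <- match(g$allele_1[idx], alle)
      a2 <- match(g$allele_2[idx], alle)
      counts <- matrix(0L, nrow = A, ncol = length(idx))
      for (j in seq_along(idx)) {
        d <- depth_tot[idx[j]]
        if (d == 0) next
        p <- numeric(A)
        # error mass spread uniformly over the locus's other haplotypes;
        # a monomorphic locus has nowhere to send errors
        err <- if (A > 1) error_rate else 0
        p[a1[j]] <- p[a1[j]] + 0.5 * (1 - err)
        p[a2[j]] <- p[a2[j]] + 0.5 * (1 - err)
        if (err > 0) {
          others1 <- setdiff(seq_len(A), a1[j])
          others2 <- setdiff(seq_len(A), a2[j])
          p[others1] <- p[others1] + 0.5 * err / length(others1)
          p[others2] <- p[others2] + 0.5 * err / length(others2)
        }
        counts[, j] <- rmultinom(1, d, p)
      }
      keep <- which(counts > 0, arr.ind = TRUE)
      out[[loc]] <- tibble(indiv = g$indiv[idx[keep[, 2]]], locus = loc,
                           haplotype = alle[keep[, 1]],
                           depth = as.integer(counts[keep]))
    }
    bind_rows(out) |> arrange(.data$indiv, .data$locus, .data$haplotype)
  })
}

#' Simulate a per-locus FST landscape over many pairwise comparisons
#'
#' Produces the input of the panel-selection stage: one FST value per locus
#' per collection pair, with loci positioned along chromosomes. Three
#' configurations support different selection scenarios:
#'
#' * `"random"` — background Beta-distributed FST with occasional values
#'   above the floor.
#' * `"saturated"` — every selection window on every chromosome contains at
#'   least two loci whose maximum pairwise FST exceeds `fst_floor`, with
#'   distinct maximising pairs within each chromosome, so windowed selection
#'   returns its maximum count.
#' * `"all_below_0.2"` — every FST is strictly below the floor, so selection
#'   returns the empty set.
#'
#' @param n_chroms,chrom_length,n_loci_per_chrom genome layout. Chromosomes
#'   with zero loci are permitted.
#' @param n_pairs number of pairwise comparisons (default 55, i.e. all pairs
#'   of 11 collections).
#' @param config one of `"random"`, `"saturated"`, `"all_below_0.2"`.
#' @param seed integer seed.
#' @param windows_per_chrom,fst_floor selection geometry the `"saturated"`
#'   configuration must satisfy.
#' @return tibble `locus`, `chrom`, `pos`, `pair_id`, `fst` (long: one row
#'   per locus per pair) with a `chrom_lengths` attribute (tibble `chrom`,
#'   `length`).
#' @export
simulate_fst_landscape <- function(n_chroms = 23, chrom_length = 1.2e7,
                                   n_loci_per_chrom = 60, n_pairs = 55,
                                   config = c("random", "saturated", "all_below_0.2"),
                                   seed = 1, windows_per_chrom = 6,
                                   fst_floor = 0.2) {
  config <- match.arg(config)
  if (n_pairs < 1) abort("`n_pairs` must be >= 1")
  seed <- check_scalar_seed(seed)
  # pair ids styled as canonical collection pairs
  m <- 2
  while (choose(m, 2) < n_pairs) m <- m + 1
  pairs <- collection_pairs(sprintf("pop%02d", seq_len(m)))$pair_id[seq_len(n_pairs)]
  chroms <- sprintf("chr%02d", seq_len(n_chroms))
  win_len <- chrom_length / windows_per_chrom
  withr::with_seed(seed, {
    loci <- lapply(seq_len(n_chroms), function(ci) {
      n <- n_loci_per_chrom
      if (n == 0) return(NULL)
      # stratify positions over windows so saturation is constructible
      win <- rep_len(seq_len(windows_per_chrom) - 1L, n)
      pos <- floor(win * win_len + runif(n) * (win_len - 1)) + 1
      while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1
      tibble(locus = sprintf("%s_L%04d", chroms[ci], seq_len(n)),
             chrom = chroms[ci], pos = as.numeric(pos), window = win)
    })
    loci <- bind_rows(loci)
    n_loci <- nrow(loci)
    fst_mat <- switch(config,
      random = matrix(rbeta(n_loci * n_pairs, 0.4, 6), nrow = n_loci),
      all_below_0.2 = matrix(runif(n_loci * n_pairs, 0, fst_floor * 0.95),
                             nrow = n_loci),
      saturated = matrix(runif(n_loci * n_pairs, 0, 0.15), nrow = n_loci))
    if (config == "saturated") {
      if (n_pairs < 2 * windows_per_chrom) {
        abort("saturated config needs n_pairs >= 2 * windows_per_chrom")
      }
      for (ch in chroms) {
        rows_ch <- which(loci$chrom == ch)
        if (length(rows_ch) == 0) next
        boost_pairs <- sample(pairs, 2 * windows_per_chrom)
        k <- 0
        for (w in seq_len(windows_per_chrom) - 1L) {
          in_win <- rows_ch[loci$window[rows_ch] == w]
          if (length(in_win) < 2) {
            abort("saturated config needs >= 2 loci per window; increase n_loci_per_chrom")
          }
          chosen <- sample(in_win, 2)
          for (r in chosen) {
            k <- k + 1
            fst_mat[r, match(boost_pairs[k], pairs)] <- runif(1, 0.3, 0.9)
          }
        }
      }
    }
    out <- tibble(
      locus = rep(loci$locus, times = n_pairs),
      chrom = rep(loci$chrom, times = n_pairs),
      pos = rep(loci$pos, times = n_pairs),
      pair_id = rep(pairs, each = n_loci),
      fst = as.vector(fst_mat))
    attr(out, "chrom_lengths") <- tibble(chrom = chroms, length = chrom_length)
    out
  })
}
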