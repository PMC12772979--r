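# Mixture side of the GSI engine: Gibbs-sampled mixing proportions,
# per-individual posteriors, confidence filtering, leave-one-out accuracy
# assessment and per-site composition reports.

#' MCMC settings for mixture inference
#'
#' @param n_sweeps total Gibbs sweeps (default 2000).
#' @param burn_in sweeps discarded before averaging (default 100; must be
#'   smaller than `n_sweeps`).
#' @param pi_prior Dirichlet parameter per collection for the mixing
#'   proportions; default `1/C` for C collections (set at run time).
#' @param seed integer seed; identical seeds reproduce chains bit-for-bit.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_sweeps = 2000, burn_in = 100, pi_prior = NULL,
                        seed = 1) {
  stopifnot(n_sweeps >= 1, burn_in >= 0, burn_in < n_sweeps)
  structure(list(n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in),
                 pi_prior = pi_prior, seed = check_scalar_seed(seed)),
            class = "mcmc_config")
}

# Gibbs sampler for the conditional mixture model. logL is the fixed
# n x C genotype log-likelihood matrix; the chain alternates
#   z_i | pi  ~ categorical( pi_c * L_ic )
#   pi | z    ~ Dirichlet( prior + counts(z) )
# and returns post-burn-in means of pi and of the Rao-Blackwellised
# per-individual membership probabilities.
gibbs_mixture <- function(logL, pi_prior, n_sweeps, burn_in, seed) {
  n <- nrow(logL); C <- ncol(logL)
  Lsc <- exp(logL - apply(logL, 1, max))       # row-scaled likelihoods
  upper <- upper.tri(matrix(0, C, C), diag = TRUE)
  storage.mode(upper) <- "double"
  withr::with_seed(seed, {
    pi <- rep(1 / C, C)
    pi_acc <- numeric(C)
    post_acc <- matrix(0, n, C)
    kept <- 0L
    for (s in seq_len(n_sweeps)) {
      P <- Lsc * rep(pi, each = n)
      P <- P / rowSums(P)
      cum <- P %*% upper                       # row-wise cumulative sums
      z <- 1L + as.integer(rowSums(cum < runif(n)))
      counts <- tabulate(z, C)
      g <- rgamma(C, shape = pi_prior + counts)
      pi <- g / sum(g)
      if (s > burn_in) {
        kept <- kept + 1L
        pi_acc <- pi_acc + pi
        post_acc <- post_acc + P
      }
    }
    list(pi = pi_acc / kept, post = post_acc / kept)
  })
}

#' Infer the stock composition of a mixture sample
#'
#' Fits the conditional Bayesian mixture model: baseline allele frequencies
#' are fixed at their Dirichlet-posterior means (prior 1/A per allele) and
#' a Gibbs sampler alternates latent origins and mixing proportions over
#' the baseline collections. Reporting-unit quantities are sums over member
#' collections. Each individual also receives a z-score diagnostic
#' ([z_scores()]) computed against its maximum-a-posteriori collection.
#'
#' @param baseline a [gsi_baseline()].
#' @param mixture long genotype tibble of unknown-origin individuals; loci
#'   are intersected with the baseline (an empty intersection is an error).
#' @param mcmc an [mcmc_config()].
#' @return object of class `gsi_mixture_result` with elements
#'   `mixing_proportions` (tibble `collection`, `repunit`, `pi`),
#'   `repunit_proportions` (tibble `repunit`, `pi`),
#'   `indiv` (tibble `indiv`, `map_collection`, `map_repunit`, `confidence`
#'   = max reporting-unit posterior, `log_likelihood`, `z_score`, `n_loci`),
#'   `indiv_posteriors` (tibble `indiv`, `repunit`, `posterior`), and
#'   `settings`.
#' @export
infer_mixture <- function(baseline, mixture, mcmc = mcmc_config()) {
  stopifnot(inherits(baseline, "gsi_baseline"))
  validate_genotypes(mixture)
  if (nrow(mixture) == 0 || length(unique(mixture$indiv)) == 0) {
    abort("mixture contains no individuals")
  }
  loci <- intersect(baseline$loci, unique(mixture$locus))
  if (length(loci) == 0) abort("no loci shared between baseline and mixture")
  sets <- merge_allele_sets(baseline$allele_sets[loci],
                            observed_allele_sets(mixture)[loci])
  bc <- baseline_allele_counts(baseline$genotypes, baseline$collections,
                               loci, sets)
  fl <- posterior_freq_list(bc$counts, bc$n_called)
  enc <- encode_genotypes(mixture, loci, sets)
  logL <- logl_matrix(enc, fl, loci)
  C <- length(baseline$collections)
  pi_prior <- mcmc$pi_prior %||% (1 / C)
  fit <- gibbs_mixture(logL, pi_prior, mcmc$n_sweeps, mcmc$burn_in, mcmc$seed)

  rm <- baseline$repunit_map
  unit_of <- rm$repunit[match(baseline$collections, rm$collection)]
  units <- sort(unique(unit_of))
  agg <- function(m) {
    um <- vapply(units, function(u) rowSums(m[, unit_of == u, drop = FALSE]),
                 numeric(nrow(m)))
    matrix(um, nrow = nrow(m), dimnames = list(rownames(m), units))
  }
  post_unit <- agg(fit$post)
  map_coll_idx <- max.col(fit$post, ties.method = "first")
  map_coll <- baseline$collections[map_coll_idx]

  mom <- hwe_logl_moments(fl, loci)
  called <- !is.na(enc$a1)
  nidx <- seq_along(enc$indivs)
  mu_sum <- (called %*% t(mom$mu))[cbind(nidx, map_coll_idx)]
  var_sum <- (called %*% t(mom$var))[cbind(nidx, map_coll_idx)]
  obs <- logL[cbind(nidx, map_coll_idx)]

  indiv <- tibble(
    indiv = enc$indivs,
    map_collection = map_coll,
    map_repunit = units[max.col(post_unit, ties.method = "first")],
    confidence = apply(post_unit, 1, max),
    log_likelihood = obs,
    z_score = ifelse(var_sum > 0, (obs - mu_sum) / sqrt(var_sum), NA_real_),
    n_loci = rowSums(called))
  structure(
    list(
      mixing_proportions = tibble(collection = baseline$collections,
                                  repunit = unit_of, pi = fit$pi),
      repunit_proportions = tibble(
        repunit = units,
        pi = unname(vapply(units, function(u) sum(fit$pi[unit_of == u]), 0))),
      indiv = indiv,
      indiv_posteriors = tibble(
        indiv = rep(enc$indivs, times = length(units)),
        repunit = rep(units, each = length(enc$indivs)),
        posterior = as.vector(post_unit)),
      settings = list(n_sweeps = mcmc$n_sweeps, burn_in = mcmc$burn_in,
                      pi_prior = pi_prior, seed = mcmc$seed,
                      n_loci = length(loci))),
    class = "gsi_mixture_result")
}

#' @export
print.gsi_mixture_result <- function(x, ...) {
  cat(sprintf("gsi_mixture_result: %d individuals, %d collections, %d loci\n",
              nrow(x$indiv), nrow(x$mixing_proportions), x$settings$n_loci))
  print(x$repunit_proportions)
  invisible(x)
}

#' Filter assignments by posterior confidence and z-score
#'
#' Retains individuals whose maximum reporting-unit posterior strictly
#' exceeds `min_posterior` and whose z-score lies strictly inside
#' `z_bounds`. Individuals with undefined z-scores are excluded and
#' reported. The conventional settings keep assignments with > 90%
#' confidence and z in (-5, 5).
#'
#' @param result a `gsi_mixture_result` (or its `indiv` tibble).
#' @param min_posterior confidence threshold (default 0.9, strict).
#' @param z_bounds length-2 numeric, exclusive bounds (default `c(-5, 5)`).
#' @return list: `retained` (tibble), `excluded` (tibble with a `reason`
#'   column).
#' @export
confidence_filter <- function(result, min_posterior = 0.9,
                              z_bounds = c(-5, 5)) {
  ind <- if (inherits(result, "gsi_mixture_result")) result$indiv else result
  stopifnot(all(c("confidence", "z_score") %in% names(ind)))
  reason <- rep(NA_character_, nrow(ind))
  reason[ind$confidence <= min_posterior] <- "low_confidence"
  reason[!is.na(ind$z_score) &
           (ind$z_score <= z_bounds[1] | ind$z_score >= z_bounds[2])] <-
    "z_out_of_range"
  reason[is.na(ind$z_score)] <- "z_undefined"
  list(retained = ind[is.na(reason), , drop = FALSE],
       excluded = bind_cols(ind[!is.na(reason), , drop = FALSE],
                            tibble(reason = reason[!is.na(reason)])))
}

#' Leave-one-out simulated-mixture accuracy assessment
#'
#' Repeatedly simulates mixtures by resampling baseline individuals:
#' reporting-unit proportions are drawn from a symmetric Dirichlet
#' (`proportion_prior` per unit, collections within a unit Dirichlet(1.5)),
#' `mixture_size` individuals are sampled with replacement accordingly, and
#' the mixture model is fitted. When a sampled individual is evaluated
#' against its own source collection, that collection's posterior-mean
#' frequencies are recomputed with the individual's two alleles removed
#' (leave-one-out), preventing self-assignment optimism. Assignment is
#' scored as maximum-a-posteriori reporting unit versus true origin, both
#' over all individuals and among those passing the `> min_posterior`
#' confidence filter.
#'
#' @param baseline a [gsi_baseline()] with at least 2 reporting units
#'   (a single-unit baseline trivially scores accuracy 1).
#' @param n_mixtures number of simulated mixtures (default 50).
#' @param mixture_size individuals per simulated mixture (default 200).
#' @param proportion_prior Dirichlet parameter per reporting unit for the
#'   simulated proportions (default 1.5).
#' @param mcmc an [mcmc_config()].
#' @param seed integer seed governing mixture simulation; mixture m uses
#'   chain seed `seed + m`.
#' @param min_posterior confidence threshold for the filtered accuracy.
#' @param leave_one_out set `FALSE` to disable the leave-one-out
#'   correction (self-assignment then scores optimistically).
#' @return list: `summary` (tibble with overall filtered/unfiltered
#'   accuracy and retention), `per_unit` (filtered accuracy by true unit),
#'   `per_mixture` (one row per simulated mixture), `settings`.
#' @export
loo_assess <- function(baseline, n_mixtures = 50, mixture_size = 200,
                       proportion_prior = 1.5, mcmc = mcmc_config(),
                       seed = 1, min_posterior = 0.9, leave_one_out = TRUE) {
  stopifnot(inherits(baseline, "gsi_baseline"))
  seed <- check_scalar_seed(seed)
  loci <- baseline$loci
  sets <- baseline$allele_sets
  colls <- baseline$collections
  C <- length(colls)
  bc <- baseline_allele_counts(baseline$genotypes, colls, loci, sets)
  fl <- posterior_freq_list(bc$counts, bc$n_called)
  enc <- encode_genotypes(baseline$genotypes, loci, sets)
  ci <- match(
    baseline$genotypes$collection[match(enc$indivs, baseline$genotypes$indiv)],
    colls)
  rm <- baseline$repunit_map
  unit_of <- rm$repunit[match(colls, rm$collection)]
  units <- sort(unique(unit_of))
  n_base_per_coll <- tabulate(ci, C)
  if (any(n_base_per_coll == 0)) {
    warn(paste0("collections with 0 baseline individuals excluded: ",
                paste(colls[n_base_per_coll == 0], collapse = ", ")))
  }
  logL <- logl_matrix(enc, fl, loci)
  own_ll <- if (leave_one_out) loo_own_loglik(enc, ci, bc, loci) else
    logL[cbind(seq_along(ci), ci)]

  pi_prior <- mcmc$pi_prior %||% (1 / C)
  per_mixture <- vector("list", n_mixtures)
  all_rows <- vector("list", n_mixtures)
  withr::with_seed(seed, {
    mix_seeds <- seed + seq_len(n_mixtures)
    for (m in seq_len(n_mixtures)) {
      rho_u <- drop(rdirichlet(1, rep(proportion_prior, length(units))))
      w_coll <- numeric(C)
      for (u in seq_along(units)) {
        memb <- which(unit_of == units[u] & n_base_per_coll > 0)
        if (length(memb) == 0) next
        w <- drop(rdirichlet(1, rep(1.5, length(memb))))
        w_coll[memb] <- rho_u[u] * w
      }
      w_coll <- w_coll / sum(w_coll)
      origin <- sample.int(C, mixture_size, replace = TRUE, prob = w_coll)
      idx <- integer(mixture_size)
      for (cc in unique(origin)) {
        pick <- which(origin == cc)
        idx[pick] <- sample(which(ci == cc), length(pick), replace = TRUE)
      }
      Lm <- logL[idx, , drop = FALSE]
      Lm[cbind(seq_len(mixture_size), origin)] <- own_ll[idx]
      fit <- gibbs_mixture(Lm, pi_prior, mcmc$n_sweeps, mcmc$burn_in,
                           seed = mix_seeds[m])
      post_unit <- matrix(
        vapply(units, function(u)
          rowSums(fit$post[, unit_of == u, drop = FALSE]),
          numeric(mixture_size)),
        nrow = mixture_size, dimnames = list(NULL, units))
      map_u <- units[max.col(post_unit, ties.method = "first")]
      conf <- apply(post_unit, 1, max)
      truth_u <- unit_of[origin]
      rows <- tibble(mixture = m, true_repunit = truth_u, map_repunit = map_u,
                     confidence = conf, correct = map_u == truth_u)
      all_rows[[m]] <- rows
      kept <- rows$confidence > min_posterior
      per_mixture[[m]] <- tibble(
        mixture = m, n = mixture_size,
        accuracy_all = mean(rows$correct),
        accuracy_filtered = mean(rows$correct[kept]),
        prop_retained = mean(kept))
    }
  })
  rows <- bind_rows(all_rows)
  kept <- rows$confidence > min_posterior
  per_unit <- rows[kept, ] |>
    group_by(repunit = .data$true_repunit) |>
    summarise(accuracy = mean(.data$correct), n = n(), .groups = "drop")
  list(
    summary = tibble(
      overall_accuracy_filtered = mean(rows$correct[kept]),
      overall_accuracy_all = mean(rows$correct),
      prop_retained = mean(kept),
      n_scored = nrow(rows)),
    per_unit = per_unit,
    per_mixture = bind_rows(per_mixture),
    settings = list(n_mixtures = n_mixtures, mixture_size = mixture_size,
                    proportion_prior = proportion_prior,
                    min_posterior = min_posterior,
                    leave_one_out = leave_one_out, seed = seed,
                    n_sweeps = mcmc$n_sweeps, burn_in = mcmc$burn_in))
}

# Leave-one-out corrected log-likelihood of each baseline individual
# against its own source collection: posterior-mean frequencies are
# recomputed with the individual's two alleles removed.
loo_own_loglik <- function(enc, ci, bc, loci) {
  n <- length(enc$indivs)
  out <- numeric(n)
  for (l in seq_along(loci)) {
    a1 <- enc$a1[, l]; a2 <- enc$a2[, l]
    called <- which(!is.na(a1))
    if (length(called) == 0) next
    cnt <- bc$counts[[loci[l]]]
    A <- ncol(cnt)
    pr <- 1 / A
    cc <- ci[called]
    n_loo <- bc$n_called[, l][cc] - 1L
    den <- 2 * n_loo + 1
    hom <- a1[called] == a2[called]
    num1 <- cnt[cbind(cc, a1[called])] - ifelse(hom, 2L, 1L) + pr
    num2 <- cnt[cbind(cc, a2[called])] - ifelse(hom, 2L, 1L) + pr
    contrib <- ifelse(hom,
                      2 * (log(num1) - log(den)),
                      log(num1) + log(num2) - 2 * log(den) + log(2))
    out[called] <- out[called] + contrib
  }
  out
}

#' Per-site mixed-stock composition report
#'
#' Summarises a set of per-site mixture fits into a stacked-proportion
#' table: reporting-unit mixing proportions, MAP assignment counts and
#' confidence-filter exclusion tallies per site. Sites with fewer
#' individuals than `min_individuals` are dropped with a warning (or raise
#' an error), mirroring the practice of binning undersized collections
#' with geographic neighbours before analysis.
#'
#' @param results named list of `gsi_mixture_result`, one per sample site.
#' @param min_individuals minimum mixture size per site (default 10).
#' @param min_posterior,z_bounds forwarded to [confidence_filter()].
#' @param undersized `"drop"` (default) or `"error"`.
#' @return tibble `site`, `repunit`, `mixing_proportion`, `n_map`,
#'   `n_retained`, `n_excluded`; proportions sum to 1 within each site.
#' @export
mixture_composition_report <- function(results, min_individuals = 10,
                                       min_posterior = 0.9,
                                       z_bounds = c(-5, 5),
                                       undersized = c("drop", "error")) {
  undersized <- match.arg(undersized)
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- vector("list", length(results))
  for (site in names(results)) {
    res <- results[[site]]
    stopifnot(inherits(res, "gsi_mixture_result"))
    n_i <- nrow(res$indiv)
    if (n_i < min_individuals) {
      msg <- sprintf("site '%s' has %d individuals (< %d)", site, n_i,
                     min_individuals)
      if (undersized == "error") abort(msg)
      warn(paste0(msg, "; dropped — bin it with a geographic neighbour"))
      next
    }
    flt <- confidence_filter(res, min_posterior, z_bounds)
    maps <- table(factor(flt$retained$map_repunit,
                         levels = res$repunit_proportions$repunit))
    rows[[site]] <- tibble(
      site = site,
      repunit = res$repunit_proportions$repunit,
      mixing_proportion = res$repunit_proportions$pi,
      n_map = as.integer(maps),
      n_retained = nrow(flt$retained),
      n_excluded = nrow(flt$excluded))
  }
  bind_rows(rows)
}
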