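# Baseline side of the genetic-stock-identification engine: reference
# object, Dirichlet-posterior allele frequencies, genotype log-likelihoods
# and the analytic moments behind the z-score diagnostic.
#
# The model is the conditional (Pella-Masuda) mixture model: baseline
# allele frequencies are fixed at their Dirichlet-posterior means given the
# reference genotypes, genotype probabilities are Hardy-Weinberg products
# across loci, and missing loci contribute factor 1.

#' Build a GSI baseline from reference genotypes
#'
#' @param genotypes long genotype tibble with `indiv`, `collection`,
#'   `repunit`, `locus`, `allele_1`, `allele_2`. Every collection must carry
#'   a reporting unit (a missing `repunit` defaults to the collection
#'   label).
#' @return object of class `gsi_baseline`: the genotype table plus the
#'   collection -> reporting-unit map and the per-locus allele universe.
#' @export
gsi_baseline <- function(genotypes) {
  validate_genotypes(genotypes)
  if (!"repunit" %in% names(genotypes)) genotypes$repunit <- genotypes$collection
  genotypes <- genotypes |>
    mutate(repunit = coalesce(.data$repunit, .data$collection))
  rm_map <- genotypes |> distinct(.data$collection, .data$repunit)
  if (anyDuplicated(rm_map$collection)) {
    abort("each collection must map to exactly one reporting unit")
  }
  structure(
    list(genotypes = genotypes,
         collections = sort(unique(genotypes$collection)),
         repunit_map = rm_map |> arrange(.data$collection),
         loci = sort(unique(genotypes$locus)),
         allele_sets = observed_allele_sets(genotypes)),
    class = "gsi_baseline")
}

#' @export
print.gsi_baseline <- function(x, ...) {
  cat(sprintf("gsi_baseline: %d individuals, %d collections, %d reporting units, %d loci\n",
              length(unique(x$genotypes$indiv)), length(x$collections),
              length(unique(x$repunit_map$repunit)), length(x$loci)))
  invisible(x)
}

observed_allele_sets <- function(genotypes) {
  g <- genotypes |> filter(!is.na(.data$allele_1))
  long <- c(split(g$allele_1, g$locus), split(g$allele_2, g$locus))
  sets <- tapply(unlist(long, use.names = FALSE),
                 rep(names(long), lengths(long)),
                 function(a) sort(unique(a)), simplify = FALSE)
  lapply(sets, as.character)
}

merge_allele_sets <- function(a, b) {
  loci <- union(names(a), names(b))
  out <- lapply(loci, function(l) sort(unique(c(a[[l]], b[[l]]))))
  names(out) <- loci
  out
}

# Integer-encode genotypes against fixed allele sets.
# Returns indiv ids plus two n x L integer matrices (NA = missing).
encode_genotypes <- function(genotypes, loci, allele_sets) {
  indivs <- sort(unique(genotypes$indiv))
  n <- length(indivs); L <- length(loci)
  a1 <- matrix(NA_integer_, n, L, dimnames = list(indivs, loci))
  a2 <- a1
  g <- genotypes |> filter(.data$locus %in% loci, !is.na(.data$allele_1))
  ri <- match(g$indiv, indivs)
  ci <- match(g$locus, loci)
  code1 <- integer(nrow(g)); code2 <- integer(nrow(g))
  for (l in seq_len(L)) {
    sel <- which(ci == l)
    if (length(sel) == 0) next
    code1[sel] <- match(g$allele_1[sel], allele_sets[[loci[l]]])
    code2[sel] <- match(g$allele_2[sel], allele_sets[[loci[l]]])
  }
  a1[cbind(ri, ci)] <- code1
  a2[cbind(ri, ci)] <- code2
  list(indivs = indivs, a1 = a1, a2 = a2)
}

# Per-locus collection x allele count matrices and called sample sizes.
baseline_allele_counts <- function(genotypes, collections, loci, allele_sets) {
  g <- genotypes |> filter(!is.na(.data$allele_1), .data$locus %in% loci)
  counts <- lapply(loci, function(l) {
    matrix(0L, length(collections), length(allele_sets[[l]]),
           dimnames = list(collections, allele_sets[[l]]))
  })
  names(counts) <- loci
  n_called <- matrix(0L, length(collections), length(loci),
                     dimnames = list(collections, loci))
  gl <- split(g, g$locus)
  for (l in names(gl)) {
    tb <- gl[[l]]
    cm <- counts[[l]]
    add <- table(factor(c(tb$collection, tb$collection),
                        levels = collections),
                 factor(c(tb$allele_1, tb$allele_2),
                        levels = allele_sets[[l]]))
    counts[[l]] <- cm + unclass(add)
    n_called[, l] <- as.integer(table(factor(tb$collection,
                                             levels = collections)))
  }
  list(counts = counts, n_called = n_called)
}

# Dirichlet-posterior mean frequencies per collection:
# (count + prior) / (2 n_called + sum of priors), prior = 1/A per allele.
posterior_freq_list <- function(counts, n_called) {
  loci <- names(counts)
  out <- lapply(loci, function(l) {
    A <- ncol(counts[[l]])
    (counts[[l]] + 1 / A) / (2 * n_called[, l] + 1)
  })
  names(out) <- loci
  out
}

#' Dirichlet-posterior mean allele frequencies of a baseline
#'
#' For locus l with A alleles the prior is 1/A per allele, so
#' `freq = (count + 1/A) / (2 n_called + 1)` per collection. A collection
#' with no called individuals at a locus gets the uniform prior-only
#' frequencies. Frequencies sum to 1 per collection per locus.
#'
#' @param baseline a [gsi_baseline()].
#' @return tibble `collection`, `locus`, `allele`, `freq`.
#' @export
baseline_posterior_freqs <- function(baseline) {
  stopifnot(inherits(baseline, "gsi_baseline"))
  bc <- baseline_allele_counts(baseline$genotypes, baseline$collections,
                               baseline$loci, baseline$allele_sets)
  fl <- posterior_freq_list(bc$counts, bc$n_called)
  rows <- lapply(names(fl), function(l) {
    f <- fl[[l]]
    tibble(collection = rep(rownames(f), times = ncol(f)),
           locus = l,
           allele = rep(colnames(f), each = nrow(f)),
           freq = as.vector(f))
  })
  bind_rows(rows) |> arrange(.data$collection, .data$locus, .data$allele)
}

# n x C log-likelihood matrix: sum over called loci of
# log P(genotype | collection frequencies) under HWE.
logl_matrix <- function(enc, freq_list, loci) {
  n <- length(enc$indivs)
  C <- nrow(freq_list[[1]])
  out <- matrix(0, n, C, dimnames = list(enc$indivs, rownames(freq_list[[1]])))
  for (l in seq_along(loci)) {
    a1 <- enc$a1[, l]; a2 <- enc$a2[, l]
    called <- which(!is.na(a1))
    if (length(called) == 0) next
    lf <- log(freq_list[[loci[l]]])        # C x A
    het <- (a1[called] != a2[called]) * log(2)
    out[called, ] <- out[called, ] +
      t(lf[, a1[called], drop = FALSE] + lf[, a2[called], drop = FALSE] +
          rep(het, each = C))
  }
  out
}

#' Genotype log-likelihood of individuals against one frequency set
#'
#' Sums, over an individual's called loci, the log Hardy-Weinberg genotype
#' probability (`p^2` for homozygotes, `2 p q` for heterozygotes) under the
#' supplied allele frequencies. Missing loci are skipped (contribute 0).
#'
#' @param genotypes long genotype tibble.
#' @param freqs tibble `locus`, `allele`, `freq` for a single collection.
#' @return named numeric vector, one log-likelihood per individual.
#' @export
genotype_log_likelihood <- function(genotypes, freqs) {
  validate_genotypes(genotypes)
  g <- genotypes |> filter(!is.na(.data$allele_1),
                           .data$locus %in% unique(freqs$locus))
  f1 <- g |> left_join(freqs, by = c("locus", "allele_1" = "allele"))
  f2 <- g |> left_join(freqs, by = c("locus", "allele_2" = "allele"))
  if (any(is.na(f1$freq)) || any(is.na(f2$freq))) {
    abort("`freqs` must cover every allele observed in `genotypes`")
  }
  ll <- log(f1$freq) + log(f2$freq) +
    ifelse(g$allele_1 != g$allele_2, log(2), 0)
  out <- tapply(ll, g$indiv, sum)
  setNames(as.numeric(out), names(out))
}

# Analytic per-(collection, locus) mean and variance of the genotype
# log-probability under HWE draws from the collection's frequencies.
# Enumerates all A(A+1)/2 genotypes per locus.
hwe_logl_moments <- function(freq_list, loci) {
  C <- nrow(freq_list[[1]])
  L <- length(loci)
  mu <- matrix(0, C, L, dimnames = list(rownames(freq_list[[1]]), loci))
  v <- mu
  for (l in seq_len(L)) {
    f <- freq_list[[loci[l]]]
    A <- ncol(f)
    for (cc in seq_len(C)) {
      p <- outer(f[cc, ], f[cc, ])
      p[lower.tri(p)] <- 0
      p[upper.tri(p)] <- 2 * p[upper.tri(p)]
      pr <- p[p > 0]
      val <- log(pr)
      mu[cc, l] <- sum(pr * val)
      v[cc, l] <- sum(pr * val^2) - mu[cc, l]^2
    }
  }
  list(mu = mu, var = v)
}

#' z-score diagnostic of genotype fit to a collection
#'
#' Standardises each individual's observed genotype log-likelihood against
#' its analytic expectation and standard deviation under Hardy-Weinberg
#' draws from the collection's posterior-mean frequencies, loci treated
#' independently: `z = (logL_obs - mu) / sigma`. Large negative values flag
#' individuals unlikely to come from any baseline collection. Individuals
#' whose called loci are all monomorphic in the collection (`sigma = 0`)
#' return `NA`.
#'
#' @param baseline a [gsi_baseline()].
#' @param genotypes genotype tibble of the individuals to score.
#' @param collection collection label to score against (a single label or
#'   one per individual).
#' @return tibble `indiv`, `collection`, `log_likelihood`, `expected`,
#'   `sd`, `z_score`.
#' @export
z_scores <- function(baseline, genotypes, collection) {
  stopifnot(inherits(baseline, "gsi_baseline"))
  validate_genotypes(genotypes)
  loci <- intersect(baseline$loci, unique(genotypes$locus))
  if (length(loci) == 0) abort("no loci shared between baseline and genotypes")
  sets <- merge_allele_sets(baseline$allele_sets[loci],
                            observed_allele_sets(genotypes)[loci])
  bc <- baseline_allele_counts(baseline$genotypes, baseline$collections,
                               loci, sets)
  fl <- posterior_freq_list(bc$counts, bc$n_called)
  enc <- encode_genotypes(genotypes, loci, sets)
  ll <- logl_matrix(enc, fl, loci)
  mom <- hwe_logl_moments(fl, loci)
  collection <- rep_len(collection, length(enc$indivs))
  ci <- match(collection, baseline$collections)
  if (any(is.na(ci))) abort("unknown collection label")
  called <- !is.na(enc$a1)                       # n x L
  mu_sum <- (called %*% t(mom$mu))[cbind(seq_along(ci), ci)]
  var_sum <- (called %*% t(mom$var))[cbind(seq_along(ci), ci)]
  obs <- ll[cbind(seq_along(ci), ci)]
  tibble(indiv = enc$indivs, collection = collection,
         log_likelihood = obs, expected = mu_sum, sd = sqrt(var_sum),
         z_score = ifelse(var_sum > 0, (obs - mu_sum) / sqrt(var_sum),
                          NA_real_))
}
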