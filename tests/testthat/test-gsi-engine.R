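# Conditional Bayesian mixture model: posterior frequencies, likelihoods,
# Gibbs inference, z-scores, confidence filtering and LOO assessment.

test_that("posterior mean allele frequencies have the closed form", {
  # 10 individuals all A/A in c1; allele 'a' observed in c2 so the locus is
  # biallelic with prior 1/2 per allele: freq(A | c1) = 20.5 / 21
  g <- bind_rows(geno_fixture(rep("A/A", 10), collection = "c1"),
                 geno_fixture(rep("A/a", 4), collection = "c2", prefix = "j"))
  fr <- baseline_posterior_freqs(gsi_baseline(g))
  expect_equal(fr$freq[fr$collection == "c1" & fr$allele == "A"], 20.5 / 21)
  # a collection with no data at a locus gets the uniform prior
  g2 <- bind_rows(
    g, geno_fixture(rep("A/a", 4), collection = "c3", prefix = "k",
                    locus = "L2"))
  fr2 <- baseline_posterior_freqs(gsi_baseline(g2))
  expect_equal(fr2$freq[fr2$collection == "c3" & fr2$locus == "L1"],
               c(0.5, 0.5))
  # frequencies sum to 1 per collection x locus
  sums <- fr2 |> group_by(collection, locus) |>
    summarise(s = sum(freq), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("genotype log-likelihood is the HWE product over called loci", {
  fr <- tibble(locus = "L1", allele = c("A", "B"), freq = c(0.5, 0.5))
  g_hom <- geno_fixture("A/A")
  expect_equal(unname(genotype_log_likelihood(g_hom, fr)), log(0.25))
  # additivity across loci and the 2pq heterozygote factor
  fr2 <- bind_rows(fr, tibble(locus = "L2", allele = c("A", "B"),
                              freq = c(0.3, 0.7)))
  g2 <- bind_rows(geno_fixture("A/A", locus = "L1"),
                  geno_fixture("A/B", locus = "L2"))
  expect_equal(unname(genotype_log_likelihood(g2, fr2)),
               log(0.25) + log(2 * 0.3 * 0.7))
  # fixture individual against a direct product-of-probabilities oracle
  fr3 <- tibble(locus = c("L1", "L1", "L1", "L2", "L2"),
                allele = c("A", "B", "C", "A", "B"),
                freq = c(0.2, 0.3, 0.5, 0.9, 0.1))
  gi <- bind_rows(geno_fixture("B/C", locus = "L1"),
                  geno_fixture("A/A", locus = "L2"))
  expect_equal(unname(genotype_log_likelihood(gi, fr3)),
               log(2 * 0.3 * 0.5 * 0.9 * 0.9))
})

test_that("mixture inference recovers known mixing proportions", {
  bl <- make_test_baseline(n_loci = 150, n_pops = 4, fst = 0.05,
                           n_per_pop = 40, seed = 201)
  truth_pi <- c(pop01 = 0.6, pop02 = 0.3, pop03 = 0.1, pop04 = 0)
  mix <- simulate_mixture(bl$freqs, truth_pi, 400, seed = 202)
  fit <- infer_mixture(bl$baseline, mix$genotypes,
                       mcmc_config(seed = 203))
  est <- fit$repunit_proportions
  expect_lt(max(abs(est$pi[match(names(truth_pi), est$repunit)] -
                      unname(truth_pi))), 0.05)
  # a pure single-unit mixture concentrates on that unit
  mix1 <- simulate_mixture(bl$freqs, c(pop01 = 0, pop02 = 1,
                                       pop03 = 0, pop04 = 0), 100,
                           seed = 204)
  fit1 <- infer_mixture(bl$baseline, mix1$genotypes, mcmc_config(seed = 205))
  expect_gte(fit1$repunit_proportions$pi[
    fit1$repunit_proportions$repunit == "pop02"], 0.95)
})

test_that("identical baseline collections give symmetric posteriors", {
  m <- random_population_model(n_loci = 50, n_pops = 1, fst = 0, seed = 31)
  fr <- draw_population_freqs(m, seed = 32)
  g1 <- simulate_baseline(fr, 40, seed = 33)
  g2 <- g1 |> mutate(collection = "pop02", repunit = "pop02",
                     indiv = sub("pop01", "pop02", indiv))
  b <- gsi_baseline(bind_rows(g1, g2))
  mix <- simulate_mixture(fr, c(pop01 = 1), 60, seed = 34)
  # equal likelihoods leave pi at its (high-variance) prior, so the chain
  # needs long averaging for a tight Monte-Carlo error on the mean
  fit <- infer_mixture(b, mix$genotypes,
                       mcmc_config(n_sweeps = 40000, burn_in = 500, seed = 35))
  post <- fit$indiv_posteriors
  expect_true(all(abs(post$posterior - 0.5) < 0.05))
  # and the mixing-proportion posterior mean stays at the prior mean
  expect_equal(fit$repunit_proportions$pi, c(0.5, 0.5), tolerance = 0.05)
})

test_that("inference is label-invariant and bit-reproducible", {
  bl <- make_test_baseline(n_loci = 60, n_pops = 3, n_per_pop = 25, seed = 41)
  mix <- simulate_mixture(bl$freqs, c(pop01 = 0.5, pop02 = 0.3, pop03 = 0.2),
                          120, seed = 42)
  fit_a <- infer_mixture(bl$baseline, mix$genotypes, mcmc_config(seed = 43))
  fit_b <- infer_mixture(bl$baseline, mix$genotypes, mcmc_config(seed = 43))
  expect_identical(fit_a$repunit_proportions, fit_b$repunit_proportions)
  expect_identical(fit_a$indiv, fit_b$indiv)

  relab <- c(pop01 = "z_unit", pop02 = "a_unit", pop03 = "m_unit")
  g_rel <- bl$genotypes |>
    mutate(collection = unname(relab[collection]),
           repunit = unname(relab[repunit]))
  fit_c <- infer_mixture(gsi_baseline(g_rel), mix$genotypes,
                         mcmc_config(seed = 43))
  est_c <- fit_c$repunit_proportions
  est_a <- fit_a$repunit_proportions
  expect_equal(est_c$pi[match(unname(relab), est_c$repunit)],
               est_a$pi[match(names(relab), est_a$repunit)],
               tolerance = 0.01)
})

test_that("degenerate inputs are rejected or fall back to the prior", {
  bl <- make_test_baseline(n_loci = 10, n_pops = 2, n_per_pop = 10, seed = 51)
  other <- bl$genotypes |> mutate(locus = paste0("other_", locus))
  expect_error(infer_mixture(bl$baseline, other), "shared")
  expect_error(infer_mixture(bl$baseline, bl$genotypes[0, ]), "individuals")
})

test_that("z-scores are standardised against the analytic HWE moments", {
  bl <- make_test_baseline(n_loci = 200, n_pops = 2, n_per_pop = 40,
                           seed = 61)
  # simulate individuals from the collection's own posterior-mean
  # frequencies: z should be ~ N(0, 1) by the CLT
  fr_post <- baseline_posterior_freqs(bl$baseline) |>
    filter(collection == "pop01") |>
    mutate(collection = "pop01")
  sim <- simulate_baseline(fr_post |> select(collection, locus, allele, freq),
                           200, seed = 62)
  zs <- z_scores(bl$baseline, sim, "pop01")
  expect_gt(mean(zs$z_score), -0.2)
  expect_lt(mean(zs$z_score), 0.2)
  expect_gt(sd(zs$z_score), 0.8)
  expect_lt(sd(zs$z_score), 1.2)
})

test_that("an individual carrying systematically rare alleles gets z < -5", {
  bl <- make_test_baseline(n_loci = 100, n_pops = 2, n_per_pop = 40,
                           seed = 71)
  fr <- baseline_posterior_freqs(bl$baseline) |> filter(collection == "pop01")
  rare <- fr |>
    group_by(locus) |>
    slice_min(freq, n = 1, with_ties = FALSE) |>
    ungroup()
  outlier <- tibble(indiv = "ghost", collection = "mixture",
                    repunit = NA_character_, locus = rare$locus,
                    allele_1 = rare$allele, allele_2 = rare$allele)
  z <- z_scores(bl$baseline, outlier, "pop01")
  expect_lt(z$z_score, -5)
})

test_that("a single monomorphic locus yields an undefined, flagged z", {
  g <- bind_rows(geno_fixture(rep("A/A", 10), collection = "c1"),
                 geno_fixture(rep("A/A", 10), collection = "c2", prefix = "j"))
  b <- gsi_baseline(g)
  probe <- geno_fixture("A/A", collection = "mixture", prefix = "m")
  z <- z_scores(b, probe, "c1")
  expect_true(is.na(z$z_score))
  fit <- infer_mixture(b, probe, mcmc_config(n_sweeps = 200, burn_in = 10,
                                             seed = 1))
  expect_true(is.na(fit$indiv$z_score))
  flt <- confidence_filter(fit)
  expect_equal(flt$excluded$reason, "z_undefined")
})

test_that("the confidence filter applies strict posterior and z bounds", {
  ind <- tibble(indiv = c("a", "b", "c", "d", "e"),
                map_repunit = "u1",
                confidence = c(0.89, 0.90, 0.99, 0.99, 0.99),
                z_score = c(0, 0, -5.2, 0, 5.0))
  flt <- confidence_filter(ind)
  expect_setequal(flt$retained$indiv, "d")
  expect_equal(flt$excluded$reason[flt$excluded$indiv == "a"],
               "low_confidence")
  expect_equal(flt$excluded$reason[flt$excluded$indiv == "b"],
               "low_confidence")          # 0.90 is not > 0.90
  expect_equal(flt$excluded$reason[flt$excluded$indiv == "c"],
               "z_out_of_range")          # -5.2 outside (-5, 5)
  expect_equal(flt$excluded$reason[flt$excluded$indiv == "e"],
               "z_out_of_range")          # bounds are exclusive
})

test_that("LOO assessment scores accuracy and the LOO correction bites", {
  bl <- make_test_baseline(n_loci = 25, n_pops = 3, fst = 0.02,
                           n_per_pop = 12, seed = 81)
  mc <- mcmc_config(n_sweeps = 400, burn_in = 50)
  with_loo <- loo_assess(bl$baseline, n_mixtures = 6, mixture_size = 60,
                         mcmc = mc, seed = 82)
  no_loo <- loo_assess(bl$baseline, n_mixtures = 6, mixture_size = 60,
                       mcmc = mc, seed = 82, leave_one_out = FALSE)
  # same seeds: disabling leave-one-out can only look better
  expect_gte(no_loo$summary$overall_accuracy_all,
             with_loo$summary$overall_accuracy_all)
  expect_equal(with_loo$summary$n_scored, 360)
  expect_identical(
    loo_assess(bl$baseline, n_mixtures = 2, mixture_size = 30, mcmc = mc,
               seed = 83)$summary,
    loo_assess(bl$baseline, n_mixtures = 2, mixture_size = 30, mcmc = mc,
               seed = 83)$summary)
})

test_that("a single-unit baseline scores perfect accuracy trivially", {
  m <- random_population_model(n_loci = 15, n_pops = 2, fst = 0.01, seed = 91)
  fr <- draw_population_freqs(m, seed = 92)
  g <- simulate_baseline(fr, 10, seed = 93,
                         repunit_map = tibble(collection = c("pop01", "pop02"),
                                              repunit = "only_unit"))
  res <- loo_assess(gsi_baseline(g), n_mixtures = 2, mixture_size = 20,
                    mcmc = mcmc_config(n_sweeps = 200, burn_in = 20),
                    seed = 94)
  expect_equal(res$summary$overall_accuracy_all, 1)
})

test_that("composition reports tally MAP assignments per site", {
  bl <- make_test_baseline(n_loci = 80, n_pops = 3, n_per_pop = 30, seed = 301)
  mix <- simulate_mixture(bl$freqs, c(pop01 = 1, pop02 = 0, pop03 = 0),
                          25, seed = 302)
  fit <- infer_mixture(bl$baseline, mix$genotypes, mcmc_config(seed = 303))
  rep <- mixture_composition_report(list(siteA = fit))
  expect_equal(sum(rep$mixing_proportion), 1, tolerance = 1e-6)
  # all individuals from one unit: MAP counts are a basis vector
  expect_equal(rep$n_map[rep$repunit == "pop01"], rep$n_retained[1])
  expect_true(all(rep$n_map[rep$repunit != "pop01"] == 0))
  # MAP counts match a hand tally of the per-individual table
  flt <- confidence_filter(fit)
  expect_equal(sum(rep$n_map), nrow(flt$retained))
  # undersized sites are dropped with a warning, or error on request
  small <- simulate_mixture(bl$freqs, c(pop01 = 1, pop02 = 0, pop03 = 0),
                            5, seed = 304)
  fit_small <- infer_mixture(bl$baseline, small$genotypes,
                             mcmc_config(seed = 305))
  expect_warning(rep2 <- mixture_composition_report(
    list(siteA = fit, tiny = fit_small)), "tiny")
  expect_false("tiny" %in% rep2$site)
  expect_error(mixture_composition_report(list(tiny = fit_small),
                                          undersized = "error"), "tiny")
})
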