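# Allele frequencies, Weir-Cockerham theta, HWE exact tests and the
# linkage screen.

test_that("allele frequencies come from observed alleles only", {
  g <- geno_fixture(c("A/A", "A/A", "A/A"))
  af <- allele_freqs(g)
  expect_equal(af$freq, 1)

  g2 <- geno_fixture(c("A/A", "A/T", "T/T"))
  af2 <- allele_freqs(g2)
  expect_equal(af2$freq[af2$allele == "A"], 0.5)

  # 3 alleles, hand-tallied on six individuals:
  # A appears 5x, B 4x, C 3x over 12 allele copies
  g3 <- geno_fixture(c("A/A", "A/A", "A/B", "B/B", "B/C", "C/C"))
  af3 <- allele_freqs(g3)
  expect_equal(af3$count[match(c("A", "B", "C"), af3$allele)], c(5L, 4L, 3L))
  expect_equal(af3$freq[match(c("A", "B", "C"), af3$allele)], c(5, 4, 3) / 12)

  # missing cells excluded from the denominator, empty strata flagged
  g4 <- g2
  g4$allele_1[1] <- NA; g4$allele_2[1] <- NA
  af4 <- allele_freqs(g4)
  expect_equal(unique(af4$n_called), 2L)
  g5 <- g2 |> mutate(locus = "L1") |>
    bind_rows(geno_fixture(c("A/A"), collection = "c2", locus = "L2",
                           prefix = "j"))
  miss <- attr(allele_freqs(g5), "missing_strata")
  expect_true(nrow(miss) == 2)   # c1 lacks L2, c2 lacks L1
})

test_that("pairwise theta matches fixed-difference and exchangeable limits", {
  fix <- bind_rows(geno_fixture(rep("A/A", 10), collection = "c1"),
                   geno_fixture(rep("T/T", 10), collection = "c2", prefix = "j"))
  expect_equal(pairwise_fst(fix)$fst, 1)

  # byte-identical samples: theta ~ 0
  m <- random_population_model(n_loci = 40, n_pops = 1, fst = 0, seed = 3)
  fr <- draw_population_freqs(m, seed = 4)
  g1 <- simulate_baseline(fr, 50, seed = 5)
  g2 <- g1 |> mutate(collection = "pop02", repunit = "pop02",
                     indiv = sub("pop01", "pop02", indiv))
  both <- bind_rows(g1, g2)
  th <- pairwise_fst(both)$fst
  expect_true(all(abs(th) < 0.05, na.rm = TRUE))

  # symmetry: swapping collection labels leaves theta unchanged
  swapped <- both |>
    mutate(collection = ifelse(collection == "pop01", "pop02", "pop01"))
  expect_equal(pairwise_fst(both)$fst, pairwise_fst(swapped)$fst)
})

test_that("theta equals an independent transcription of the WC84 components", {
  # two pops, n = 4 each, multi-allelic genotype counts fixed by hand
  g1m <- rbind(c("A", "A"), c("A", "B"), c("B", "C"), c("C", "C"))
  g2m <- rbind(c("A", "B"), c("B", "B"), c("B", "B"), c("A", "C"))
  g <- bind_rows(
    tibble(indiv = sprintf("a%d", 1:4), collection = "c1", repunit = "c1",
           locus = "L1", allele_1 = g1m[, 1], allele_2 = g1m[, 2]),
    tibble(indiv = sprintf("b%d", 1:4), collection = "c2", repunit = "c2",
           locus = "L1", allele_1 = g2m[, 1], allele_2 = g2m[, 2]))
  expect_equal(pairwise_fst(g)$fst, oracle_wc_theta(g1m, g2m))

  # and on a random biallelic fixture
  set.seed(7)
  r1 <- matrix(sample(c("A", "G"), 24, TRUE), ncol = 2)
  r2 <- matrix(sample(c("A", "G"), 24, TRUE, prob = c(0.8, 0.2)), ncol = 2)
  gr <- bind_rows(
    tibble(indiv = sprintf("a%d", 1:12), collection = "c1", repunit = "c1",
           locus = "L1", allele_1 = r1[, 1], allele_2 = r1[, 2]),
    tibble(indiv = sprintf("b%d", 1:12), collection = "c2", repunit = "c2",
           locus = "L1", allele_1 = r2[, 1], allele_2 = r2[, 2]))
  expect_equal(pairwise_fst(gr)$fst, oracle_wc_theta(r1, r2))
})

test_that("theta is undefined for monomorphic or undersized strata", {
  mono <- bind_rows(geno_fixture(rep("A/A", 5)),
                    geno_fixture(rep("A/A", 5), collection = "c2", prefix = "j"))
  expect_true(is.na(pairwise_fst(mono)$fst))
  tiny <- bind_rows(geno_fixture(c("A/T")),
                    geno_fixture(c("A/A", "A/T", "T/T"), collection = "c2",
                                 prefix = "j"))
  expect_true(is.na(pairwise_fst(tiny)$fst))
})

test_that("biallelic HWE p-values match full enumeration", {
  ca <- counts_to_alleles(25, 50, 25)
  expect_equal(hwe_test(ca$a1, ca$a2), 1)          # modal configuration
  expect_equal(hwe_test(ca$a1, ca$a2), oracle_hwe_exact(25, 50, 25))

  cb <- counts_to_alleles(0, 50, 0)
  expect_lt(hwe_test(cb$a1, cb$a2), 0.001)
  expect_equal(hwe_test(cb$a1, cb$a2), oracle_hwe_exact(0, 50, 0))

  expect_equal(hwe_test(rep("A", 10), rep("A", 10)), 1)  # monomorphic

  # parameterised sweep against the oracle
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    g <- sample(0:2, n, TRUE, prob = c(0.3, 0.4, 0.3))
    cnt <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    cc <- counts_to_alleles(cnt[1], cnt[2], cnt[3])
    expect_equal(hwe_test(cc$a1, cc$a2),
                 oracle_hwe_exact(cnt[1], cnt[2], cnt[3]))
  }
})

test_that("multi-allelic Monte-Carlo HWE test detects disequilibrium and is valid", {
  # gross heterozygote excess across three alleles
  a1 <- rep(c("A", "B", "C"), each = 20)
  a2 <- rep(c("B", "C", "A"), each = 20)
  expect_lt(hwe_test(a1, a2, n_perm = 2000, seed = 1), 0.01)
  # p has the add-one floor
  expect_gte(hwe_test(a1, a2, n_perm = 2000, seed = 1), 1 / 2001)
  # determinism under a fixed seed
  expect_identical(hwe_test(a1, a2, n_perm = 500, seed = 9),
                   hwe_test(a1, a2, n_perm = 500, seed = 9))
})

test_that("biallelic exact HWE p-values are valid (sub-uniform) under the null", {
  set.seed(17)
  ps <- replicate(400, {
    f <- runif(1, 0.2, 0.8)
    g <- sample(0:2, 80, TRUE, prob = c((1 - f)^2, 2 * f * (1 - f), f^2))
    cc <- counts_to_alleles(sum(g == 0), sum(g == 1), sum(g == 2))
    hwe_test(cc$a1, cc$a2)
  })
  # exact conditional tests are conservative: P(p <= a) <= a (+ MC slack)
  for (a in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(ps <= a), a + 2.5 * sqrt(a * (1 - a) / 400))
  }
})

test_that("dosage r-squared flags perfectly associated loci", {
  expect_equal(dosage_r2(c(0, 1, 2, 2, 1, 0), c(2, 1, 0, 0, 1, 2)), 1)
  expect_true(is.na(dosage_r2(c(1, 1, 1, 1), c(0, 1, 2, 0))))

  # a duplicated genotype column reaches the minimum attainable p
  set.seed(5)
  m <- random_population_model(n_loci = 4, n_pops = 1, fst = 0, seed = 6)
  fr <- draw_population_freqs(m, seed = 7)
  g <- simulate_baseline(fr, 30, seed = 8)
  dup <- g |> filter(locus == "mhap0001") |> mutate(locus = "mhap_dup")
  gd <- bind_rows(g, dup)
  li <- bind_rows(m$loci, tibble(locus = "mhap_dup",
                                 chrom = m$loci$chrom[1],
                                 pos = m$loci$pos[1] + 1))
  scr <- linkage_screen(gd, li, n_perm = 199, seed = 9)
  hit <- scr |> filter(locus_1 == "mhap0001", locus_2 == "mhap_dup")
  expect_equal(hit$r2, 1)
  expect_equal(hit$p_value, 1 / 200)
  expect_true(hit$linked)
})

test_that("linkage screen has the nominal type-I rate on independent loci", {
  m <- random_population_model(n_loci = 46, n_pops = 1, fst = 0,
                               n_chroms = 1, seed = 11)
  fr <- draw_population_freqs(m, seed = 12)
  g <- simulate_baseline(fr, 40, seed = 13)
  scr <- linkage_screen(g, m$loci, n_perm = 499, alpha = 0.05, seed = 14)
  expect_gte(nrow(scr), 900)     # ~ C(46,2) = 1035 pairs, minus monomorphic
  expect_lt(abs(mean(scr$linked) - 0.05), 0.02)
})

test_that("linkage screen requires 20 individuals and skips monomorphic loci", {
  g <- geno_fixture(rep("A/T", 10))
  expect_error(linkage_screen(g), "20 individuals")
  gm <- bind_rows(
    geno_fixture(rep(c("A/T", "A/A"), 10), locus = "L1"),
    geno_fixture(rep("C/C", 20), locus = "L2"))
  scr <- linkage_screen(gm, n_perm = 99, seed = 1)
  expect_equal(nrow(scr), 0)     # only pair has a monomorphic member
})

test_that("genome-wide theta is a ratio of summed components", {
  fix <- bind_rows(geno_fixture(rep("A/A", 10)),
                   geno_fixture(rep("T/T", 10), collection = "c2", prefix = "j"))
  expect_equal(genomewide_fst(fix)$fst, 1)
  # multi-locus: agrees with summing oracle components
  set.seed(23)
  mk <- function(coll, prefix) {
    bind_rows(lapply(1:5, function(l) {
      m <- matrix(sample(c("A", "C", "G"), 40, TRUE), ncol = 2)
      tibble(indiv = sprintf("%s%d", prefix, 1:20), collection = coll,
             repunit = coll, locus = paste0("L", l),
             allele_1 = m[, 1], allele_2 = m[, 2])
    }))
  }
  g <- bind_rows(mk("c1", "a"), mk("c2", "b"))
  per_locus <- vapply(paste0("L", 1:5), function(l) {
    gl <- g |> filter(locus == l)
    m1 <- as.matrix(gl[gl$collection == "c1", c("allele_1", "allele_2")])
    m2 <- as.matrix(gl[gl$collection == "c2", c("allele_1", "allele_2")])
    oracle_wc_theta(m1, m2)
  }, 0)
  # ratio-of-averages differs from average-of-ratios; both bounded sanity
  gw <- genomewide_fst(g)$fst
  expect_true(gw > min(per_locus) - 1e-9 && gw < max(per_locus) + 1e-9)
})
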