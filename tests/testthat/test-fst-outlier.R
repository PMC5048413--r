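test_that("allele counts from genotypes tally dosages and missingness", {
  g <- genotype_matrix(matrix(c(0L, 2L, 1L, NA), 2, 2), c("p1", "p2"))
  ac <- allele_counts_from_genotypes(g)
  expect_equal(unname(ac$a[, "p1"]), c(0L, 2L))
  expect_equal(unname(ac$n[1, ]), c(2L, 2L))
  expect_equal(unname(ac$n[2, ]), c(2L, 0L))  # missing individual drops n

  g2 <- genotype_matrix(matrix(c(0L, 2L), 1, 2), c("p1", "p1"))
  ac2 <- allele_counts_from_genotypes(g2)
  expect_equal(unname(ac2$a[1, 1]), 2L)
  expect_equal(unname(ac2$n[1, 1]), 4L)

  gm <- genotype_matrix(matrix(c(NA, NA, 1L, 1L), 1, 4),
                        c("p1", "p1", "p2", "p2"))
  acm <- allele_counts_from_genotypes(gm)
  expect_equal(unname(acm$n[1, ]), c(0L, 4L))
  expect_equal(attr(acm, "flagged_loci"), gm$loci$locus_id[1])

  set.seed(3)
  geno <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 5, 12)
  pops <- rep(c("x", "y", "z"), each = 4)
  gg <- genotype_matrix(geno, pops)
  acc <- allele_counts_from_genotypes(gg)
  for (p in c("x", "y", "z")) {
    cols <- which(pops == p)
    expect_equal(unname(acc$a[, p]),
                 unname(rowSums(geno[, cols], na.rm = TRUE)))
    expect_equal(unname(acc$n[, p]),
                 unname(2L * rowSums(!is.na(geno[, cols]))))
  }
})

test_that("Weir-Cockerham F_ST matches the worksheet and its limits", {
  ct <- allele_count_table(matrix(c(5, 15), 1), matrix(c(20, 20), 1))
  f <- wc_fst(ct)
  expect_equal(unname(f$per_locus_fst), 0.3684211, tolerance = 1e-6)
  expect_equal(f$global_fst, unname(f$per_locus_fst))

  fixed <- allele_count_table(matrix(c(0, 20), 1), matrix(c(20, 20), 1))
  expect_equal(unname(wc_fst(fixed)$per_locus_fst), 1)

  # same frequencies in every population: estimator near zero
  set.seed(4)
  a <- matrix(rbinom(300 * 4, 200, 0.4), 300, 4)
  f0 <- wc_fst(allele_count_table(a, matrix(200, 300, 4)))
  expect_lt(abs(f0$global_fst), 0.02)

  # allele-label swap invariance
  ct2 <- allele_count_table(matrix(c(5, 12, 30, 2), 2),
                            matrix(c(20, 20, 40, 18), 2))
  swapped <- allele_count_table(ct2$n - ct2$a, ct2$n)
  expect_equal(wc_fst(ct2)$per_locus_fst, wc_fst(swapped)$per_locus_fst)

  mono <- allele_count_table(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE),
                             matrix(10, 2, 2))
  expect_true(is.na(wc_fst(mono)$per_locus_fst[1]))
})

test_that("HWE exact test equals enumeration and handles edge cases", {
  expect_equal(hwe_exact(5, 0, 0), 1)   # monomorphic
  expect_equal(hwe_exact(0, 2, 0), oracle_hwe(0, 2, 0))
  set.seed(10)
  for (i in 1:40) {
    n <- sample(1:30, 1)
    aa <- sample(0:n, 1); het <- sample(0:(n - aa), 1)
    expect_equal(hwe_exact(aa, het, n - aa - het),
                 oracle_hwe(aa, het, n - aa - het), tolerance = 1e-12,
                 info = sprintf("(%d,%d,%d)", aa, het, n - aa - het))
  }
})

test_that("LD test: perfect correlation, monomorphic partner, null uniformity", {
  set.seed(5)
  g <- sample(0:2, 40, replace = TRUE, prob = c(.25, .5, .25))
  dup <- ld_test(g, g, n_mc = 4000, seed = 1)
  expect_lt(dup$p_value, 0.01)

  mono <- ld_test(g, rep(1L, 40), n_mc = 1000, seed = 1)
  expect_equal(mono$p_value, 1)
  expect_true(mono$flagged)

  set.seed(6)
  ps <- replicate(200, {
    a <- rbinom(60, 2, 0.5); b <- rbinom(60, 2, 0.5)
    ld_test(a, b, n_mc = 2000, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("posterior q-values follow the cumulative-mean definition", {
  expect_equal(qvalues_from_posterior(rep(1, 4)), rep(0, 4))
  expect_equal(qvalues_from_posterior(c(0.9, 0.5)), c(0.1, 0.3))
  expect_equal(qvalues_from_posterior(c(0.5, 0.9)), c(0.3, 0.1))
  expect_equal(qvalues_from_posterior(rep(0, 3)), rep(1, 3))
})

test_that("outlier classification follows q-threshold and alpha sign", {
  res <- data.frame(q_value = c(0.01, 0.01, 0.20, 0.01),
                    alpha_mean = c(1.2, -0.8, 3.0, 0))
  expect_warning(out <- classify_outliers(res), "alpha_mean exactly 0")
  expect_equal(out$selection_class,
               c("diversifying", "balancing", "neutral", "neutral"))
})

test_that("transect consistency intersects outlier sets", {
  mk <- function(cls) data.frame(locus_id = c("l1", "l2", "l3"),
                                 selection_class = cls,
                                 stringsAsFactors = FALSE)
  glob <- mk(c("balancing", "diversifying", "neutral"))
  loc1 <- mk(c("balancing", "neutral", "neutral"))
  loc2 <- mk(c("balancing", "neutral", "diversifying"))
  out <- transect_consistency(glob, list(t1 = loc1, t2 = loc2))
  expect_equal(out$locus_id, "l1")
  expect_true(out$class_agreement)

  none <- transect_consistency(mk(rep("neutral", 3)), list(t1 = loc1))
  expect_equal(nrow(none), 0L)
})

test_that("scan posterior matches a dense-grid conjugate-style check", {
  # two loci, two populations, p and beta fixed: posterior of alpha is a
  # 1-D integral we can evaluate on a grid
  a <- matrix(c(38, 3, 20, 20), 2, 2, byrow = TRUE)
  n <- matrix(40, 2, 2)
  ct <- allele_count_table(a, n)
  set <- mcmc_settings(n_iter = 9000, burn_in = 3000, thinning = 1,
                       n_pilot = 3, pilot_length = 300, seed = 2)
  scan <- bayescan_scan(ct, set,
                        fixed = list(p = 0.5, beta = c(-1, -1),
                                     always_include = TRUE))
  grid <- seq(-6, 6, length.out = 2001)
  post_mean <- function(i) {
    ll <- vapply(grid, function(al) {
      th <- exp(-(al + c(-1, -1)))
      sum(lbeta(a[i, ] + 0.5 * th, n[i, ] - a[i, ] + 0.5 * th) -
            lbeta(0.5 * th, 0.5 * th))
    }, numeric(1))
    w <- exp(ll - max(ll)) * stats::dnorm(grid, 0, 1)
    sum(grid * w) / sum(w)
  }
  expect_lt(abs(scan$results$alpha_mean[1] - post_mean(1)), 0.1)
  expect_lt(abs(scan$results$alpha_mean[2] - post_mean(2)), 0.1)
})

test_that("scan is reproducible under a seed and excludes monomorphic loci", {
  sim <- simulate_allele_counts(
    island_model_params(n_loci = 30, alpha = c(2, rep(0, 29)), seed = 3))
  set <- mcmc_settings(n_iter = 2500, burn_in = 1500, thinning = 1,
                       n_pilot = 2, pilot_length = 200, seed = 5)
  s1 <- suppressMessages(bayescan_scan(sim$counts, set))
  s2 <- suppressMessages(bayescan_scan(sim$counts, set))
  expect_identical(s1$results, s2$results)
  expect_identical(s1$beta, s2$beta)

  mono_a <- sim$counts$a; mono_a[2, ] <- 0
  ct <- allele_count_table(mono_a, sim$counts$n)
  expect_message(s3 <- bayescan_scan(ct, set), "monomorphic")
  expect_false(ct$locus_ids[2] %in% s3$results$locus_id)
})
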