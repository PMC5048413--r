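test_that("concatenation preserves columns, boundaries and likelihood", {
  tree <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2);")
  g1 <- simulate_codon_alignment(
    seq_sim_params(tree, omega_map = 0.3, n_codons = 40, seed = 1), "g1")
  g2 <- simulate_codon_alignment(
    seq_sim_params(tree, omega_map = 0.3, n_codons = 60, seed = 2), "g2")
  cc <- concatenate(list(g1, g2))
  expect_equal(ncol(cc$codons), 100L)
  expect_equal(attr(cc, "gene_map")$end, c(40L, 100L))
  expect_identical(concatenate(list(g1))$codons, g1$codons)

  p <- codon_model_params(2, 0.3)
  expect_equal(log_likelihood(cc, tree, p),
               log_likelihood(g1, tree, p) + log_likelihood(g2, tree, p),
               tolerance = 1e-9)

  bad <- g2; bad$taxon_ids[1] <- "zz"; rownames(bad$codons)[1] <- "zz"
  expect_error(concatenate(list(g1, bad)), "taxon set mismatch")
})

test_that("bootstrap with identity resampling equals the point fit; seeded runs repeat", {
  tree <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2);")
  aln <- simulate_codon_alignment(
    seq_sim_params(tree, omega_map = 0.3, n_codons = 80, seed = 6))
  part <- setNames(c("x", "y", "y"), branch_ids(tree))
  point <- fit_branch(aln, tree, branch_partition = part, control = quick_ctl)
  boot1 <- bootstrap_branch_rates(aln, tree, n_rep = 1, seed = 5,
                                  branch_partition = part,
                                  resample = identity_resample,
                                  control = quick_ctl)
  expect_equal(unname(boot1$omega[1, names(point$omegas)]),
               unname(point$omegas), tolerance = 1e-9)

  b1 <- bootstrap_branch_rates(aln, tree, n_rep = 3, seed = 11,
                               branch_partition = part, control = quick_ctl)
  b2 <- bootstrap_branch_rates(aln, tree, n_rep = 3, seed = 11,
                               branch_partition = part, control = quick_ctl)
  expect_identical(b1$omega, b2$omega)
})

test_that("equal true rates give overlapping bootstrap distributions", {
  # paired bootstrap replicates share the original dataset, so under equal
  # true rates the per-dataset success fraction is roughly uniform rather
  # than concentrated at 1/2 and the binomial comparison is loose by
  # construction (see the methods vignette). The testable overlap property:
  # the two branches' bootstrap ranges intersect in nearly every dataset,
  # successes fall on both sides across datasets, and a fair share of
  # datasets stay non-significant.
  tree <- ape::read.tree(text = "(a:0.25,b:0.25,c:0.25);")
  nonsig <- 0; ranges_overlap <- 0; ks <- integer(0)
  for (trial in 1:10) {
    aln <- simulate_codon_alignment(
      seq_sim_params(tree, omega_map = 0.3, n_codons = 100,
                     seed = 200 + trial))
    boot <- bootstrap_branch_rates(aln, tree, n_rep = 12, seed = trial,
                                   control = list(max_sweeps = 2,
                                                  tol = 1e-2, starts = 0.5))
    a <- boot$omega[, "a"]; b <- boot$omega[, "b"]
    nonsig <- nonsig + (binomial_rate_test(a, b) > 0.05)
    ranges_overlap <- ranges_overlap +
      (min(max(a), max(b)) > max(min(a), min(b)))
    ks <- c(ks, sum(a > b))
  }
  expect_gte(ranges_overlap, 8)
  expect_gte(nonsig, 3)
  expect_true(any(ks < 6) && any(ks > 6))  # no systematic branch bias
})

test_that("paired binomial test matches closed forms and enumeration", {
  expect_equal(binomial_rate_test(rep(2, 1000), rep(1, 1000)),
               2 * 0.5^1000)
  expect_equal(binomial_rate_test(c(rep(2, 500), rep(0, 500)), rep(1, 1000)),
               1)
  # k = 600 of 1000: exact two-sided tail sum
  p600 <- binomial_rate_test(c(rep(2, 600), rep(0, 400)), rep(1, 1000))
  x <- 0:1000
  expect_equal(p600, sum(dbinom(x[abs(x - 500) >= 100], 1000, 0.5)),
               tolerance = 1e-12)
  # ties count as half-successes
  expect_equal(binomial_rate_test(c(2, 1), c(1, 1)),
               sum(dbinom(0:2, 2, 0.5)[abs(0:2 - 1) >= 0.5]))
  expect_error(binomial_rate_test(1:3, 1:4), "equal length")
})

test_that("binomial test p-values are calibrated (super-uniform) under the null", {
  # the exact two-sided test at n = 50 is discrete, so its null p-values are
  # super-uniform: P(p <= t) <= t at every threshold (within binomial noise)
  set.seed(31)
  ps <- replicate(200, {
    binomial_rate_test(rnorm(50), rnorm(50))
  })
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    expect_lte(mean(ps <= t), t + 3 * sqrt(t * (1 - t) / 200))
  }
  # and not degenerate: large p-values do occur in fair proportion
  expect_gt(mean(ps > 0.5), 0.3)
})

test_that("category rates: null flatness, planted power, global identity", {
  set.seed(8)
  # all genes equal omega: nothing can be 'higher than average'
  eq <- setNames(rep(0.2, 50), sprintf("g%02d", 1:50))
  ann_eq <- data.frame(gene_id = names(eq),
                       category_id = rep(c("c1", "c2"), 25))
  out <- category_rates(eq, ann_eq, min_genes = 5, n_boot = 200, seed = 1)
  expect_true(all(out$p_value == 1))

  # category covering the whole universe has exactly the global mean
  omg <- setNames(stats::rlnorm(100, log(0.2), 0.5), sprintf("g%03d", 1:100))
  ann_all <- data.frame(gene_id = names(omg), category_id = "everything")
  out2 <- category_rates(omg, ann_all, n_boot = 100, seed = 2)
  expect_equal(out2$mean_omega, mean(omg))

  # planted 3x category detected; permuting labels destroys it
  hits <- 0
  for (trial in 1:10) {
    set.seed(1000 + trial)
    omega <- stats::rlnorm(500, log(0.15), 0.4)
    names(omega) <- sprintf("g%03d", 1:500)
    omega[1:20] <- omega[1:20] * 3
    ann <- data.frame(gene_id = names(omega),
                      category_id = rep(sprintf("cat%02d", 1:25), each = 20))
    res <- category_rates(omega, ann, n_boot = 500, seed = trial)
    hits <- hits + (res$q_value[res$category_id == "cat01"] < 0.05)
  }
  expect_gte(hits, 9)

  set.seed(77)
  omega <- stats::rlnorm(500, log(0.15), 0.4)
  names(omega) <- sprintf("g%03d", 1:500)
  omega[1:20] <- omega[1:20] * 3
  qs <- replicate(10, {
    ann <- data.frame(gene_id = sample(names(omega)),
                      category_id = rep(sprintf("cat%02d", 1:25), each = 20))
    res <- category_rates(omega, ann, n_boot = 300,
                          seed = sample.int(1e6, 1))
    res$q_value[res$category_id == "cat01"]
  })
  expect_gt(mean(qs), 0.3)
})

test_that("enrichment test matches the hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  ann <- data.frame(gene_id = universe[1:10], category_id = "term")
  psg <- c(universe[1:5], universe[51:55])  # k = 5 of K = 10, n = 10
  res <- enrichment_test(psg, universe, ann)
  closed <- sum(choose(10, 5:10) * choose(90, 10 - (5:10))) / choose(100, 10)
  expect_equal(res$p_value, closed, tolerance = 1e-12)
  expect_equal(res[, c("k", "K", "n", "N")],
               data.frame(k = 5L, K = 10L, n = 10L, N = 100L),
               ignore_attr = TRUE)

  res_all <- enrichment_test(universe, universe, ann)
  expect_true(all(res_all$p_value == 1))

  none <- enrichment_test(universe[51:60], universe, ann)  # k = 0
  expect_gt(none$p_value, 0.5)
  expect_error(enrichment_test("g001", character(0), ann), "empty universe")
  expect_error(enrichment_test("zzz", universe, ann), "subset")
})

test_that("BH q-values match an independent step-up implementation", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("gene-function edge list covers exactly the selected genes", {
  ann <- data.frame(gene_id = c("g1", "g1", "g2", "g3"),
                    category_id = c("c1", "c2", "c1", "c3"))
  edges <- gene_function_edges(c("g1", "g3"), ann)
  expect_setequal(edges$gene_id, c("g1", "g3"))
  expect_equal(nrow(edges), 3L)
})
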