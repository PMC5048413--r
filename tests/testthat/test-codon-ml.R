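test_that("GY94 rate matrix is a reversible generator", {
  set.seed(2)
  pi <- as.numeric(stats::rgamma(61, 2)); pi <- pi / sum(pi)
  params <- codon_model_params(kappa = 3, omega_map = 0.7, codon_freqs = pi)
  Q <- build_rate_matrix(params, 0.7)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance over all entries: pi_x q_xy = pi_y q_yx
  expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-14)

  Q0 <- build_rate_matrix(params, 0)
  expect_equal(Q0["TTT", "GTT"], 0)          # Phe -> Val, nonsynonymous
  expect_gt(Q0["TTT", "TTC"], 0)             # Phe -> Phe, synonymous
  expect_equal(Q["AAA", "TTT"], 0)           # > 1 position apart
  expect_warning(build_rate_matrix(
    codon_model_params(2, 1, codon_freqs = c(0, rep(1 / 60, 60))), 1),
    "pseudo-frequency")
})

test_that("pruning equals enumeration over internal-node states", {
  for (seed in 1:12) {
    inst <- random_lnL_instance(seed)
    got <- log_likelihood(inst$aln, inst$tree, inst$params)
    want <- oracle_lnL(inst$tree, inst$aln, inst$params, inst$omega)
    expect_lt(abs(got - want), 1e-8)
  }
})

test_that("degenerate cases: zero branch lengths, duplicated and gap columns", {
  tree0 <- ape::read.tree(text = "(a:0,b:0,c:0);")
  aln0 <- codon_alignment(c(a = "ATGAAA", b = "ATGAAA", c = "ATGAAA"), "g")
  params <- codon_model_params(2, 0.5)
  expect_equal(log_likelihood(aln0, tree0, params), 2 * log(1 / 61),
               tolerance = 1e-10)

  inst <- random_lnL_instance(99)
  base <- log_likelihood(inst$aln, inst$tree, inst$params)
  dup <- codon_alignment(cbind(inst$aln$codons, inst$aln$codons), "dup")
  expect_equal(log_likelihood(dup, inst$tree, inst$params), 2 * base,
               tolerance = 1e-9)

  gapped <- codon_alignment(cbind(inst$aln$codons, "---"), "gap")
  expect_equal(log_likelihood(gapped, inst$tree, inst$params), base,
               tolerance = 1e-9)
})

test_that("likelihood is invariant to row order and root placement", {
  inst <- random_lnL_instance(7)
  base <- log_likelihood(inst$aln, inst$tree, inst$params)
  perm <- codon_alignment(inst$aln$codons[rev(seq_len(nrow(inst$aln$codons))), ],
                          "perm")
  expect_equal(log_likelihood(perm, inst$tree, inst$params), base,
               tolerance = 1e-10)

  unrooted <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,c:0.3,d:0.4);")
  rooted <- ape::read.tree(text = "(((a:0.1,b:0.2):0.05,c:0.3):0.25,d:0.15);")
  aln <- codon_alignment(matrix(sample(sense_codons(), 16, replace = TRUE), 4,
                                dimnames = list(c("a", "b", "c", "d"), NULL)),
                         "r")
  p <- codon_model_params(2.5, 0.4)
  expect_equal(log_likelihood(aln, unrooted, p),
               log_likelihood(aln, rooted, p), tolerance = 1e-9)
})

test_that("a neutral site mixture collapses to the single-class model", {
  inst <- random_lnL_instance(5)
  p1 <- codon_model_params(inst$params$kappa, 1, inst$params$codon_freqs)
  mix <- site_class_mix(0.5, 0.3, omega0 = 1 - 1e-9, omega2 = 1)
  expect_equal(
    log_likelihood(inst$aln, inst$tree, p1, mix = mix, foreground = "a"),
    log_likelihood(inst$aln, inst$tree, p1), tolerance = 1e-6)
})

test_that("likelihood ratio test follows the chi-square tail", {
  expect_equal(lrt(-100, -100)$p_value, 1)
  expect_equal(lrt(-100, -100 + 3.841 / 2)$p_value, 0.0500, tolerance = 1e-3)
  expect_equal(lrt(-100, -95)$p_value, 1.565e-3, tolerance = 1e-3)
  expect_equal(lrt(-100, -100.5)$statistic, 0)  # clipped
  expect_equal(lrt(-100, -100.5)$p_value, 1)
  expect_error(lrt(-10, -9, df = 0))
})

test_that("branch model with a single class reproduces M0 exactly", {
  tree <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2);")
  aln <- simulate_codon_alignment(
    seq_sim_params(tree, omega_map = 0.4, n_codons = 120, seed = 77))
  m0 <- fit_m0(aln, tree, control = quick_ctl)
  one <- setNames(rep("all", 3), branch_ids(tree))
  br <- fit_branch(aln, tree, branch_partition = one, control = quick_ctl)
  expect_lt(abs(m0$lnL - br$lnL), 1e-6)
  expect_lt(abs(m0$omega - br$omegas[["all"]]), 1e-8)
})

test_that("fitted likelihood dominates the generating parameters", {
  tree <- example_phylogeny()
  aln <- simulate_codon_alignment(
    seq_sim_params(tree, kappa = 2, omega_map = 0.2, n_codons = 200,
                   seed = 15))
  fit <- fit_m0(aln, tree, codon_freqs = rep(1 / 61, 61))
  truth <- log_likelihood(aln, tree, codon_model_params(2, 0.2))
  expect_gte(fit$lnL, truth - 1e-6)
})

test_that("branch-site fit: alternative dominates null, flags low information", {
  tree <- example_phylogeny()
  aln <- simulate_codon_alignment(
    seq_sim_params(tree, site_mix = site_class_mix(0.7, 0.2, 0.1, 4),
                   foreground = "rana_high", n_codons = 150, seed = 33))
  bs <- fit_branch_site(aln, tree, foreground = "rana_high",
                        control = quick_ctl)
  expect_gte(bs$lrt$lnL_alt, bs$lrt$lnL_null)
  expect_gte(bs$lrt$statistic, 0)
  expect_true(bs$lrt$p_value >= 0 && bs$lrt$p_value <= 1)
  expect_false(bs$lrt$low_information)
  expect_error(fit_branch_site(aln, tree, foreground = "no_such_branch"),
               "not found")

  const <- codon_alignment(
    matrix("ATG", 5, 70, dimnames = list(tree$tip.label, NULL)), "const")
  bs0 <- fit_branch_site(const, tree, foreground = "rana_high",
                         control = quick_ctl)
  expect_true(bs0$lrt$low_information)
  expect_equal(bs0$lrt$statistic, 0, tolerance = 1e-6)
})

test_that("CODEML-style #1 marks designate the foreground", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  tree$tip.label[1] <- "a#1"
  pf <- parse_foreground(tree)
  expect_equal(pf$foreground, "a")
  expect_equal(sort(pf$tree$tip.label), c("a", "b", "c", "d"))
})
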