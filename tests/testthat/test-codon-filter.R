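mk_aln <- function(n_codons, ntaxa = 2, codon = "ATG", gene = "g") {
  m <- matrix(codon, ntaxa, n_codons,
              dimnames = list(letters[1:ntaxa], NULL))
  codon_alignment(m, gene_id = gene)
}

test_that("validation flags internal stops and short alignments", {
  expect_length(validate_codon_alignment(mk_aln(70)), 0L)         # 210 nt
  expect_equal(validate_codon_alignment(mk_aln(66)), "too_short") # 198 nt
  a <- mk_aln(80)
  a$codons[1, 10] <- "TGA"
  expect_equal(validate_codon_alignment(a), "internal_stop")
  short_stop <- mk_aln(50)
  short_stop$codons[1, 10] <- "TGA"  # 150 nt: both reasons reported
  expect_setequal(validate_codon_alignment(short_stop),
                  c("internal_stop", "too_short"))
  b <- mk_aln(70)
  b$codons[1, 70] <- "TAA"  # terminal stop is expected, not flagged
  expect_length(validate_codon_alignment(b), 0L)
})

test_that("trimming removes gappy columns, preserves order, is idempotent", {
  a <- mk_aln(70, ntaxa = 4)
  expect_identical(trim_alignment(a)$codons, a$codons)

  a$codons[2, 5] <- "A-G"
  tr <- trim_alignment(a, max_gap_fraction = 0)
  expect_equal(ncol(tr$codons), 69L)

  set.seed(1)
  b <- mk_aln(40, ntaxa = 3)
  b$codons[sample(length(b$codons), 20)] <- "NNN"
  t1 <- trim_alignment(b)
  expect_identical(trim_alignment(t1)$codons, t1$codons)

  allgap <- mk_aln(5, codon = "---")
  expect_error(trim_alignment(allgap), "all columns removed")
})

test_that("NG86 counting matches an independent worksheet", {
  a <- c("TTT", "TTC", "CTG", "ATG", "GAA", "AAA", "CGC", "AGC", "GGG", "TAC")
  b <- c("TTC", "TTC", "CTC", "ATG", "GAC", "AGA", "CGC", "AGC", "GGG", "TAC")
  ng <- ng86_pairwise(a, b)
  # frozen from a first-principles tabulation (site fractions, single-step
  # differences, Jukes-Cantor correction) computed outside the package
  expect_equal(ng$syn_sites, 5.3333333333, tolerance = 1e-9)
  expect_equal(ng$nonsyn_sites, 24.6666666667, tolerance = 1e-9)
  expect_equal(ng$syn_diffs, 2)
  expect_equal(ng$nonsyn_diffs, 2)
  expect_equal(ng$dS, 0.5198603854, tolerance = 1e-9)
  expect_equal(ng$dN, 0.0858077634, tolerance = 1e-9)

  ident <- ng86_pairwise(a, a)
  expect_equal(ident$dN, 0); expect_equal(ident$dS, 0)

  syn1 <- ng86_pairwise("TTT", "TTC")  # both Phe
  expect_equal(syn1$dN, 0)
  expect_gt(syn1$dS, 0)

  # symmetry, gap skipping, degenerate input
  ba <- ng86_pairwise(b, a)
  expect_equal(ba$dN, ng$dN); expect_equal(ba$dS, ng$dS)
  gap <- ng86_pairwise(c("TTT", "---"), c("TTC", "AAA"))
  expect_equal(gap$n_codons_compared, 1L)
  expect_error(ng86_pairwise("---", "AAA"), "zero comparable")
})

test_that("saturation flags undefined or capped dS", {
  expect_length(saturation_filter(mk_aln(70)), 0L)

  # every codon differs synonymously: proportion >= 3/4, correction undefined
  sat <- codon_alignment(rbind(a = rep("TTT", 70), b = rep("TTC", 70)), "s")
  expect_equal(saturation_filter(sat), "saturated")
  expect_true(is.infinite(ng86_pairwise(sat$codons[1, ], sat$codons[2, ])$dS))
})

test_that("deep-divergence simulations are usually flagged saturated", {
  # at total branch length 10 true dS is far beyond 3, but the NG86 counting
  # estimator itself saturates (finite estimates cluster at 1.5-3.5), so a
  # quarter of replicates sneak under the cap: the filter catches most, not
  # all, fully saturated pairs (see the methods vignette)
  tree <- ape::read.tree(text = "(a:5,b:5);")  # total length 10
  hits <- 0
  for (r in 1:100) {
    aln <- simulate_codon_alignment(
      seq_sim_params(tree, omega_map = 0.2, n_codons = 100, seed = 900 + r))
    hits <- hits + (length(saturation_filter(aln)) > 0)
  }
  expect_gte(hits, 70)
})

test_that("filter_orthologs applies validate, trim, saturation in order", {
  tree <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2);")
  alns <- lapply(1:8, function(g) simulate_codon_alignment(
    seq_sim_params(tree, omega_map = 0.2, n_codons = 80, seed = 40 + g),
    gene_id = sprintf("clean_%d", g)))
  short <- mk_aln(66, gene = "short_gene")
  stopg <- mk_aln(80, gene = "stop_gene")
  stopg$codons[1, 10] <- "TAA"
  out <- filter_orthologs(c(alns, list(short, stopg)))
  expect_equal(sum(out$reports$retained), 8L)
  expect_equal(nrow(out$reports), 10L)
  expect_match(out$reports$reasons[out$reports$gene_id == "short_gene"],
               "too_short")
  expect_match(out$reports$reasons[out$reports$gene_id == "stop_gene"],
               "internal_stop")
  expect_setequal(names(out$retained), sprintf("clean_%d", 1:8))

  expect_warning(empty <- filter_orthologs(list()), "no alignments")
  expect_equal(nrow(empty$reports), 0L)
})

test_that("NG86 dN/dS stays below 1 on purifying simulations", {
  tree <- ape::read.tree(text = "(a:0.3,b:0.3);")
  ratios <- numeric(0)
  for (r in 1:50) {
    aln <- simulate_codon_alignment(
      seq_sim_params(tree, omega_map = 0.2, n_codons = 150, seed = 700 + r))
    ng <- ng86_pairwise(aln$codons[1, ], aln$codons[2, ])
    if (ng$dS > 0 && is.finite(ng$dS)) ratios <- c(ratios, ng$dN / ng$dS)
  }
  expect_gt(length(ratios), 40)
  expect_lt(mean(ratios), 1)
})
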