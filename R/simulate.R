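#' Parameters for the codon-alignment simulator
#'
#' Defines a GY94 generative model on a tree: either one omega per branch
#' (`omega_map`) or a branch-site mixture (`site_mix` + `foreground`) in
#' which i.i.d. site classes choose the omega regime per site.
#'
#' @param tree [ape::phylo] with branch lengths (expected substitutions per
#'   codon). CODEML-style `#1` labels may designate the foreground.
#' @param kappa Transition/transversion ratio.
#' @param omega_map Scalar or named per-branch omega (ignored when
#'   `site_mix` given).
#' @param site_mix Optional [site_class_mix()].
#' @param foreground Foreground branch ids when `site_mix` is given.
#' @param codon_freqs Stationary codon frequencies (61-vector, sums to 1).
#' @param n_codons Number of codon columns to simulate.
#' @param seed Integer seed; identical parameters and seed give identical
#'   output.
#' @return An object of class `seq_sim_params`.
#' @export
seq_sim_params <- function(tree, kappa = 2, omega_map = NULL, site_mix = NULL,
                           foreground = NULL, codon_freqs = rep(1 / 61, 61),
                           n_codons, seed = 1) {
  if (is.null(foreground)) {
    pf <- parse_foreground(tree)
    tree <- pf$tree
    if (length(pf$foreground)) foreground <- pf$foreground
  }
  stopifnot(kappa > 0, n_codons >= 1, length(codon_freqs) == 61)
  if (abs(sum(codon_freqs) - 1) > 1e-9) stop("codon_freqs must sum to 1")
  if (length(tree$tip.label) < 2) stop("tree must have at least 2 leaves")
  if (is.null(site_mix) && is.null(omega_map))
    stop("omega_map is required when site_mix is absent")
  if (!is.null(site_mix) && !length(foreground))
    stop("site_mix requires foreground branch(es)")
  structure(list(tree = tree, kappa = kappa, omega_map = omega_map,
                 site_mix = site_mix, foreground = foreground,
                 codon_freqs = as.numeric(codon_freqs),
                 n_codons = as.integer(n_codons), seed = as.integer(seed)),
            class = "seq_sim_params")
}

#' Simulate a codon alignment under the GY94 model
#'
#' Draws the root sequence from the stationary codon frequencies and evolves
#' it along the tree with branch-specific (and, for branch-site simulation,
#' site-class-specific) transition probabilities. Stop codons are never
#' emitted; there are no gaps. Per-branch random substreams are derived from
#' the global seed so the output is reproducible.
#'
#' @param params A [seq_sim_params()].
#' @param gene_id Gene id for the returned alignment.
#' @return A [codon_alignment()] with attribute `site_class` (integer, 1-4;
#'   all 1 when `site_mix` is absent) giving the true per-site class.
#' @export
simulate_codon_alignment <- function(params, gene_id = "sim_gene") {
  stopifnot(inherits(params, "seq_sim_params"))
  pt <- prepare_tree(params$tree)
  pi <- check_pi(params$codon_freqs)
  nc <- params$n_codons
  nedge <- nrow(pt$edge)
  fg <- pt$ids %in% params$foreground

  if (is.null(params$site_mix)) {
    class_omega <- matrix(resolve_omega_map(params$omega_map, pt$ids), ncol = 1)
    weights <- 1.0
  } else {
    m <- params$site_mix
    class_omega <- bs_class_omega(fg, m$omega0, m$omega2)
    weights <- m$weights
  }
  nclass <- length(weights)

  set.seed(params$seed)
  site_class <- if (nclass == 1) rep(1L, nc) else
    sample.int(nclass, nc, replace = TRUE, prob = weights)
  root_state <- sample.int(61L, nc, replace = TRUE, prob = pi)
  edge_seed <- sample.int(.Machine$integer.max - 1L, nedge)

  nnode <- max(pt$edge)
  states <- matrix(NA_integer_, nnode, nc)
  root <- pt$edge[nedge, 1]
  states[root, ] <- root_state

  cache <- new.env(parent = emptyenv())
  rc <- gy94_rate_components(pi)
  for (e in rev(seq_len(nedge))) {  # reverse postorder = parents first
    parent <- pt$edge[e, 1]; child <- pt$edge[e, 2]
    set.seed(edge_seed[e])
    out <- states[parent, ]
    # site classes share one per-branch scale (see make_lnL_engine)
    rates <- gy94_rate(rc, params$kappa, class_omega[e, ])
    scale_e <- sum(weights * rates)
    for (cl in unique(site_class)) {
      w <- class_omega[e, cl]
      key <- sprintf("%.14g", w)
      dec <- cache[[key]]
      if (is.null(dec)) {
        dec <- codon_eigen(params$kappa, pi, w)
        cache[[key]] <- dec
      }
      P <- transition_matrix(dec, pt$edge_length[e] * rates[cl] / scale_e)
      sites <- which(site_class == cl)
      par_states <- states[parent, sites]
      for (x in unique(par_states)) {
        sel <- sites[par_states == x]
        out[sel] <- sample.int(61L, length(sel), replace = TRUE, prob = P[x, ])
      }
    }
    states[child, ] <- out
  }

  tipmat <- matrix(.code$sense[states[seq_len(pt$ntip), , drop = FALSE]],
                   nrow = pt$ntip, dimnames = list(pt$tree$tip.label, NULL))
  aln <- codon_alignment(tipmat, gene_id = gene_id)
  attr(aln, "site_class") <- site_class
  aln
}

#' Parameters of the island-model allele-count simulator
#'
#' The generative counterpart of the Bayesian outlier scan: per-locus and
#' per-population differentiation follows
#' `logit(F_ST(i,j)) = alpha_i + beta_j`; population allele frequencies are
#' Beta-distributed around an ancestral frequency with concentration
#' `theta_ij = 1/F_ST(i,j) - 1`, and observed counts are binomial.
#'
#' @param n_pops Number of populations (>= 2).
#' @param n_loci Number of biallelic loci.
#' @param beta Per-population effect (length `n_pops` or scalar); the default
#'   -1 puts neutral differentiation near `F_ST = 0.27`.
#' @param alpha Per-locus selection effect (length `n_loci` or scalar);
#'   positive = diversifying, negative = balancing, 0 = neutral.
#' @param ancestral_freq_prior Beta shape pair for the ancestral allele
#'   frequency. The default `c(2, 2)` favours mid-range frequencies, as is
#'   realistic for a genotyped tag-SNP panel (SNPs are ascertained as
#'   polymorphic before genotyping); use `c(1, 1)` for unascertained loci.
#' @param sample_sizes Sampled allele counts per population (default 40 =
#'   20 diploid individuals).
#' @param seed Integer seed.
#' @return An object of class `island_model_params`.
#' @export
island_model_params <- function(n_pops = 5, n_loci = 100, beta = -1,
                                alpha = 0, ancestral_freq_prior = c(2, 2),
                                sample_sizes = 40, seed = 1) {
  if (n_pops < 2) stop("n_pops must be >= 2")
  beta <- rep_len(beta, n_pops)
  alpha <- rep_len(alpha, n_loci)
  sample_sizes <- rep_len(sample_sizes, n_pops)
  if (any(sample_sizes < 2)) stop("sample sizes must be >= 2")
  stopifnot(length(ancestral_freq_prior) == 2, all(ancestral_freq_prior > 0))
  fst <- stats::plogis(outer(alpha, beta, `+`))
  if (any(!is.finite(fst)) || any(fst <= 0) || any(fst >= 1))
    stop("implied F_ST outside (0,1); check alpha and beta")
  structure(list(n_pops = as.integer(n_pops), n_loci = as.integer(n_loci),
                 beta = beta, alpha = alpha,
                 ancestral_freq_prior = ancestral_freq_prior,
                 sample_sizes = as.integer(sample_sizes),
                 seed = as.integer(seed)),
            class = "island_model_params")
}

#' Allele count table
#'
#' Container for per-locus, per-population biallelic counts: `a` is the
#' alternate-allele count and `n` the total sampled alleles.
#'
#' @param a,n Integer matrices (loci x populations), `0 <= a <= n`.
#' @param locus_ids,pop_ids Row/column identifiers.
#' @return An object of class `allele_count_table`.
#' @export
allele_count_table <- function(a, n, locus_ids = NULL, pop_ids = NULL) {
  a <- as.matrix(a); n <- as.matrix(n)
  stopifnot(all(dim(a) == dim(n)), all(a >= 0), all(a <= n))
  if (is.null(locus_ids)) locus_ids <- rownames(a)
  if (is.null(locus_ids)) locus_ids <- sprintf("locus_%03d", seq_len(nrow(a)))
  if (is.null(pop_ids)) pop_ids <- colnames(a)
  if (is.null(pop_ids)) pop_ids <- sprintf("pop%d", seq_len(ncol(a)))
  dimnames(a) <- dimnames(n) <- list(locus_ids, pop_ids)
  structure(list(a = a, n = n, locus_ids = locus_ids, pop_ids = pop_ids),
            class = "allele_count_table")
}

#' @export
print.allele_count_table <- function(x, ...) {
  cat(sprintf("allele_count_table: %d loci x %d populations\n",
              nrow(x$a), ncol(x$a)))
  invisible(x)
}

#' Simulate allele counts under the island model
#'
#' @param params An [island_model_params()].
#' @return List with `counts` (an [allele_count_table()]) and `truth`, a
#'   data.frame of the generating `alpha` and ancestral frequency `p` per
#'   locus; `beta` is attached as an attribute of `truth`.
#' @export
simulate_allele_counts <- function(params) {
  stopifnot(inherits(params, "island_model_params"))
  np <- params$n_pops; nl <- params$n_loci
  set.seed(params$seed)
  locus_seed <- sample.int(.Machine$integer.max - 1L, nl)
  a <- matrix(0L, nl, np)
  p <- numeric(nl)
  pr <- params$ancestral_freq_prior
  for (i in seq_len(nl)) {
    set.seed(locus_seed[i])
    p[i] <- min(max(rbeta(1, pr[1], pr[2]), 1e-9), 1 - 1e-9)
    fst <- stats::plogis(params$alpha[i] + params$beta)
    theta <- 1 / fst - 1
    pf <- rbeta(np, p[i] * theta, (1 - p[i]) * theta)
    pf <- pmin(pmax(pf, 0), 1)
    a[i, ] <- rbinom(np, params$sample_sizes, pf)
  }
  counts <- allele_count_table(a, matrix(rep(params$sample_sizes, each = nl),
                                         nl, np))
  truth <- data.frame(locus_id = counts$locus_ids, alpha = params$alpha,
                      p = p, stringsAsFactors = FALSE)
  attr(truth, "beta") <- params$beta
  list(counts = counts, truth = truth)
}

#' Genotype matrix container
#'
#' @param genotypes Integer matrix (loci x individuals) of alternate-allele
#'   dosages in \{0, 1, 2\}, `NA` = missing.
#' @param populations Character vector of population labels per individual.
#' @param loci Optional data.frame with columns `locus_id`, `gene_id`,
#'   `position`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, populations, loci = NULL) {
  genotypes <- as.matrix(genotypes)
  stopifnot(ncol(genotypes) == length(populations),
            all(genotypes %in% c(0L, 1L, 2L, NA)))
  if (!all(nzchar(populations))) stop("population labels must be nonempty")
  if (is.null(loci))
    loci <- data.frame(locus_id = sprintf("locus_%03d", seq_len(nrow(genotypes))),
                       gene_id = NA_character_, position = NA_integer_,
                       stringsAsFactors = FALSE)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("ind_%03d", seq_len(ncol(genotypes)))
  rownames(genotypes) <- loci$locus_id
  structure(list(loci = loci,
                 individuals = data.frame(individual_id = colnames(genotypes),
                                          population = populations,
                                          stringsAsFactors = FALSE),
                 genotypes = genotypes),
            class = "genotype_matrix")
}

#' Simulate diploid genotypes with optional inbreeding
#'
#' Genotype probabilities per individual are
#' `{(1-p)^2 + F p(1-p), 2 p (1-p)(1-F), p^2 + F p(1-p)}` for dosages
#' 0/1/2, where `p` is the population alternate-allele frequency and `F` the
#' inbreeding coefficient.
#'
#' @param pop_freqs Numeric matrix (loci x populations) of alternate-allele
#'   frequencies, or a vector for a single locus.
#' @param n_ind Individuals per population (scalar or per-population).
#' @param inbreeding_f Inbreeding coefficient in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(pop_freqs, n_ind, inbreeding_f = 0, seed = 1) {
  if (!is.matrix(pop_freqs)) pop_freqs <- matrix(pop_freqs, nrow = 1)
  stopifnot(all(pop_freqs >= 0), all(pop_freqs <= 1),
            inbreeding_f >= 0, inbreeding_f <= 1)
  np <- ncol(pop_freqs); nl <- nrow(pop_freqs)
  n_ind <- rep_len(n_ind, np)
  if (any(n_ind < 1)) stop("n_ind must be >= 1 in every population")
  set.seed(seed)
  Fc <- inbreeding_f
  pops <- rep(sprintf("pop%d", seq_len(np)), n_ind)
  g <- matrix(NA_integer_, nl, sum(n_ind))
  col0 <- cumsum(c(0, n_ind))
  for (j in seq_len(np)) {
    for (i in seq_len(nl)) {
      p <- pop_freqs[i, j]
      pq <- p * (1 - p)
      probs <- c((1 - p)^2 + Fc * pq, 2 * pq * (1 - Fc), p^2 + Fc * pq)
      g[i, (col0[j] + 1):col0[j + 1]] <-
        sample(0:2, n_ind[j], replace = TRUE, prob = probs)
    }
  }
  genotype_matrix(g, pops)
}

#' Parameters of the read-count simulator
#'
#' @param mean_coverage Mean sequencing depth per site (Poisson).
#' @param error_rate Per-read probability of a miscall (uniform over the
#'   other three bases); must be `< 0.5`.
#' @param seed Integer seed.
#' @return An object of class `read_sim_params`.
#' @export
read_sim_params <- function(mean_coverage = 250, error_rate = 0.001,
                            seed = 1) {
  stopifnot(mean_coverage > 0, error_rate >= 0, error_rate < 0.5)
  structure(list(mean_coverage = mean_coverage, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

#' Simulate per-site read counts
#'
#' Depth is Poisson at `mean_coverage`; each read samples the true allele at
#' the site's pooled alternate frequency and is miscalled with probability
#' `error_rate` (uniformly to one of the other three bases).
#'
#' @param x Either a numeric vector of pooled alternate-allele frequencies
#'   (one per site) or a [genotype_matrix()] (frequencies pooled over all
#'   individuals per locus).
#' @param params A [read_sim_params()].
#' @param gene_ids,positions Optional site metadata (defaults: one gene,
#'   positions 1..n).
#' @return data.frame with columns `gene_id`, `position`, `A`, `C`, `G`,
#'   `T`, `ref`, `alt`.
#' @export
simulate_read_counts <- function(x, params, gene_ids = NULL,
                                 positions = NULL) {
  stopifnot(inherits(params, "read_sim_params"))
  if (inherits(x, "genotype_matrix")) {
    freqs <- rowMeans(x$genotypes, na.rm = TRUE) / 2
    if (is.null(gene_ids) && !all(is.na(x$loci$gene_id)))
      gene_ids <- x$loci$gene_id
  } else {
    freqs <- as.numeric(x)
  }
  stopifnot(all(freqs >= 0), all(freqs <= 1))
  ns <- length(freqs)
  if (is.null(gene_ids)) gene_ids <- rep("gene1", ns)
  if (is.null(positions)) positions <- seq_len(ns)
  set.seed(params$seed)
  counts <- matrix(0L, ns, 4, dimnames = list(NULL, .nucs))
  ref <- character(ns); alt <- character(ns)
  err <- params$error_rate
  for (s in seq_len(ns)) {
    pair <- sample(.nucs, 2)
    ref[s] <- pair[1]; alt[s] <- pair[2]
    depth <- rpois(1, params$mean_coverage)
    n_alt <- rbinom(1, depth, freqs[s])
    for (b in c(ref[s], alt[s])) {
      n_true <- if (b == alt[s]) n_alt else depth - n_alt
      if (n_true == 0) next
      probs <- rep(err / 3, 4)
      probs[match(b, .nucs)] <- 1 - err
      counts[s, ] <- counts[s, ] + as.integer(rmultinom(1, n_true, probs))
    }
  }
  data.frame(gene_id = gene_ids, position = positions,
             A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
             T = counts[, "T"], ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Write allele counts as a long-format TSV
#'
#' Columns: `locus`, `pop`, `allele1_count`, `total`.
#' @param counts An [allele_count_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  df <- data.frame(locus = rep(counts$locus_ids, ncol(counts$a)),
                   pop = rep(counts$pop_ids, each = nrow(counts$a)),
                   allele1_count = as.vector(counts$a),
                   total = as.vector(counts$n), stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_allele_counts
#' @export
read_allele_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  loci <- unique(df$locus); pops <- unique(df$pop)
  a <- matrix(0L, length(loci), length(pops), dimnames = list(loci, pops))
  n <- a
  a[cbind(match(df$locus, loci), match(df$pop, pops))] <- df$allele1_count
  n[cbind(match(df$locus, loci), match(df$pop, pops))] <- df$total
  allele_count_table(a, n, loci, pops)
}
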