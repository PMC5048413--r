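#' Concatenate codon alignments
#'
#' Column-wise concatenation of alignments over the same taxon set, keeping
#' a gene-boundary map.
#'
#' @param alignments List of [codon_alignment()]s with identical taxa.
#' @param gene_id Id for the concatenated alignment.
#' @return A [codon_alignment()] with attribute `gene_map`, a data.frame of
#'   `gene_id`, `start`, `end` (1-based codon columns).
#' @export
concatenate <- function(alignments, gene_id = "concatenated") {
  stopifnot(length(alignments) >= 1)
  taxa <- alignments[[1]]$taxon_ids
  mats <- lapply(alignments, function(a) {
    if (!setequal(a$taxon_ids, taxa))
      stop("taxon set mismatch in gene ", a$gene_id)
    a$codons[taxa, , drop = FALSE]
  })
  ncs <- vapply(mats, ncol, integer(1))
  out <- codon_alignment(do.call(cbind, mats), gene_id = gene_id)
  ends <- cumsum(ncs)
  attr(out, "gene_map") <- data.frame(
    gene_id = vapply(alignments, function(a) a$gene_id, character(1)),
    start = c(1L, head(ends, -1) + 1L), end = ends,
    stringsAsFactors = FALSE)
  out
}

#' Bootstrap distributions of per-branch dN/dS
#'
#' Resamples codon columns of (usually concatenated) alignment with
#' replacement, refits the branch model on each replicate, and records the
#' per-branch-class omega estimates. Replicates are deterministic under
#' `seed`; non-converged replicates are recorded and kept.
#'
#' @param aln A [codon_alignment()].
#' @param tree Topology with starting branch lengths.
#' @param n_rep Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param branch_partition Passed to [fit_branch()] (default: one omega per
#'   branch).
#' @param resample Optional hook: a `function(n_columns)` returning column
#'   indices (e.g. `identity_resample` for testing); default is sampling
#'   with replacement.
#' @param control Optimizer control for [fit_branch()].
#' @return List with `omega` (n_rep x classes matrix), `n_replicates`,
#'   `seed`, `n_not_converged`.
#' @export
bootstrap_branch_rates <- function(aln, tree, n_rep = 1000, seed = 1,
                                   branch_partition = NULL, resample = NULL,
                                   control = list()) {
  nc <- ncol(aln$codons)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  out <- NULL
  bad <- 0L
  for (r in seq_len(n_rep)) {
    set.seed(rep_seeds[r])
    idx <- if (is.null(resample)) sample.int(nc, nc, replace = TRUE)
           else resample(nc)
    baln <- codon_alignment(aln$codons[, idx, drop = FALSE],
                            gene_id = paste0(aln$gene_id, "_boot", r))
    fit <- fit_branch(baln, tree, branch_partition = branch_partition,
                      control = control)
    if (!fit$converged) bad <- bad + 1L
    if (is.null(out))
      out <- matrix(NA_real_, n_rep, length(fit$omegas),
                    dimnames = list(NULL, names(fit$omegas)))
    out[r, ] <- fit$omegas
  }
  list(omega = out, n_replicates = n_rep, seed = seed,
       n_not_converged = bad)
}

#' Identity resampling hook for [bootstrap_branch_rates()]
#' @param n Number of columns.
#' @return `1:n`.
#' @export
identity_resample <- function(n) seq_len(n)

#' Paired binomial test for a rate difference between two branches
#'
#' Counts the replicates in which `omega_high > omega_low` (ties count as
#' half-successes) and performs a two-sided exact binomial test against
#' success probability 1/2: the p-value sums `Binomial(n, 1/2)` probabilities
#' over all outcomes at least as far from `n/2` as the observed count.
#'
#' @param omega_high,omega_low Equal-length paired replicate vectors (the
#'   same bootstrap resample in each position).
#' @return Two-sided exact p-value.
#' @export
binomial_rate_test <- function(omega_high, omega_low) {
  if (length(omega_high) != length(omega_low))
    stop("replicate vectors must have equal length")
  n <- length(omega_high)
  k <- sum(omega_high > omega_low) + 0.5 * sum(omega_high == omega_low)
  dev <- abs(k - n / 2)
  x <- 0:n
  min(1, sum(dbinom(x[abs(x - n / 2) >= dev - 1e-12], n, 0.5)))
}

#' Category-level dN/dS statistics
#'
#' For each annotation category with at least `min_genes` genes, computes the
#' mean per-gene omega and an upper-tail resampling p-value ("is this
#' category's mean higher than that of random same-size gene sets from the
#' universe?"), with BH FDR across categories.
#'
#' @param per_gene_omega Named numeric vector: gene id -> omega.
#' @param annotation data.frame with columns `gene_id`, `category_id` (and
#'   optionally `category_name`).
#' @param min_genes Minimum annotated genes per category.
#' @param n_boot Resampling replicates.
#' @param seed Integer seed.
#' @return data.frame with `category_id`, `n_genes`, `mean_omega`,
#'   `p_value`, `q_value`, ordered by p.
#' @export
category_rates <- function(per_gene_omega, annotation, min_genes = 5,
                           n_boot = 1000, seed = 1) {
  stopifnot(!is.null(names(per_gene_omega)),
            all(c("gene_id", "category_id") %in% names(annotation)))
  ann <- annotation[annotation$gene_id %in% names(per_gene_omega), ]
  cats <- split(unique(ann[c("gene_id", "category_id")])$gene_id,
                unique(ann[c("gene_id", "category_id")])$category_id)
  sizes <- lengths(cats)
  skipped <- names(cats)[sizes < min_genes]
  if (length(skipped))
    message("skipping ", length(skipped), " categories below min_genes")
  cats <- cats[sizes >= min_genes]
  if (!length(cats))
    return(data.frame(category_id = character(), n_genes = integer(),
                      mean_omega = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE))
  universe <- per_gene_omega
  set.seed(seed)
  res <- lapply(names(cats), function(cid) {
    genes <- cats[[cid]]
    m <- mean(universe[genes])
    boot <- vapply(seq_len(n_boot), function(i) {
      mean(sample(universe, length(genes)))
    }, numeric(1))
    data.frame(category_id = cid, n_genes = length(genes), mean_omega = m,
               p_value = (1 + sum(boot >= m)) / (n_boot + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Hypergeometric over-representation test
#'
#' For each annotation term, tests whether the term is over-represented in
#' `psg_set` relative to `universe`: upper-tail hypergeometric p with BH
#' q-values across terms. `k` = term genes in the set, `K` = term genes in
#' the universe, `n` = set size, `N` = universe size.
#'
#' @param psg_set Character vector of selected genes (subset of universe).
#' @param universe Character vector of all tested genes.
#' @param annotation data.frame with columns `gene_id`, `category_id`.
#' @return data.frame with `category_id`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, ordered by p.
#' @export
enrichment_test <- function(psg_set, universe, annotation) {
  if (!length(universe)) stop("empty universe")
  if (!all(psg_set %in% universe)) stop("psg_set must be a subset of universe")
  ann <- unique(annotation[annotation$gene_id %in% universe,
                           c("gene_id", "category_id")])
  N <- length(unique(universe))
  n <- length(unique(psg_set))
  terms <- split(ann$gene_id, ann$category_id)
  res <- lapply(names(terms), function(t) {
    K <- length(terms[[t]])
    k <- sum(terms[[t]] %in% psg_set)
    data.frame(category_id = t, k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; monotone in p-rank and always
#' `>= p`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Export a bipartite gene-function edge list
#'
#' The data behind a gene/function network figure: one row per
#' (selected gene, annotated category) pair.
#'
#' @param psg_set Character vector of selected genes.
#' @param annotation data.frame with `gene_id`, `category_id`.
#' @return data.frame with columns `gene_id`, `category_id`.
#' @export
gene_function_edges <- function(psg_set, annotation) {
  unique(annotation[annotation$gene_id %in% psg_set,
                    c("gene_id", "category_id")])
}
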