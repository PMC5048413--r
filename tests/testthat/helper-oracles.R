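# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the code paths they check: matrix exponentials come from
# Matrix::expm (not the package's spectral decomposition), likelihoods from
# explicit sums over internal-node states (not pruning), and best-hit logic
# from a direct reading of the definition.

quick_ctl <- list(max_sweeps = 3, tol = 1e-3, starts = 0.5)

# brute-force GY94 log-likelihood by enumeration over internal-node codon
# assignments; supports 3-taxon star and 4-taxon unrooted trees
oracle_lnL <- function(tree, aln, params, omega) {
  tr <- ape::reorder.phylo(tree, "postorder")
  Q <- build_rate_matrix(params, omega)
  P <- lapply(tr$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  ntip <- length(tr$tip.label)
  states <- matrix(match(aln$codons, sense_codons()), nrow = nrow(aln$codons))
  states <- states[match(tr$tip.label, aln$taxon_ids), , drop = FALSE]
  pi <- params$codon_freqs
  internal <- sort(unique(tr$edge[tr$edge > ntip]))
  root <- tr$edge[nrow(tr$edge), 1]
  stopifnot(length(internal) <= 2)
  total <- 0
  for (s in seq_len(ncol(states))) {
    lik <- 0
    if (length(internal) == 1) {
      for (x in 1:61) {
        term <- pi[x]
        for (e in seq_len(nrow(tr$edge)))
          term <- term * P[[e]][x, states[tr$edge[e, 2], s]]
        lik <- lik + term
      }
    } else {
      other <- setdiff(internal, root)
      for (x in 1:61) for (y in 1:61) {
        assign_state <- function(node) if (node == root) x else
          if (node == other) y else states[node, s]
        term <- pi[x]
        for (e in seq_len(nrow(tr$edge))) {
          term <- term * P[[e]][assign_state(tr$edge[e, 1]),
                                assign_state(tr$edge[e, 2])]
        }
        lik <- lik + term
      }
    }
    total <- total + log(lik)
  }
  unname(total)
}

# random small codon-model test instance for the pruning-vs-enumeration check
random_lnL_instance <- function(seed) {
  set.seed(seed)
  ntaxa <- sample(3:4, 1)
  nsite <- sample(1:5, 1)
  taxa <- letters[1:ntaxa]
  bl <- round(runif(if (ntaxa == 3) 3 else 5, 0.02, 0.8), 3)
  txt <- if (ntaxa == 3) {
    sprintf("(a:%g,b:%g,c:%g);", bl[1], bl[2], bl[3])
  } else {
    sprintf("((a:%g,b:%g):%g,c:%g,d:%g);", bl[1], bl[2], bl[3], bl[4], bl[5])
  }
  tree <- ape::read.tree(text = txt)
  pi <- as.numeric(stats::rgamma(61, 2, 1)); pi <- pi / sum(pi)
  params <- codon_model_params(kappa = runif(1, 0.5, 5),
                               omega_map = runif(1, 0.05, 3),
                               codon_freqs = pi)
  cod <- matrix(sample(sense_codons(), ntaxa * nsite, replace = TRUE),
                nrow = ntaxa, dimnames = list(taxa, NULL))
  list(tree = tree, aln = codon_alignment(cod, "oracle_gene"),
       params = params, omega = unname(params$omega_map))
}

# definition-checking best-reciprocal-hit oracle (same tie rule, written
# straight from the definition rather than via sort/dedup)
oracle_brh <- function(hits_ab, hits_ba, e_threshold = 1e-10) {
  best_of <- function(hits, q) {
    h <- hits[hits$qseqid == q, , drop = FALSE]
    if (!nrow(h)) return(NULL)
    b <- h[1, ]
    for (r in seq_len(nrow(h))[-1]) {
      cand <- h[r, ]
      better <- cand$bitscore > b$bitscore ||
        (cand$bitscore == b$bitscore && cand$evalue < b$evalue) ||
        (cand$bitscore == b$bitscore && cand$evalue == b$evalue &&
           cand$sseqid < b$sseqid)
      if (better) b <- cand
    }
    b
  }
  pairs <- character(0)
  for (q in unique(hits_ab$qseqid)) {
    fwd <- best_of(hits_ab, q)
    if (is.null(fwd) || fwd$evalue > e_threshold) next
    rev <- best_of(hits_ba, fwd$sseqid)
    if (is.null(rev) || rev$evalue > e_threshold) next
    if (rev$sseqid == q) pairs <- c(pairs, paste(q, fwd$sseqid))
  }
  sort(pairs)
}

random_hit_tables <- function(seed, n_a = 8, n_b = 8, n_hits = 60) {
  set.seed(seed)
  qa <- sprintf("a%02d", seq_len(n_a)); qb <- sprintf("b%02d", seq_len(n_b))
  mk <- function(qs, ss) data.frame(
    qseqid = sample(qs, n_hits, replace = TRUE),
    sseqid = sample(ss, n_hits, replace = TRUE),
    bitscore = sample(seq(50, 70, by = 5), n_hits, replace = TRUE),
    evalue = 10^-sample(c(5, 9, 12, 20, 30), n_hits, replace = TRUE),
    stringsAsFactors = FALSE)
  list(ab = mk(qa, qb), ba = mk(qb, qa))
}

# exact HWE p by full enumeration of genotype tables with the observed
# allele counts, probabilities from multinomial coefficients
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  tabs <- list()
  for (het in 0:min(nA, 2 * n - nA)) {
    if ((nA - het) %% 2 != 0) next
    aa_hom <- (nA - het) / 2
    bb_hom <- n - aa_hom - het
    if (bb_hom < 0) next
    tabs[[length(tabs) + 1]] <- c(aa_hom, het, bb_hom)
  }
  logp <- vapply(tabs, function(t)
    lgamma(n + 1) - sum(lgamma(t + 1)) + t[2] * log(2), numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- which(vapply(tabs, function(t) t[2] == n_Aa, logical(1)))
  sum(pr[pr <= pr[obs] * (1 + 1e-9)])
}

# brute-force best local alignment score with affine gaps: enumerate every
# monotone set of aligned residue pairs; unaligned residues strictly inside
# the aligned region cost gap_open + len * gap_extend per run
oracle_local_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  na <- length(sa); nb <- length(sb)
  best <- 0
  combs <- function(n, k) if (k == 0) list(integer(0)) else
    utils::combn(n, k, simplify = FALSE)
  for (k in seq_len(min(na, nb))) {
    for (ia in combs(na, k)) for (ib in combs(nb, k)) {
      sc <- sum(mat[cbind(sa[ia], sb[ib])])
      if (k > 1) {
        ga <- diff(ia) - 1L; gb <- diff(ib) - 1L
        sc <- sc - sum(ifelse(ga > 0, gap_open + ga * gap_extend, 0)) -
          sum(ifelse(gb > 0, gap_open + gb * gap_extend, 0))
      }
      if (sc > best) best <- sc
    }
  }
  best
}

# independent BH step-up from the definition: q_i = min over ranks >= rank_i
# of p_(j) * n / j
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    ri <- which(ord == i)
    cand <- vapply(ri:n, function(j) p[ord[j]] * n / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

short_mcmc <- function(seed = 1) {
  mcmc_settings(n_iter = 7000, burn_in = 5000, thinning = 1,
                n_pilot = 4, pilot_length = 500, seed = seed)
}
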