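#' Codon substitution model parameters
#'
#' Parameters of the Goldman-Yang (GY94) codon model: transition/transversion
#' ratio kappa, a per-branch nonsynonymous/synonymous rate ratio omega, and
#' stationary codon frequencies pi over the 61 sense codons.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega_map Either a single omega applied to every branch or a named
#'   numeric vector keyed by [branch_ids()].
#' @param codon_freqs Numeric 61-vector summing to 1 (codon order of
#'   [sense_codons()]); defaults to uniform.
#' @return An object of class `codon_model_params`.
#' @export
codon_model_params <- function(kappa, omega_map,
                               codon_freqs = rep(1 / 61, 61)) {
  stopifnot(kappa > 0, all(omega_map >= 0), length(codon_freqs) == 61)
  if (abs(sum(codon_freqs) - 1) > 1e-9)
    stop("codon_freqs must sum to 1")
  structure(list(kappa = kappa, omega_map = omega_map,
                 codon_freqs = setNames(as.numeric(codon_freqs), .code$sense)),
            class = "codon_model_params")
}

#' Site-class mixture of branch-site model A
#'
#' Four site classes: class 0 (omega0 on all branches, proportion p0),
#' class 1 (neutral, proportion p1), and classes 2a/2b in which foreground
#' branches take omega2 while background branches keep omega0 or 1. The 2a/2b
#' proportions split `1 - p0 - p1` in ratio `p0 : p1`.
#'
#' @param p0,p1 Proportions of the two background-only classes
#'   (`p0 + p1 <= 1`).
#' @param omega0 Purifying-class omega in `[0, 1)`.
#' @param omega2 Foreground omega (`>= 1`; fixed at 1 under the null).
#' @return An object of class `site_class_mix` with the four class
#'   proportions in `$weights`.
#' @export
site_class_mix <- function(p0, p1, omega0, omega2) {
  stopifnot(p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12, p0 + p1 > 0,
            omega0 >= 0, omega0 < 1 + 1e-12, omega2 >= 0)
  p2 <- max(0, 1 - p0 - p1)
  w <- c(p0, p1, p2 * p0 / (p0 + p1), p2 * p1 / (p0 + p1))
  structure(list(p0 = p0, p1 = p1, omega0 = omega0, omega2 = omega2,
                 weights = w / sum(w)),
            class = "site_class_mix")
}

# GY94 generator, scaled to one expected substitution per codon per unit
# time: q_xy = pi_y * kappa^[transition] * omega^[nonsynonymous] for single-
# nucleotide changes, 0 otherwise.
build_Q <- function(kappa, pi, omega) {
  Q <- matrix(0, 61, 61, dimnames = list(.code$sense, .code$sense))
  rate <- pi[.pairs$j] *
    ifelse(.pairs$transition, kappa, 1) *
    ifelse(.pairs$synonymous, 1, omega)
  Q[cbind(.pairs$i, .pairs$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) scale <- 1  # omega = 0 with degenerate pi: leave unscaled
  Q / scale
}

# Stationary substitution-rate components of the unscaled GY94 generator:
# rate(kappa, omega) = (sTV + kappa*sTS) + omega*(nTV + kappa*nTS).
# Mixture classes on a branch share one scale (the class-weighted mean
# rate), so relative speeds between site classes are preserved - the
# convention CODEML uses for branch-site models.
gy94_rate_components <- function(pi) {
  w <- pi[.pairs$i] * pi[.pairs$j]
  c(sTV = sum(w[.pairs$synonymous & !.pairs$transition]),
    sTS = sum(w[.pairs$synonymous & .pairs$transition]),
    nTV = sum(w[!.pairs$synonymous & !.pairs$transition]),
    nTS = sum(w[!.pairs$synonymous & .pairs$transition]))
}

gy94_rate <- function(rc, kappa, omega) {
  unname((rc["sTV"] + kappa * rc["sTS"]) +
           omega * (rc["nTV"] + kappa * rc["nTS"]))
}

check_pi <- function(pi) {
  pi <- as.numeric(pi)
  if (length(pi) != 61) stop("codon_freqs must have length 61")
  if (any(pi <= 0)) {
    warning("zero codon frequencies; applying pseudo-frequency")
    pi <- pi + 1e-6
  }
  pi / sum(pi)
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61 x 61 generator for a given omega: entries are zero for
#' codon pairs differing at more than one position and otherwise
#' `pi_y`, `kappa * pi_y`, `omega * pi_y` or `omega * kappa * pi_y` for
#' synonymous transversions/transitions and nonsynonymous
#' transversions/transitions. Rows sum to zero and the matrix is scaled so
#' the expected substitution rate at stationarity is 1.
#'
#' @param params A [codon_model_params()].
#' @param omega Nonsynonymous/synonymous rate ratio for this matrix.
#' @return 61 x 61 numeric matrix (codon order of [sense_codons()]).
#' @export
build_rate_matrix <- function(params, omega) {
  stopifnot(inherits(params, "codon_model_params"), omega >= 0)
  build_Q(params$kappa, check_pi(params$codon_freqs), omega)
}

# Spectral decomposition of the reversible Q via symmetrization:
# P(t) = U diag(exp(lam t)) Uinv.
codon_eigen <- function(kappa, pi, omega) {
  Q <- build_Q(kappa, pi, omega)
  s <- sqrt(pi)
  B <- Q * outer(s, 1 / s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / s, lam = e$values, Uinv = t(e$vectors * s))
}

# Dense transition probability matrix (used by the simulator and oracles).
transition_matrix <- function(decomp, t) {
  P <- decomp$U %*% (decomp$Uinv * exp(decomp$lam * t))
  P[P < 0] <- 0
  P / rowSums(P)
}

# Shared evaluation engine: fixes alignment patterns, tree shape and pi,
# caches eigendecompositions across likelihood evaluations.
make_lnL_engine <- function(aln, tree, pi, foreground = NULL) {
  pt <- prepare_tree(tree, aln$taxon_ids)
  pi <- check_pi(pi)
  cp <- compress_patterns(aln)
  states <- cp$states[pt$tree$tip.label, , drop = FALSE]
  states[is.na(states)] <- 0L
  storage.mode(states) <- "integer"
  fg <- pt$ids %in% foreground
  if (!is.null(foreground) && length(foreground) && !any(fg))
    stop("foreground branch(es) not found in tree: ",
         paste(setdiff(foreground, pt$ids), collapse = ", "))
  cache <- new.env(parent = emptyenv())
  eig <- function(kappa, omega) {
    key <- sprintf("%.14g|%.14g", kappa, omega)
    d <- cache[[key]]
    if (is.null(d)) {
      if (length(ls(cache)) > 400) rm(list = ls(cache), envir = cache)
      d <- codon_eigen(kappa, pi, omega)
      cache[[key]] <- d
    }
    d
  }
  rc <- gy94_rate_components(pi)
  n_eval <- 0L
  evaluate <- function(kappa, class_omega, class_weights, edge_length) {
    omegas <- sort(unique(as.numeric(class_omega)))
    dec <- lapply(omegas, function(w) eig(kappa, w))
    edge_decomp <- matrix(match(as.numeric(class_omega), omegas),
                          nrow = nrow(class_omega))
    storage.mode(edge_decomp) <- "integer"
    # per-branch common scaling across site classes: effective length of
    # (edge e, class c) is t_e * rate(omega_ec) / weighted-mean rate
    rate_mat <- matrix(gy94_rate(rc, kappa, as.numeric(class_omega)),
                       nrow = nrow(class_omega))
    scale_e <- as.numeric(rate_mat %*% class_weights)
    t_eff <- edge_length * rate_mat / scale_e
    sll <- codon_pruning_loglik(states, pt$edge, t_eff,
                                lapply(dec, `[[`, "U"),
                                lapply(dec, `[[`, "lam"),
                                lapply(dec, `[[`, "Uinv"),
                                edge_decomp, pi, class_weights)
    n_eval <<- n_eval + 1L
    sum(sll * cp$weights)
  }
  nvar <- sum(apply(states, 2, function(x) {
    x <- x[x > 0]; length(unique(x)) > 1
  }) * (cp$weights > 0))
  list(evaluate = evaluate, nedge = nrow(pt$edge), ids = pt$ids, fg = fg,
       pi = pi, n_variable = nvar, n_eval = function() n_eval)
}

# omega matrix (nedge x 4) for branch-site model A given (omega0, omega2)
bs_class_omega <- function(fg, omega0, omega2) {
  cbind(ifelse(fg, omega0, omega0), rep(1, length(fg)),
        ifelse(fg, omega2, omega0), ifelse(fg, omega2, 1))
}

#' Log-likelihood of a codon alignment under a GY94 model
#'
#' Felsenstein pruning over the 61 sense-codon states. With a
#' [site_class_mix()] the per-site likelihood is the class-proportion
#' weighted sum of the four class-specific likelihoods (branch-site model
#' A); otherwise each branch uses its `omega_map` entry. Gap, `N` and stop
#' codons are treated as missing data at the affected tips.
#'
#' @param aln A [codon_alignment()].
#' @param tree An [ape::phylo] with branch lengths in expected substitutions
#'   per codon; tips must match the alignment taxa.
#' @param params A [codon_model_params()].
#' @param mix Optional [site_class_mix()]; requires `foreground`.
#' @param foreground Branch ids (see [branch_ids()]) forming the foreground
#'   when `mix` is given.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood <- function(aln, tree, params, mix = NULL, foreground = NULL) {
  eng <- make_lnL_engine(aln, tree, params$codon_freqs, foreground)
  pt <- prepare_tree(tree, aln$taxon_ids)
  el <- pt$edge_length
  if (is.null(mix)) {
    om <- resolve_omega_map(params$omega_map, eng$ids)
    eng$evaluate(params$kappa, matrix(om, ncol = 1), 1.0, el)
  } else {
    co <- bs_class_omega(eng$fg, mix$omega0, mix$omega2)
    eng$evaluate(params$kappa, co, mix$weights, el)
  }
}

# ---- optimization ---------------------------------------------------------

# Coordinate-wise bounded maximization. Each parameter is searched by Brent
# within a window around its current value; the window shrinks to track the
# step size of the previous sweep, so late sweeps cost only a few likelihood
# evaluations per coordinate. Windows expand when the optimum hits a window
# edge (never past the hard bounds).
coord_ascent <- function(par, lower, upper, fn, window,
                         tol = 1e-6, max_sweeps = 12,
                         sweep_tol = c(0.05, 0.01, 0.005)) {
  cur <- fn(par)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    otol <- sweep_tol[min(sweep, length(sweep_tol))]
    for (k in seq_along(par)) {
      lo <- max(lower[k], par[k] - window[k])
      hi <- min(upper[k], par[k] + window[k])
      repeat {
        opt <- optimize(function(v) {
          p <- par; p[k] <- v; fn(p)
        }, interval = c(lo, hi), maximum = TRUE, tol = otol)
        at_lo <- opt$maximum - lo < 2 * otol && lo > lower[k] + 1e-12
        at_hi <- hi - opt$maximum < 2 * otol && hi < upper[k] - 1e-12
        if (!at_lo && !at_hi) break
        window[k] <- 2 * window[k]
        if (at_lo) lo <- max(lower[k], lo - window[k])
        if (at_hi) hi <- min(upper[k], hi + window[k])
      }
      if (opt$objective > cur) {
        window[k] <- min(window[k],
                         max(4 * abs(opt$maximum - par[k]), 8 * otol))
        par[k] <- opt$maximum
        cur <- opt$objective
      } else {
        window[k] <- min(window[k], 16 * otol)
      }
    }
    if (cur - prev < tol) { converged <- TRUE; break }
  }
  list(par = par, lnL = cur, converged = converged)
}

fit_control <- function(control = list()) {
  def <- list(tol = 1e-6, max_sweeps = 12, starts = c(0.5, 2),
              omega2_grid = c(1 + 1e-6, 2.5, 8))
  def[names(control)] <- control
  def
}

init_edge_lengths <- function(tree) {
  el <- ape::reorder.phylo(tree, "postorder")$edge.length
  el[!is.finite(el) | el <= 0] <- 0.1
  pmin(el, 50)
}

.LOG_BL_MIN <- log(1e-7)

#' Fit the one-ratio (M0) codon model
#'
#' Maximizes the GY94 likelihood over kappa, a single omega shared by all
#' branches, and all branch lengths; codon frequencies are fixed at their
#' F3x4 estimates from the alignment. Optimization is coordinate-wise
#' bounded ascent on log scale with two omega starts.
#'
#' @param aln A [codon_alignment()].
#' @param tree Topology (branch lengths used as starting values when
#'   positive). Rooted trees are unrooted first.
#' @param codon_freqs Optional 61-vector overriding F3x4.
#' @param control List of optimizer settings (`tol`, `max_sweeps`,
#'   `starts`).
#' @return List with `kappa`, `omega`, `branch_lengths` (named by branch
#'   id), `lnL`, `codon_freqs`, `converged`, `n_eval`.
#' @export
fit_m0 <- function(aln, tree, codon_freqs = NULL, control = list()) {
  ctl <- fit_control(control)
  tree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pi <- if (is.null(codon_freqs)) f3x4_frequencies(aln) else codon_freqs
  eng <- make_lnL_engine(aln, tree, pi)
  el0 <- init_edge_lengths(tree)
  nb <- eng$nedge
  fn <- function(p) {
    eng$evaluate(exp(p[1]), matrix(rep(exp(p[2]), nb), ncol = 1), 1.0,
                 exp(p[2 + seq_len(nb)]))
  }
  lower <- c(log(0.1), log(1e-4), rep(.LOG_BL_MIN, nb))
  upper <- c(log(99), log(999), rep(log(50), nb))
  window <- c(1.5, 2, rep(1.5, nb))
  best <- NULL
  for (w_start in ctl$starts) {
    par <- c(log(2), log(w_start), log(el0))
    res <- coord_ascent(par, lower, upper, fn, window,
                        tol = ctl$tol, max_sweeps = ctl$max_sweeps)
    if (is.null(best) || res$lnL > best$lnL) best <- res
  }
  p <- best$par
  list(kappa = exp(p[1]), omega = exp(p[2]),
       branch_lengths = setNames(exp(p[2 + seq_len(nb)]), eng$ids),
       lnL = best$lnL, codon_freqs = setNames(eng$pi, .code$sense),
       converged = best$converged, n_eval = eng$n_eval())
}

#' Fit a branch model (one omega per branch class)
#'
#' Like [fit_m0()] but with an independent omega for each class of branches.
#' The default partition assigns every branch its own omega (the free-ratios
#' model used to measure per-branch evolutionary rates).
#'
#' @inheritParams fit_m0
#' @param branch_partition Named character vector mapping branch ids to class
#'   labels, or `NULL` for one class per branch. All branches in a class
#'   share an omega.
#' @return List with `kappa`, `omegas` (named by class), `branch_lengths`,
#'   `lnL`, `converged`, `n_eval`.
#' @export
fit_branch <- function(aln, tree, branch_partition = NULL,
                       codon_freqs = NULL, control = list()) {
  ctl <- fit_control(control)
  tree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pi <- if (is.null(codon_freqs)) f3x4_frequencies(aln) else codon_freqs
  eng <- make_lnL_engine(aln, tree, pi)
  nb <- eng$nedge
  if (is.null(branch_partition)) {
    cls <- setNames(eng$ids, eng$ids)
  } else {
    missing <- setdiff(eng$ids, names(branch_partition))
    if (length(missing))
      stop("branch_partition missing branch(es): ",
           paste(missing, collapse = ", "))
    cls <- branch_partition[eng$ids]
  }
  classes <- unique(unname(cls))
  ncl <- length(classes)
  cls_idx <- match(unname(cls), classes)
  el0 <- init_edge_lengths(tree)
  fn <- function(p) {
    om <- exp(p[1 + seq_len(ncl)])[cls_idx]
    eng$evaluate(exp(p[1]), matrix(om, ncol = 1), 1.0,
                 exp(p[1 + ncl + seq_len(nb)]))
  }
  lower <- c(log(0.1), rep(log(1e-4), ncl), rep(.LOG_BL_MIN, nb))
  upper <- c(log(99), rep(log(999), ncl), rep(log(50), nb))
  window <- c(1.5, rep(2, ncl), rep(1.5, nb))
  best <- NULL
  for (w_start in ctl$starts) {
    par <- c(log(2), rep(log(w_start), ncl), log(el0))
    res <- coord_ascent(par, lower, upper, fn, window,
                        tol = ctl$tol, max_sweeps = ctl$max_sweeps)
    if (is.null(best) || res$lnL > best$lnL) best <- res
  }
  p <- best$par
  list(kappa = exp(p[1]),
       omegas = setNames(exp(p[1 + seq_len(ncl)]), classes),
       branch_lengths = setNames(exp(p[1 + ncl + seq_len(nb)]), eng$ids),
       lnL = best$lnL, converged = best$converged, n_eval = eng$n_eval())
}

#' Likelihood ratio test
#'
#' `p = P(chi2_df >= 2 (lnL_alt - lnL_null))` with the statistic clipped at
#' zero. The chi-square reference (rather than the 50:50 point-mass mixture)
#' makes the boundary test conservative.
#'
#' @param lnL_null,lnL_alt Optimized log-likelihoods of nested models.
#' @param df Degrees of freedom (>= 1).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(lnL_null, lnL_alt, df = 1) {
  stopifnot(df >= 1)
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Branch-site test for positive selection (model A)
#'
#' Fits the branch-site model A alternative (foreground omega2 free, >= 1)
#' and null (omega2 fixed at 1), both with kappa, site-class proportions,
#' omega0 and all branch lengths re-optimized, and performs the one-degree
#' LRT. The alternative is started from the optimized null (where the two
#' models coincide) plus a small omega2 grid, so `lnL_alt >= lnL_null` by
#' monotone ascent. A gene is a putative positively selected gene (PSG) when
#' `p < p_threshold`.
#'
#' @inheritParams fit_m0
#' @param foreground Branch id(s) of the foreground (see [branch_ids()]);
#'   alternatively mark the tree with CODEML-style `#1` labels and pass
#'   `foreground = NULL`.
#' @param p_threshold PSG call threshold on the raw LRT p-value.
#' @return List with `null`, `alt` (fitted parameter lists) and `lrt`, a
#'   one-row data.frame (`gene_id`, `lnL_null`, `lnL_alt`, `statistic`,
#'   `df`, `p_value`, `is_psg`, `low_information`, `converged`).
#' @export
fit_branch_site <- function(aln, tree, foreground = NULL, codon_freqs = NULL,
                            p_threshold = 0.05, control = list()) {
  # a slightly looser default lnL tolerance than the point fits: the LRT
  # compares two fits anchored at the same start, so shared residual error
  # cancels while cost halves
  if (is.null(control$tol)) control$tol <- 1e-4
  ctl <- fit_control(control)
  if (is.null(foreground)) {
    pf <- parse_foreground(tree)
    tree <- pf$tree
    foreground <- pf$foreground
  }
  if (!length(foreground)) stop("no foreground branch designated")
  tree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pi <- if (is.null(codon_freqs)) f3x4_frequencies(aln) else codon_freqs
  eng <- make_lnL_engine(aln, tree, pi, foreground = foreground)
  nb <- eng$nedge
  el0 <- init_edge_lengths(tree)
  low_info <- eng$n_variable < 2

  # working scale: log kappa, log omega0, f = p0+p1, r = p0/(p0+p1),
  # [log omega2], log branch lengths
  make_fn <- function(omega2_free) {
    function(p) {
      w0 <- exp(p[2])
      f <- p[3]; r <- p[4]
      w2 <- if (omega2_free) exp(p[5]) else 1
      mixw <- site_class_mix(f * r, f * (1 - r), min(w0, 1), w2)$weights
      bl <- exp(p[(if (omega2_free) 5 else 4) + seq_len(nb)])
      eng$evaluate(exp(p[1]), bs_class_omega(eng$fg, w0, w2), mixw, bl)
    }
  }
  lower0 <- c(log(0.1), log(1e-4), 0.05, 0.02)
  upper0 <- c(log(99), log(1 - 1e-6), 1 - 1e-6, 1 - 0.02)
  win0 <- c(1.5, 1.5, 0.25, 0.25)

  # warm start: a coarse one-ratio fit pins kappa and branch lengths near
  # their optima before the (4x costlier) mixture sweeps
  m0 <- fit_m0(aln, tree, codon_freqs = pi,
               control = list(max_sweeps = 3, starts = 0.5, tol = 1e-3))
  el0 <- pmax(pmin(m0$branch_lengths, 50), 1e-7)
  fn_null <- make_fn(FALSE)
  par0 <- c(log(m0$kappa), log(min(max(m0$omega, 1e-3), 0.9)), 0.85, 0.7,
            log(el0))
  nres <- coord_ascent(par0, c(lower0, rep(.LOG_BL_MIN, nb)),
                       c(upper0, rep(log(50), nb)), fn_null,
                       c(win0, rep(1.5, nb)),
                       tol = ctl$tol, max_sweeps = ctl$max_sweeps)

  fn_alt <- make_fn(TRUE)
  pn <- nres$par
  grid <- vapply(ctl$omega2_grid, function(w2) {
    fn_alt(c(pn[1:4], log(w2), pn[4 + seq_len(nb)]))
  }, numeric(1))
  par1 <- c(pn[1:4], log(ctl$omega2_grid[which.max(grid)]),
            pn[4 + seq_len(nb)])
  ares <- coord_ascent(par1,
                       c(lower0, log(1), rep(.LOG_BL_MIN, nb)),
                       c(upper0, log(999), rep(log(50), nb)),
                       fn_alt, c(win0, 1.5, rep(1.5, nb)),
                       tol = ctl$tol, max_sweeps = ctl$max_sweeps)
  # the null is nested at omega2 = 1: never report alt below null
  lnL_alt <- max(ares$lnL, nres$lnL)

  unpack <- function(p, omega2_free) {
    w2 <- if (omega2_free) exp(p[5]) else 1
    off <- if (omega2_free) 5 else 4
    list(kappa = exp(p[1]),
         mix = site_class_mix(p[3] * p[4], p[3] * (1 - p[4]),
                              min(exp(p[2]), 1), w2),
         branch_lengths = setNames(exp(p[off + seq_len(nb)]), eng$ids))
  }
  test <- lrt(nres$lnL, lnL_alt, df = 1)
  res <- data.frame(gene_id = aln$gene_id, lnL_null = nres$lnL,
                    lnL_alt = lnL_alt, statistic = test$statistic,
                    df = test$df, p_value = test$p_value,
                    is_psg = test$p_value < p_threshold,
                    omega2 = if (ares$lnL >= nres$lnL) exp(ares$par[5]) else 1,
                    low_information = low_info,
                    converged = nres$converged && ares$converged,
                    stringsAsFactors = FALSE)
  list(null = c(unpack(nres$par, FALSE), lnL = nres$lnL),
       alt = c(unpack(ares$par, TRUE), lnL = lnL_alt),
       lrt = res, n_eval = eng$n_eval() + m0$n_eval)
}
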