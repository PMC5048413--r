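#' Allele counts from a genotype matrix
#'
#' `a_ij` sums alternate-allele dosages of population `j` at locus `i`;
#' `n_ij` is twice the number of non-missing individuals. Loci with a
#' population of zero genotyped individuals are flagged.
#'
#' @param g A [genotype_matrix()].
#' @return An [allele_count_table()] with attribute `flagged_loci`.
#' @export
allele_counts_from_genotypes <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  pops <- unique(g$individuals$population)
  a <- sapply(pops, function(p) {
    cols <- g$individuals$population == p
    rowSums(g$genotypes[, cols, drop = FALSE], na.rm = TRUE)
  })
  n <- sapply(pops, function(p) {
    cols <- g$individuals$population == p
    2L * rowSums(!is.na(g$genotypes[, cols, drop = FALSE]))
  })
  a <- matrix(a, nrow = nrow(g$genotypes)); n <- matrix(n, nrow = nrow(a))
  out <- allele_count_table(a, n, g$loci$locus_id, pops)
  attr(out, "flagged_loci") <- g$loci$locus_id[apply(n == 0, 1, any)]
  out
}

#' Weir-Cockerham F_ST from allele counts
#'
#' Variance-components estimator (Weir & Cockerham 1984) on allele-count
#' data: per locus, `theta = a / (a + b)` with between-population component
#' `a = (MSP - MSG) / n_c` and within component `b = MSG`; the global value
#' is the ratio of summed components across loci. Loci monomorphic across
#' all populations are undefined (`NA`). Invariant to swapping allele labels.
#'
#' @param counts An [allele_count_table()] with >= 2 populations sampled.
#' @return List with `per_locus_fst` (named) and `global_fst`.
#' @export
wc_fst <- function(counts) {
  stopifnot(inherits(counts, "allele_count_table"))
  comp <- function(ai, ni) {
    ok <- ni > 0
    ai <- ai[ok]; ni <- ni[ok]
    r <- length(ni)
    if (r < 2) return(c(NA, NA))
    p <- ai / ni
    pbar <- sum(ai) / sum(ni)
    if (pbar <= 0 || pbar >= 1) return(c(NA, NA))
    msp <- sum(ni * (p - pbar)^2) / (r - 1)
    msg <- sum(ni * p * (1 - p)) / sum(ni - 1)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    c((msp - msg) / nc, msg)
  }
  ab <- t(vapply(seq_len(nrow(counts$a)),
                 function(i) comp(counts$a[i, ], counts$n[i, ]),
                 numeric(2)))
  per <- ab[, 1] / (ab[, 1] + ab[, 2])
  ok <- !is.na(ab[, 1])
  if (!any(ok)) stop("no polymorphic locus with >= 2 sampled populations")
  list(per_locus_fst = setNames(per, counts$locus_ids),
       global_fst = sum(ab[ok, 1]) / sum(ab[ok, 1] + ab[ok, 2]))
}

#' Exact test for Hardy-Weinberg equilibrium (biallelic)
#'
#' Conditional on the observed allele counts, sums the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed table.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (>= 0, sum >= 1).
#' @return Exact p-value.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one individual required")
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hmax <- min(nA, 2 * n - nA)
  h <- seq(nA %% 2, hmax, by = 2)
  logp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial(n - (nA + h) / 2) + h * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, h)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' Monte-Carlo exact test for linkage disequilibrium
#'
#' Tests independence of the two-locus genotype contingency table with the
#' probability-test statistic, using the Monte-Carlo exact test of
#' [stats::fisher.test()] (conditional on table margins). A monomorphic
#' locus yields `p = 1` and is flagged.
#'
#' @param geno_a,geno_b Genotype dosage vectors (0/1/2, `NA` allowed) over
#'   the same individuals.
#' @param n_mc Number of Monte-Carlo tables.
#' @param seed Integer seed.
#' @return List with `p_value`, `se` (MC standard error; 0 when the exact
#'   enumeration was used) and `flagged`.
#' @export
ld_test <- function(geno_a, geno_b, n_mc = 10000, seed = 1) {
  stopifnot(length(geno_a) == length(geno_b))
  ok <- !is.na(geno_a) & !is.na(geno_b)
  tab <- table(factor(geno_a[ok], levels = 0:2),
               factor(geno_b[ok], levels = 0:2))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    return(list(p_value = 1, se = 0, flagged = TRUE))
  set.seed(seed)
  if (nrow(tab) == 2 && ncol(tab) == 2) {
    p <- fisher.test(tab)$p.value
    return(list(p_value = p, se = 0, flagged = FALSE))
  }
  p <- fisher.test(tab, simulate.p.value = TRUE, B = n_mc)$p.value
  list(p_value = p, se = sqrt(p * (1 - p) / n_mc), flagged = FALSE)
}

#' MCMC run control for the outlier scan
#'
#' Defaults mirror the published defaults of the BayeScan-style scan: 20
#' pilot rounds of 2000 iterations for proposal tuning, 50,000 burn-in, and
#' 5,000 retained samples at thinning 10.
#'
#' @param n_iter Total post-pilot iterations (burn-in + sampling).
#' @param burn_in Discarded iterations (`< n_iter`).
#' @param thinning Keep every `thinning`-th post-burn-in iteration.
#' @param n_pilot,pilot_length Proposal-tuning rounds and their length.
#' @param prior_odds_neutral Prior odds for the neutral (alpha excluded)
#'   model; 10 means neutrality is a priori 10x more likely.
#' @param seed Integer seed.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 100000, burn_in = 50000, thinning = 10,
                          n_pilot = 20, pilot_length = 2000,
                          prior_odds_neutral = 10, seed = 1) {
  stopifnot(burn_in < n_iter, thinning >= 1, prior_odds_neutral > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 n_pilot = as.integer(n_pilot),
                 pilot_length = as.integer(pilot_length),
                 prior_odds_neutral = prior_odds_neutral,
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# beta-binomial log-likelihood matrix for given effective alpha, p, beta
# (theta_ij = exp(-(alpha_i + beta_j)) since logit(F_ST) = alpha + beta)
bb_loglik <- function(a, n, alpha_eff, p, beta) {
  th <- exp(-outer(alpha_eff, beta, `+`))
  s1 <- p * th
  s2 <- (1 - p) * th
  lbeta(a + s1, n - a + s2) - lbeta(s1, s2)
}

#' BayeScan-style hierarchical Bayesian F_ST outlier scan
#'
#' Decomposes locus-by-population differentiation as
#' `logit(F_ST(i,j)) = alpha_i + beta_j` with a beta-binomial likelihood for
#' the allele counts. A reversible-jump move toggles each locus-specific
#' `alpha_i` in and out of the model against prior odds
#' `prior_odds_neutral`; the posterior inclusion probability yields q-values
#' ([qvalues_from_posterior()]) and the sign of the posterior mean alpha the
#' selection class (positive = diversifying, negative = balancing).
#' Priors: `alpha ~ N(0, 1)`, `beta ~ N(-1, 1.8)`, ancestral frequencies
#' uniform. Loci monomorphic across all populations are excluded before the
#' scan.
#'
#' @param counts An [allele_count_table()] (>= 2 populations, >= 2 loci).
#' @param settings An [mcmc_settings()].
#' @param q_threshold Outlier threshold passed to [classify_outliers()].
#' @param fixed Optional diagnostic constraints: a list with any of `p`
#'   (ancestral frequencies), `beta`, and `always_include = TRUE` to disable
#'   the reversible-jump move (alpha always in the model).
#' @return List with `results` (data.frame: `locus_id`, `fst`, `alpha_mean`,
#'   `alpha_sd`, `inclusion_prob`, `q_value`, `selection_class`), `beta`
#'   (posterior mean/sd per population), `diagnostics` (acceptance rates,
#'   `flagged` if any falls below 5 percent after tuning), and
#'   `n_monomorphic_excluded`.
#' @export
bayescan_scan <- function(counts, settings = mcmc_settings(),
                          q_threshold = 0.05, fixed = NULL) {
  stopifnot(inherits(counts, "allele_count_table"),
            inherits(settings, "mcmc_settings"))
  a0 <- counts$a; n0 <- counts$n
  if (ncol(a0) < 2 || nrow(a0) < 2)
    stop("need >= 2 populations and >= 2 loci")
  poly <- rowSums(a0) > 0 & rowSums(a0) < rowSums(n0)
  n_mono <- sum(!poly)
  if (n_mono) message(n_mono, " monomorphic locus/loci excluded from scan")
  a <- a0[poly, , drop = FALSE]; n <- n0[poly, , drop = FALSE]
  ids <- counts$locus_ids[poly]
  nl <- nrow(a); np <- ncol(a)

  set.seed(settings$seed)
  fix_p <- !is.null(fixed$p)
  fix_beta <- !is.null(fixed$beta)
  always_in <- isTRUE(fixed$always_include)
  prior_in <- 1 / (1 + settings$prior_odds_neutral)

  p <- if (fix_p) rep_len(fixed$p, nl) else
    pmin(pmax(rowSums(a) / rowSums(n), 0.01), 0.99)
  beta <- if (fix_beta) rep_len(fixed$beta, np) else rep(-1, np)
  alpha <- rep(0, nl)
  delta <- rep(always_in, nl)
  lp <- stats::qlogis(p)

  sd_p <- rep(0.5, nl); sd_a <- rep(0.6, nl); sd_b <- rep(0.25, np)
  ll <- bb_loglik(a, n, alpha * delta, p, beta)

  run_block <- function(n_it, record = FALSE) {
    nrec <- if (record) (n_it %/% settings$thinning) else 0L
    rec_alpha <- if (record) matrix(0, nrec, nl) else NULL
    rec_delta <- if (record) matrix(FALSE, nrec, nl) else NULL
    rec_beta <- if (record) matrix(0, nrec, np) else NULL
    acc <- list(p = numeric(nl), a = numeric(nl), a_n = numeric(nl),
                b = numeric(np), rj = 0)
    ri <- 0L
    for (it in seq_len(n_it)) {
      if (!fix_p) {  # ancestral frequencies, logit random walk
        lp_new <- lp + rnorm(nl) * sd_p
        p_new <- pmin(pmax(stats::plogis(lp_new), 1e-12), 1 - 1e-12)
        ll_new <- bb_loglik(a, n, alpha * delta, p_new, beta)
        lr <- rowSums(ll_new - ll) +
          log(p_new * (1 - p_new)) - log(p * (1 - p))
        ok <- log(runif(nl)) < lr
        lp[ok] <- lp_new[ok]; p[ok] <- p_new[ok]
        ll[ok, ] <- ll_new[ok, ]
        acc$p <- acc$p + ok
      }
      inc <- which(delta)
      if (length(inc)) {  # alpha random walk for included loci
        an <- alpha
        an[inc] <- alpha[inc] + rnorm(length(inc)) * sd_a[inc]
        ll_new <- bb_loglik(a[inc, , drop = FALSE], n[inc, , drop = FALSE],
                            an[inc], p[inc], beta)
        lr <- rowSums(ll_new - ll[inc, , drop = FALSE]) +
          stats::dnorm(an[inc], 0, 1, log = TRUE) -
          stats::dnorm(alpha[inc], 0, 1, log = TRUE)
        ok <- log(runif(length(inc))) < lr
        alpha[inc[ok]] <- an[inc[ok]]
        ll[inc[ok], ] <- ll_new[ok, , drop = FALSE]
        acc$a[inc] <- acc$a[inc] + ok
        acc$a_n[inc] <- acc$a_n[inc] + 1
      }
      if (!always_in) {  # reversible-jump toggle, prior as proposal
        a_prop <- ifelse(delta, 0, rnorm(nl))
        ll_new <- bb_loglik(a, n, a_prop, p, beta)
        lr <- rowSums(ll_new - ll) +
          ifelse(delta, log(settings$prior_odds_neutral),
                 -log(settings$prior_odds_neutral))
        ok <- log(runif(nl)) < lr
        delta[ok] <- !delta[ok]
        alpha[ok] <- ifelse(delta[ok], a_prop[ok], 0)
        ll[ok, ] <- ll_new[ok, ]
        acc$rj <- acc$rj + mean(ok)
      }
      if (!fix_beta) {  # population effects, one column at a time
        for (j in seq_len(np)) {
          bn <- beta[j] + rnorm(1) * sd_b[j]
          th <- exp(-(alpha * delta + bn))
          s1 <- p * th; s2 <- (1 - p) * th
          llj <- lbeta(a[, j] + s1, n[, j] - a[, j] + s2) - lbeta(s1, s2)
          lr <- sum(llj - ll[, j]) +
            stats::dnorm(bn, -1, 1.8, log = TRUE) -
            stats::dnorm(beta[j], -1, 1.8, log = TRUE)
          if (log(runif(1)) < lr) {
            beta[j] <- bn
            ll[, j] <- llj
            acc$b[j] <- acc$b[j] + 1
          }
        }
      }
      if (record && it %% settings$thinning == 0L) {
        ri <- ri + 1L
        rec_alpha[ri, ] <- alpha * delta
        rec_delta[ri, ] <- delta
        rec_beta[ri, ] <- beta
      }
    }
    # write state back to the enclosing frame
    lp <<- lp; p <<- p; alpha <<- alpha; delta <<- delta; beta <<- beta
    ll <<- ll
    list(acc = acc, n_it = n_it, alpha = rec_alpha, delta = rec_delta,
         beta = rec_beta)
  }

  for (k in seq_len(settings$n_pilot)) {  # proposal tuning
    pb <- run_block(settings$pilot_length)
    tune <- function(sd, rate) {
      sd * ifelse(rate > 0.45, 1.3, ifelse(rate < 0.25, 1 / 1.3, 1))
    }
    sd_p <- tune(sd_p, pb$acc$p / settings$pilot_length)
    ar <- ifelse(pb$acc$a_n > 0, pb$acc$a / pmax(pb$acc$a_n, 1), 0.3)
    sd_a <- tune(sd_a, ar)
    sd_b <- tune(sd_b, pb$acc$b / settings$pilot_length)
  }
  run_block(settings$burn_in)
  main <- run_block(settings$n_iter - settings$burn_in, record = TRUE)

  rates <- c(p = mean(main$acc$p) / main$n_it,
             alpha = if (any(main$acc$a_n > 0))
               sum(main$acc$a) / sum(main$acc$a_n) else NA,
             beta = mean(main$acc$b) / main$n_it)
  flagged <- any(rates < 0.05, na.rm = TRUE)

  inclusion <- colMeans(main$delta)
  alpha_mean <- colMeans(main$alpha)
  alpha_sd <- apply(main$alpha, 2, sd)
  fst_post <- vapply(seq_len(nl), function(i) {
    mean(stats::plogis(matrix(main$alpha[, i], nrow(main$beta), np) +
                         main$beta))
  }, numeric(1))
  res <- data.frame(locus_id = ids, fst = fst_post,
                    alpha_mean = alpha_mean, alpha_sd = alpha_sd,
                    inclusion_prob = inclusion,
                    q_value = qvalues_from_posterior(inclusion),
                    stringsAsFactors = FALSE)
  res <- classify_outliers(res, q_threshold = q_threshold)
  list(results = res,
       beta = data.frame(pop = counts$pop_ids,
                         beta_mean = colMeans(main$beta),
                         beta_sd = apply(main$beta, 2, sd),
                         stringsAsFactors = FALSE),
       diagnostics = list(acceptance = rates, flagged = flagged,
                          settings = settings),
       n_monomorphic_excluded = n_mono)
}

#' q-values from posterior inclusion probabilities
#'
#' Loci are sorted by decreasing inclusion probability `P`; the q-value of a
#' locus is the mean of `1 - P` over all loci with inclusion probability at
#' least as large (the Bayesian FDR of calling everything down to that locus
#' an outlier).
#'
#' @param inclusion_probs Probabilities in `[0, 1]`.
#' @return q-values in the input order.
#' @export
qvalues_from_posterior <- function(inclusion_probs) {
  stopifnot(all(inclusion_probs >= 0 & inclusion_probs <= 1))
  ord <- order(inclusion_probs, decreasing = TRUE)
  q <- cumsum(1 - inclusion_probs[ord]) / seq_along(ord)
  out <- numeric(length(q))
  # ties share the q of the last tied locus
  q <- rev(cummin(rev(q)))  # enforce monotonicity in P-rank
  for (v in unique(inclusion_probs[ord]))
    out[inclusion_probs == v] <- max(q[inclusion_probs[ord] == v])
  out
}

#' Classify outlier loci by q-value and alpha sign
#'
#' `q < q_threshold` with positive posterior mean alpha is diversifying
#' selection, with negative alpha balancing selection; everything else is
#' neutral.
#'
#' @param results data.frame with `q_value` and `alpha_mean` columns.
#' @param q_threshold Outlier q-value threshold (default 0.05).
#' @return `results` with a `selection_class` column.
#' @export
classify_outliers <- function(results, q_threshold = 0.05) {
  cls <- rep("neutral", nrow(results))
  sel <- results$q_value < q_threshold
  zero <- sel & results$alpha_mean == 0
  if (any(zero)) warning("outlier with alpha_mean exactly 0 left neutral")
  cls[sel & results$alpha_mean > 0] <- "diversifying"
  cls[sel & results$alpha_mean < 0] <- "balancing"
  results$selection_class <- cls
  results
}

#' Consistency of outliers across independent analyses
#'
#' Intersects the outlier sets of a global scan and local (per-transect)
#' scans: a locus is consistent when it is a non-neutral outlier in every
#' analysis; class agreement across analyses is reported.
#'
#' @param global `results` data.frame of the global [bayescan_scan()].
#' @param locals Named list of `results` data.frames of the local scans.
#' @return data.frame with `locus_id`, one class column per analysis, and
#'   `class_agreement`.
#' @export
transect_consistency <- function(global, locals) {
  analyses <- c(list(global = global), locals)
  if (is.null(names(analyses)) || any(!nzchar(names(analyses))))
    names(analyses) <- c("global", paste0("local", seq_along(locals)))
  out_sets <- lapply(analyses, function(r)
    r$locus_id[r$selection_class != "neutral"])
  consistent <- Reduce(intersect, out_sets)
  if (!length(consistent))
    return(data.frame(locus_id = character(), class_agreement = logical(),
                      stringsAsFactors = FALSE))
  cls <- sapply(analyses, function(r)
    r$selection_class[match(consistent, r$locus_id)])
  cls <- matrix(cls, nrow = length(consistent),
                dimnames = list(NULL, paste0("class_", names(analyses))))
  data.frame(locus_id = consistent, cls,
             class_agreement = apply(cls, 1, function(x) length(unique(x)) == 1),
             stringsAsFactors = FALSE)
}
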