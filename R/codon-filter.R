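# NG86 bookkeeping: per-codon synonymous site fractions and pathway-averaged
# difference counts. Changes that create a stop codon count as nonsynonymous;
# mutation pathways passing through a stop codon are excluded from averaging
# (all pathways blocked: fall back to including them).
.ng_env <- new.env(parent = emptyenv())

ng_syn_sites <- function() {
  if (!is.null(.ng_env$sites)) return(.ng_env$sites)
  s <- .code$sense
  out <- numeric(61)
  for (i in seq_len(61)) {
    syn <- 0
    for (pos in 1:3) {
      for (nt in setdiff(.nucs, substring(s[i], pos, pos))) {
        mut <- s[i]
        substring(mut, pos, pos) <- nt
        if (!(mut %in% .code$stops) && codon_aa(mut) == codon_aa(s[i]))
          syn <- syn + 1
      }
    }
    out[i] <- syn / 3
  }
  .ng_env$sites <- setNames(out, s)
  .ng_env$sites
}

# average (syn, nonsyn) differences between two codons over all mutation
# orders; returns c(syn, nonsyn)
ng_diffs <- function(ca, cb) {
  if (ca == cb) return(c(0, 0))
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  perms <- switch(length(pos), matrix(1), rbind(1:2, 2:1), .perm3)
  paths <- lapply(seq_len(nrow(perms)), function(k) pos[perms[k, ]])
  acc <- matrix(NA_real_, length(paths), 2)
  for (k in seq_along(paths)) {
    cur <- ca; sy <- 0; ns <- 0; valid <- TRUE
    for (p in paths[[k]]) {
      nxt <- cur
      substring(nxt, p, p) <- substring(cb, p, p)
      if (nxt %in% .code$stops) { valid <- FALSE; break }
      if (codon_aa(nxt) == codon_aa(cur)) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    if (valid) acc[k, ] <- c(sy, ns)
  }
  ok <- !is.na(acc[, 1])
  if (!any(ok)) {  # every pathway passes through a stop: count ignoring stops
    for (k in seq_along(paths)) {
      cur <- ca; sy <- 0; ns <- 0
      for (p in paths[[k]]) {
        nxt <- cur
        substring(nxt, p, p) <- substring(cb, p, p)
        if (nxt %in% .code$stops || codon_aa(nxt) != codon_aa(cur))
          ns <- ns + 1 else sy <- sy + 1
        cur <- nxt
      }
      acc[k, ] <- c(sy, ns)
    }
    ok <- rep(TRUE, length(paths))
  }
  colMeans(acc[ok, , drop = FALSE])
}

# all 3! mutation orders (codon differences span at most 3 positions)
.perm3 <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))

#' Pairwise NG86 estimates of dN and dS
#'
#' Nei-Gojobori (1986) counting with Jukes-Cantor correction. Synonymous
#' site fractions count mutations to stop codons as nonsynonymous;
#' multi-position codon differences are averaged over mutation pathways,
#' excluding pathways through stop codons. Columns where either sequence has
#' a gap, ambiguity or stop are skipped. `dS` (or `dN`) is `Inf` when the
#' corresponding proportion of differences reaches 3/4, where the correction
#' is undefined (synonymous saturation).
#'
#' @param row_a,row_b Equal-length codon sequences: character vectors of
#'   3-mers or single nucleotide strings.
#' @return List with `dN`, `dS`, `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`, `n_codons_compared`.
#' @export
ng86_pairwise <- function(row_a, row_b) {
  to_codons <- function(x) {
    if (length(x) == 1L && nchar(x) > 3) {
      starts <- seq(1L, nchar(x), by = 3L)
      substring(x, starts, starts + 2L)
    } else as.character(x)
  }
  a <- to_codons(row_a); b <- to_codons(row_b)
  if (length(a) != length(b)) stop("sequences must have equal codon length")
  keep <- a %in% .code$sense & b %in% .code$sense
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop("zero comparable codons")
  sites <- ng_syn_sites()
  S <- sum((sites[a] + sites[b]) / 2)
  N <- 3 * length(a) - S
  diff <- vapply(seq_along(a), function(i) ng_diffs(a[i], b[i]), numeric(2))
  Sd <- sum(diff[1, ]); Nd <- sum(diff[2, ])
  jc <- function(p) {
    if (p >= 3 / 4) return(Inf)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  list(dN = if (N > 0) jc(Nd / N) else 0,
       dS = if (S > 0) jc(Sd / S) else 0,
       syn_sites = unname(S), nonsyn_sites = unname(N),
       syn_diffs = Sd, nonsyn_diffs = Nd, n_codons_compared = length(a))
}

has_internal_stop <- function(aln) {
  nc <- ncol(aln$codons)
  if (nc < 2) return(FALSE)
  any(aln$codons[, -nc, drop = FALSE] %in% .code$stops)
}

#' Validate a codon alignment
#'
#' Flags `internal_stop` when any row contains a stop codon before the final
#' column, and `too_short` when the nucleotide length is below `min_len_nt`.
#'
#' @param aln A [codon_alignment()].
#' @param min_len_nt Minimum alignment length in nucleotides (default 200).
#' @return Character vector of flags (empty when clean).
#' @export
validate_codon_alignment <- function(aln, min_len_nt = 200) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!is.matrix(aln$codons) || any(nchar(aln$codons) != 3L))
    stop("structural error: malformed codon matrix")
  flags <- character(0)
  if (has_internal_stop(aln)) flags <- c(flags, "internal_stop")
  if (3L * ncol(aln$codons) < min_len_nt) flags <- c(flags, "too_short")
  flags
}

#' Trim unreliable codon columns
#'
#' Removes whole codon columns whose gap-or-N fraction exceeds
#' `max_gap_fraction` (default 0: any column containing a gap or ambiguity
#' is dropped). Column order is preserved; trimming is idempotent.
#'
#' @param aln A [codon_alignment()].
#' @param max_gap_fraction Maximum tolerated fraction of rows with a gap or
#'   N in a column.
#' @return The trimmed [codon_alignment()].
#' @export
trim_alignment <- function(aln, max_gap_fraction = 0) {
  stopifnot(inherits(aln, "codon_alignment"))
  gapish <- matrix(grepl("[-N]", aln$codons), nrow = nrow(aln$codons))
  keep <- colMeans(gapish) <= max_gap_fraction
  if (!any(keep)) stop("all columns removed by trimming")
  codon_alignment(aln$codons[, keep, drop = FALSE], gene_id = aln$gene_id)
}

#' Synonymous-saturation filter
#'
#' Flags an alignment as saturated when any pairwise NG86 `dS` is infinite
#' (proportion of synonymous differences >= 3/4, where the Jukes-Cantor
#' correction is undefined) or exceeds `ds_cap`.
#'
#' @param aln A [codon_alignment()] with >= 2 rows.
#' @param ds_cap Maximum tolerated pairwise dS (default 3).
#' @return `"saturated"` or an empty character vector.
#' @export
saturation_filter <- function(aln, ds_cap = 3.0) {
  stopifnot(inherits(aln, "codon_alignment"), nrow(aln$codons) >= 2)
  nr <- nrow(aln$codons)
  for (i in seq_len(nr - 1)) {
    for (j in (i + 1):nr) {
      ds <- tryCatch(
        ng86_pairwise(aln$codons[i, ], aln$codons[j, ])$dS,
        error = function(e) NA_real_)
      if (!is.na(ds) && (is.infinite(ds) || ds > ds_cap))
        return("saturated")
    }
  }
  character(0)
}

#' Filter a set of ortholog alignments
#'
#' Applies [validate_codon_alignment()], [trim_alignment()] and
#' [saturation_filter()] in that order; a gene is retained iff no flags were
#' raised. Alignments whose trimming removes every column are flagged
#' `excess_gaps`.
#'
#' @param alignments List of [codon_alignment()]s.
#' @param min_len_nt,max_gap_fraction,ds_cap Stage thresholds.
#' @return List with `retained` (named list of trimmed alignments) and
#'   `reports` (data.frame `gene_id`, `retained`, `reasons`).
#' @export
filter_orthologs <- function(alignments, min_len_nt = 200,
                             max_gap_fraction = 0, ds_cap = 3.0) {
  if (!length(alignments)) {
    warning("no alignments to filter")
    return(list(retained = list(),
                reports = data.frame(gene_id = character(),
                                     retained = logical(),
                                     reasons = character(),
                                     stringsAsFactors = FALSE)))
  }
  retained <- list()
  reports <- vector("list", length(alignments))
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    flags <- validate_codon_alignment(aln, min_len_nt = min_len_nt)
    trimmed <- tryCatch(trim_alignment(aln, max_gap_fraction),
                        error = function(e) NULL)
    if (is.null(trimmed)) {
      flags <- c(flags, "excess_gaps")
    } else {
      flags <- c(flags, saturation_filter(trimmed, ds_cap = ds_cap))
    }
    ok <- !length(flags)
    if (ok) retained[[aln$gene_id]] <- trimmed
    reports[[k]] <- data.frame(gene_id = aln$gene_id, retained = ok,
                               reasons = paste(flags, collapse = ","),
                               stringsAsFactors = FALSE)
  }
  list(retained = retained, reports = do.call(rbind, reports))
}
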