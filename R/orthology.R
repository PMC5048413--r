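#' Six-frame translation
#'
#' Translates a nucleotide sequence in frames +1..+3 and, after reverse
#' complementing, -1..-3. Trailing partial codons are dropped; ambiguous
#' codons translate to `X` and stops to `*`.
#'
#' @param sequence Single nucleotide string over \{A,C,G,T,N\}.
#' @return Named character vector of up to six peptides
#'   (`"+1".."+3"`, `"-1".."-3"`); frames shorter than one codon are empty
#'   strings.
#' @export
six_frame_translate <- function(sequence) {
  if (length(sequence) != 1L || !nzchar(sequence)) stop("empty sequence")
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) stop("sequence must be over {A,C,G,T,N}")
  fwd <- Biostrings::DNAString(sequence)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(x, off) {
    n <- length(x) - off
    if (n < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(x, off + 1L, off + 3L * (n %/% 3L)),
      if.fuzzy.codon = "X"))
  }
  out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  setNames(out, c("+1", "+2", "+3", "-1", "-2", "-3"))
}

#' Best local alignment score (Smith-Waterman, affine gaps)
#'
#' @param peptide_a,peptide_b Nonempty peptide strings.
#' @param substitution_matrix Square scoring matrix with residue dimnames;
#'   default BLOSUM62.
#' @param gap_open,gap_extend Positive penalties: a gap of length k costs
#'   `gap_open + k * gap_extend` (BLAST convention; defaults 11/1).
#' @return Best local alignment score (>= 0).
#' @export
local_align_score <- function(peptide_a, peptide_b,
                              substitution_matrix = NULL,
                              gap_open = 11, gap_extend = 1) {
  if (!nzchar(peptide_a) || !nzchar(peptide_b)) stop("empty peptide")
  if (is.null(substitution_matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    substitution_matrix <- e$BLOSUM62
  }
  resid <- unique(strsplit(paste0(peptide_a, peptide_b), "")[[1]])
  unknown <- setdiff(resid, rownames(substitution_matrix))
  if (length(unknown))
    stop("residue(s) not in substitution matrix: ",
         paste(unknown, collapse = ", "))
  max(0, Biostrings::pairwiseAlignment(
    Biostrings::AAString(peptide_a), Biostrings::AAString(peptide_b),
    type = "local", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

#' Translated all-vs-all hit table for small transcript sets
#'
#' A desk-scale stand-in for a translated BLAST search: every query/subject
#' pair is scored by the best Smith-Waterman local score over all 36
#' six-frame peptide combinations, and an e-value is attached from the
#' Karlin-Altschul formula with gapped BLOSUM62 constants
#' (lambda = 0.267, K = 0.041). Intended for fixtures and bundled pipeline
#' runs; production-scale searches should import an external BLAST tabular
#' file via [read_blast_tab()].
#'
#' @param queries,subjects Named character vectors of nucleotide sequences.
#' @return data.frame with columns `qseqid`, `sseqid`, `bitscore`, `evalue`.
#' @export
translated_hit_table <- function(queries, subjects) {
  lambda <- 0.267; K <- 0.041
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  mat <- e$BLOSUM62
  frames <- function(seqs) lapply(seqs, function(s) {
    f <- six_frame_translate(s)
    Biostrings::AAStringSet(f[nzchar(f)])
  })
  qf <- frames(queries); sf <- frames(subjects)
  rows <- vector("list", length(queries) * length(subjects))
  r <- 0L
  for (q in names(queries)) {
    for (s in names(subjects)) {
      sc <- 0
      for (b in seq_along(sf[[s]])) {
        sc <- max(sc, Biostrings::pairwiseAlignment(
          qf[[q]], sf[[s]][[b]], type = "local",
          substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
          scoreOnly = TRUE))
      }
      sc <- max(0, sc)
      bit <- (lambda * sc - log(K)) / log(2)
      ev <- nchar(queries[[q]]) * nchar(subjects[[s]]) * 2^(-bit)
      r <- r + 1L
      rows[[r]] <- data.frame(qseqid = q, sseqid = s, bitscore = bit,
                              evalue = ev, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Read a BLAST tabular (outfmt 6) hit table
#'
#' Only `qseqid`, `sseqid`, `bitscore` and `evalue` are consumed; the file
#' may have the full 12 columns or just those four.
#'
#' @param path TSV path.
#' @return data.frame with columns `qseqid`, `sseqid`, `bitscore`, `evalue`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  bad <- which(nfld != 12L & nfld != 4L)
  if (length(bad))
    stop(sprintf("malformed hit table row at line %d: expected 4 or 12 fields, got %d",
                 bad[1], nfld[bad[1]]))
  ev_col <- ifelse(nfld == 12L, 11L, 4L)
  bit_col <- ifelse(nfld == 12L, 12L, 3L)
  df <- data.frame(
    qseqid = vapply(parts, `[[`, "", 1L),
    sseqid = vapply(parts, `[[`, "", 2L),
    bitscore = as.numeric(mapply(function(p, k) p[[k]], parts, bit_col)),
    evalue = as.numeric(mapply(function(p, k) p[[k]], parts, ev_col)),
    stringsAsFactors = FALSE)
  if (anyNA(df$bitscore) || anyNA(df$evalue)) {
    bad <- which(is.na(df$bitscore) | is.na(df$evalue))[1]
    stop(sprintf("malformed hit table row at line %d: non-numeric score", bad))
  }
  df
}

# best hit per query: highest bit score, ties by lowest e-value, then
# lexicographic subject id (deterministic); flags whether a tie was broken
best_hits <- function(hits) {
  ord <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$qseqid)
  best <- h[first, , drop = FALSE]
  nxt <- h[which(first) + 1L, , drop = FALSE]
  tie <- !is.na(nxt$qseqid) & nxt$qseqid == best$qseqid &
    nxt$bitscore == best$bitscore & nxt$evalue == best$evalue
  best$tie <- tie & !is.na(tie)
  best
}

#' Best reciprocal hits (one-to-one ortholog inference)
#'
#' A pair `(a, b)` is returned iff `b` is `a`'s best subject in `hits_ab`,
#' `a` is `b`'s best subject in `hits_ba`, and both supporting e-values are
#' at or below `e_threshold`. "Best" means highest bit score, with ties
#' broken by lowest e-value then lexicographic subject id; pairs whose best
#' hit required a tie-break are flagged in the `tie` column.
#'
#' @param hits_ab,hits_ba Hit tables (data.frames with `qseqid`, `sseqid`,
#'   `bitscore`, `evalue`) for the two search directions.
#' @param e_threshold Maximum e-value for both directions (default 1e-10).
#' @return data.frame with columns `id_a`, `id_b`, `evalue_ab`, `evalue_ba`,
#'   `bitscore_ab`, `bitscore_ba`, `tie`.
#' @export
best_reciprocal_hits <- function(hits_ab, hits_ba, e_threshold = 1e-10) {
  need <- c("qseqid", "sseqid", "bitscore", "evalue")
  if (!all(need %in% names(hits_ab)) || !all(need %in% names(hits_ba)))
    stop("hit tables need columns qseqid, sseqid, bitscore, evalue")
  empty <- data.frame(id_a = character(), id_b = character(),
                      evalue_ab = numeric(), evalue_ba = numeric(),
                      bitscore_ab = numeric(), bitscore_ba = numeric(),
                      tie = logical(), stringsAsFactors = FALSE)
  if (!nrow(hits_ab) || !nrow(hits_ba)) return(empty)
  ab <- best_hits(hits_ab)
  ba <- best_hits(hits_ba)
  m <- match(ab$sseqid, ba$qseqid)
  ok <- !is.na(m) & ba$sseqid[m] == ab$qseqid &
    ab$evalue <= e_threshold & ba$evalue[m] <= e_threshold
  if (!any(ok)) return(empty)
  out <- data.frame(id_a = ab$qseqid[ok], id_b = ab$sseqid[ok],
                    evalue_ab = ab$evalue[ok], evalue_ba = ba$evalue[m][ok],
                    bitscore_ab = ab$bitscore[ok],
                    bitscore_ba = ba$bitscore[m][ok],
                    tie = ab$tie[ok] | ba$tie[m][ok],
                    stringsAsFactors = FALSE)
  out[order(out$id_a), , drop = FALSE]
}

#' Assembly summary statistics
#'
#' N50 is the length of the shortest transcript in the minimal set of
#' longest transcripts whose combined length covers at least half the total.
#'
#' @param transcript_lengths Nonempty vector of transcript lengths.
#' @return List with `n_transcripts`, `n50`, `mean_length`.
#' @export
assembly_stats <- function(transcript_lengths) {
  if (!length(transcript_lengths)) stop("empty length list")
  len <- sort(as.numeric(transcript_lengths), decreasing = TRUE)
  n50 <- len[which(cumsum(len) >= sum(len) / 2)[1]]
  list(n_transcripts = length(len), n50 = n50, mean_length = mean(len))
}
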