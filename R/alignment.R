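#' Construct a codon alignment
#'
#' The unit of all selection tests: a taxa-by-codon-columns matrix of 3-mers
#' over \{A,C,G,T,-,N\}. Rows must be equal length and the nucleotide length
#' divisible by three.
#'
#' @param sequences Named character vector of nucleotide sequences (equal
#'   length, length divisible by 3), or a character matrix of codons
#'   (taxa x columns) with rownames.
#' @param gene_id Identifier carried through filtering and testing.
#' @return An object of class `codon_alignment` with elements `taxon_ids`,
#'   `codons` (character matrix, rows = taxa) and `gene_id`.
#' @export
codon_alignment <- function(sequences, gene_id = "gene") {
  if (is.matrix(sequences)) {
    cod <- sequences
    if (is.null(rownames(cod))) stop("codon matrix must have rownames")
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named")
    nc <- unique(nchar(sequences))
    if (length(nc) != 1L)
      stop("all rows must have equal length")
    if (nc %% 3L != 0L)
      stop("nucleotide length must be divisible by 3")
    starts <- seq(1L, nc, by = 3L)
    cod <- t(vapply(sequences, function(s) substring(s, starts, starts + 2L),
                    character(length(starts))))
    if (nc == 3L) cod <- matrix(cod, nrow = length(sequences),
                                dimnames = list(names(sequences), NULL))
    rownames(cod) <- names(sequences)
  }
  bad <- !grepl("^[ACGTN-]{3}$", cod)
  if (any(bad)) stop("invalid codon(s): ", paste(unique(cod[bad]), collapse = ", "))
  structure(list(taxon_ids = rownames(cod), codons = cod, gene_id = gene_id),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment '%s': %d taxa x %d codons (%d nt)\n",
              x$gene_id, nrow(x$codons), ncol(x$codons), 3L * ncol(x$codons)))
  invisible(x)
}

#' @export
dim.codon_alignment <- function(x) dim(x$codons)

#' Nucleotide sequences of a codon alignment
#' @param aln A [codon_alignment()].
#' @return Named character vector of concatenated nucleotide sequences.
#' @export
alignment_sequences <- function(aln) {
  setNames(apply(aln$codons, 1L, paste0, collapse = ""), aln$taxon_ids)
}

#' Read / write codon alignments as FASTA
#'
#' @param path File path.
#' @param gene_id Gene id to attach on read (defaults to the file stem).
#' @return `read_codon_fasta()` returns a [codon_alignment()];
#'   `write_codon_fasta()` returns `path` invisibly.
#' @export
read_codon_fasta <- function(path, gene_id = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (is.null(gene_id)) gene_id <- sub("\\.[^.]*$", "", basename(path))
  codon_alignment(setNames(toupper(as.character(seqs)),
                           sub("\\s.*$", "", names(seqs))), gene_id = gene_id)
}

#' @rdname read_codon_fasta
#' @param aln Alignment to write.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- alignment_sequences(aln)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con)
  invisible(path)
}

# Collapse alignment columns to site patterns for the likelihood kernel.
# Returns an integer matrix (ntaxa x npattern, 1..61, NA = missing),
# pattern weights, and the pattern index of every original column.
compress_patterns <- function(aln) {
  idx <- matrix(codon_to_index(aln$codons), nrow = nrow(aln$codons),
                dimnames = list(aln$taxon_ids, NULL))
  key <- apply(idx, 2L, paste0, collapse = "_")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(states = idx[, first, drop = FALSE],
       weights = as.numeric(tabulate(map, sum(first))),
       column_pattern = map)
}
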