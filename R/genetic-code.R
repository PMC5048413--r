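#' @importFrom stats optimize pchisq phyper p.adjust rbeta rbinom rpois runif
#'   rnorm rmultinom setNames dbinom fisher.test sd quantile
#' @importFrom utils read.table write.table head
NULL

# Standard genetic code over the 61 sense codons, in lexicographic order
# (A < C < G < T). Stop codons (TAA, TAG, TGA) are excluded everywhere:
# they have frequency zero and are never emitted by the simulator.
.nucs <- c("A", "C", "G", "T")

.all_codons <- as.vector(outer(outer(.nucs, .nucs, paste0), .nucs,
                               function(ab, c) paste0(rep(ab, length(c) / length(ab)), c)))

.make_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  aa <- gc[codons]
  list(codons = codons, aa = aa,
       sense = codons[aa != "*"], stops = codons[aa == "*"])
}
.code <- .make_code()

#' The 61 sense codons of the universal genetic code
#'
#' Codons are in lexicographic order (A < C < G < T); this ordering indexes
#' every 61-vector and 61 x 61 matrix in the package (codon frequencies,
#' rate matrices, transition probabilities).
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .code$sense

#' Translate a codon string under the universal code
#' @param codon Character vector of 3-mers over A,C,G,T.
#' @return Amino-acid letters; `"*"` for stops, `"X"` if ambiguous.
#' @export
codon_aa <- function(codon) {
  out <- unname(.code$aa[codon])
  out[is.na(out)] <- "X"
  out
}

.codon_index <- setNames(seq_along(.code$sense), .code$sense)

# Map codon strings to 1..61 indices; anything unresolvable (gap, N, stop)
# becomes NA and is treated as missing data by the likelihood machinery.
codon_to_index <- function(codons) {
  unname(.codon_index[codons])
}

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Precompute the single-nucleotide-difference structure of the 61 x 61
# codon space: for each ordered pair differing at exactly one position,
# record indices and the substitution type.
.make_pair_structure <- function() {
  s <- .code$sense
  n <- length(s)
  m1 <- substring(s, 1, 1); m2 <- substring(s, 2, 2); m3 <- substring(s, 3, 3)
  aa <- .code$aa[s]
  ii <- integer(0); jj <- integer(0); ts <- logical(0); syn <- logical(0)
  for (pos in 1:3) {
    px <- switch(pos, m1, m2, m3)
    other1 <- switch(pos, m2, m1, m1)
    other2 <- switch(pos, m3, m3, m2)
    for (i in seq_len(n)) {
      same <- which(other1 == other1[i] & other2 == other2[i] & px != px[i])
      if (length(same)) {
        ii <- c(ii, rep.int(i, length(same)))
        jj <- c(jj, same)
        ts <- c(ts, .is_transition(px[i], px[same]))
        syn <- c(syn, aa[i] == aa[same])
      }
    }
  }
  list(i = ii, j = jj, transition = ts, synonymous = syn)
}
.pairs <- .make_pair_structure()

#' Empirical codon frequencies by the F3x4 method
#'
#' Computes position-specific nucleotide frequencies from a codon alignment
#' and forms codon frequencies as their product, restricted to the 61 sense
#' codons and renormalized. Gap and ambiguous characters are ignored.
#'
#' @param aln A [codon_alignment()].
#' @param pseudo Small count added to every nucleotide at every position so
#'   that no observed codon gets zero frequency.
#' @return Numeric 61-vector summing to 1, named by codon.
#' @export
f3x4_frequencies <- function(aln, pseudo = 0.5) {
  stopifnot(inherits(aln, "codon_alignment"))
  cod <- aln$codons
  freq <- matrix(pseudo, 3, 4, dimnames = list(NULL, .nucs))
  for (pos in 1:3) {
    ch <- substring(cod, pos, pos)
    tab <- table(factor(ch[ch %in% .nucs], levels = .nucs))
    freq[pos, ] <- freq[pos, ] + as.numeric(tab)
  }
  freq <- freq / rowSums(freq)
  s <- .code$sense
  pi <- freq[1, substring(s, 1, 1)] * freq[2, substring(s, 2, 2)] *
    freq[3, substring(s, 3, 3)]
  pi <- pi / sum(pi)
  setNames(pi, s)
}
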