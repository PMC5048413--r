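#' Call SNPs from per-site read counts
#'
#' A site is a SNP iff at least two alleles are observed and the rarer of the
#' two most-covered alleles has coverage strictly greater than
#' `min_rare_coverage` (default 20, so 20 observations of the rare allele do
#' not qualify but 21 do). Only base counts are considered; indel evidence
#' is ignored. Sites with a third observed allele are kept with their top two
#' alleles and flagged tri-allelic.
#'
#' @param sites data.frame with columns `gene_id`, `position`, `A`, `C`,
#'   `G`, `T` (e.g. from [simulate_read_counts()] or a pileup-derived TSV).
#' @param min_rare_coverage Coverage the rare allele must exceed.
#' @return data.frame with `gene_id`, `position`, `ref_allele`,
#'   `alt_allele`, `rare_allele_coverage`, `major_allele_coverage`,
#'   `tri_allelic`; zero rows when nothing passes.
#' @export
call_snps <- function(sites, min_rare_coverage = 20) {
  stopifnot(all(c("gene_id", "position", "A", "C", "G", "T") %in%
                  names(sites)))
  cnt <- as.matrix(sites[, c("A", "C", "G", "T")])
  storage.mode(cnt) <- "numeric"
  if (any(cnt < 0)) stop("negative counts")
  rows <- lapply(seq_len(nrow(cnt)), function(i) {
    x <- sort(cnt[i, ], decreasing = TRUE)
    if (sum(x > 0) < 2) return(NULL)
    rare <- x[2]
    if (!(rare > min_rare_coverage)) return(NULL)
    data.frame(gene_id = sites$gene_id[i], position = sites$position[i],
               ref_allele = names(x)[1], alt_allele = names(x)[2],
               rare_allele_coverage = unname(rare),
               major_allele_coverage = unname(x[1]),
               tri_allelic = sum(x > 0) > 2,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(gene_id = character(), position = integer(),
                      ref_allele = character(), alt_allele = character(),
                      rare_allele_coverage = numeric(),
                      major_allele_coverage = numeric(),
                      tri_allelic = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Select tag SNPs per gene
#'
#' Ranks each gene's called SNPs by rare-allele coverage (descending; ties by
#' ascending position) and keeps at most `max_per_gene` per gene. Genes with
#' no SNPs are omitted.
#'
#' @param snps data.frame from [call_snps()].
#' @param max_per_gene Maximum tags per gene (default 2).
#' @return data.frame of selected tag SNPs (same columns as `snps`), ordered
#'   by gene and rank.
#' @export
select_tag_snps <- function(snps, max_per_gene = 2) {
  stopifnot(max_per_gene >= 1)
  if (!nrow(snps)) return(snps)
  ord <- order(snps$gene_id, -snps$rare_allele_coverage, snps$position)
  s <- snps[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(s)), s$gene_id), function(ix)
    ix[seq_len(min(max_per_gene, length(ix)))]), use.names = FALSE)
  out <- s[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tag SNPs as a minimal VCF
#'
#' CHROM is the gene id, POS the 1-based transcript position; REF/ALT are
#' the major/rare alleles.
#'
#' @param tags data.frame from [select_tag_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_snp_vcf <- function(tags, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(tags)) {
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tRC=%d",
                       tags$gene_id, as.integer(tags$position),
                       paste0(tags$gene_id, "_", tags$position),
                       tags$ref_allele, tags$alt_allele,
                       as.integer(tags$rare_allele_coverage)), con)
  }
  invisible(path)
}
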