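# simple FNV-1a hash for provenance headers (no external digest dependency)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "")) %% 256
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on the low byte only (bitwXor cannot take doubles >= 2^31), and
    # split the multiply so intermediates stay within exact double range
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    h <- ((h %% 65536) * p + ((h %/% 65536) * p %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

write_stage_tsv <- function(df, path, config_hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# altiscan %s | config_hash=%s | seed=%d",
                     as.character(utils::packageVersion("altiscan")),
                     config_hash, seed), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Subset an allele count table by population
#' @param counts An [allele_count_table()].
#' @param pops Population ids to keep.
#' @return An [allele_count_table()] over `pops`.
#' @export
subset_populations <- function(counts, pops) {
  stopifnot(all(pops %in% counts$pop_ids))
  allele_count_table(counts$a[, pops, drop = FALSE],
                     counts$n[, pops, drop = FALSE],
                     counts$locus_ids, pops)
}

#' Pipeline configuration
#'
#' Collects thresholds (defaults follow the standard settings of this kind
#' of study: e-value 1e-10, minimum alignment length 200 nt, dS cap 3, PSG
#' p < 0.05, outlier q < 0.05, rare-allele coverage > 20), run sizes, MCMC
#' settings and the global seed. With no explicit inputs the pipeline runs
#' on the bundled synthetic study: simulated codon orthologs with planted
#' positively selected genes and an island-model SNP panel with planted
#' outlier loci.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; every stage derives its randomness from it.
#' @param e_value,min_len_nt,max_gap_fraction,ds_cap,p_psg,q_outlier,min_rare_coverage
#'   Stage thresholds.
#' @param n_bootstrap Bootstrap replicates for branch-rate distributions.
#' @param mcmc An [mcmc_settings()] (the default here is a short chain sized
#'   for the bundled synthetic study).
#' @param synthetic List controlling the synthetic study: `n_genes`,
#'   `n_codons`, `n_psg` (planted positive-selection genes), `omega2`
#'   (planted foreground omega), `n_loci`, `n_outlier` (planted diversifying
#'   loci), `alpha` (planted effect), `run_orthology` (logical).
#' @param alignments Optional named list of [codon_alignment()]s to analyse
#'   instead of simulating.
#' @param counts Optional [allele_count_table()] for the outlier scan.
#' @param annotation Optional data.frame (`gene_id`, `category_id`).
#' @param tree Phylogeny (default [example_phylogeny()]).
#' @param foreground Foreground branch id for the branch-site test.
#' @param compare_branches Length-2 character vector (high, low) for the
#'   bootstrap rate comparison.
#' @param transects Named list of population-id vectors for local outlier
#'   scans.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1,
                            e_value = 1e-10, min_len_nt = 200,
                            max_gap_fraction = 0, ds_cap = 3.0,
                            p_psg = 0.05, q_outlier = 0.05,
                            min_rare_coverage = 20, n_bootstrap = 30,
                            mcmc = mcmc_settings(n_iter = 7000,
                                                 burn_in = 5000,
                                                 thinning = 1, n_pilot = 4,
                                                 pilot_length = 500),
                            synthetic = list(), alignments = NULL,
                            counts = NULL, annotation = NULL,
                            tree = example_phylogeny(),
                            foreground = "bufo_high",
                            compare_branches = c("bufo_high", "bufo_low"),
                            transects = list(
                              minshan = c("pop1", "pop2", "pop3"),
                              daxueshan = c("pop4", "pop5"))) {
  syn_def <- list(n_genes = 10, n_codons = 150, n_psg = 2, omega2 = 20,
                  omega_background = 0.2, n_loci = 60, n_outlier = 3,
                  alpha = 4, run_orthology = TRUE)
  syn_def[names(synthetic)] <- synthetic
  stopifnot(e_value > 0, min_len_nt >= 0, ds_cap > 0,
            p_psg > 0, p_psg < 1, q_outlier > 0, q_outlier < 1,
            min_rare_coverage >= 0, n_bootstrap >= 1,
            inherits(mcmc, "mcmc_settings"))
  structure(list(outdir = outdir, seed = as.integer(seed),
                 e_value = e_value, min_len_nt = min_len_nt,
                 max_gap_fraction = max_gap_fraction, ds_cap = ds_cap,
                 p_psg = p_psg, q_outlier = q_outlier,
                 min_rare_coverage = min_rare_coverage,
                 n_bootstrap = n_bootstrap, mcmc = mcmc,
                 synthetic = syn_def, alignments = alignments,
                 counts = counts, annotation = annotation, tree = tree,
                 foreground = foreground,
                 compare_branches = compare_branches,
                 transects = transects),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] plus the `synthetic` block may be
#' set; unknown keys are an error.
#'
#' @param path YAML file.
#' @param outdir Output directory (overrides any `outdir` key).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  known <- c("outdir", "seed", "e_value", "min_len_nt", "max_gap_fraction",
             "ds_cap", "p_psg", "q_outlier", "min_rare_coverage",
             "n_bootstrap", "synthetic", "foreground", "compare_branches",
             "transects", "mcmc", "tree")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(y$mcmc)) y$mcmc <- do.call(mcmc_settings, y$mcmc)
  if (!is.null(y$tree)) y$tree <- ape::read.tree(text = y$tree)
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(pipeline_config, y)
}

# generate the synthetic gene set for a pipeline run: planted PSGs first,
# then background genes evolving under a shared-omega branch model
synthetic_gene_set <- function(config) {
  syn <- config$synthetic
  set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max - 1L, syn$n_genes)
  alns <- vector("list", syn$n_genes)
  truth <- logical(syn$n_genes)
  for (g in seq_len(syn$n_genes)) {
    planted <- g <= syn$n_psg
    params <- if (planted) {
      seq_sim_params(config$tree,
                     site_mix = site_class_mix(0.5, 0.3, 0.1, syn$omega2),
                     foreground = config$foreground,
                     n_codons = syn$n_codons, seed = gene_seeds[g])
    } else {
      seq_sim_params(config$tree, omega_map = syn$omega_background,
                     n_codons = syn$n_codons, seed = gene_seeds[g])
    }
    alns[[g]] <- simulate_codon_alignment(params,
                                          gene_id = sprintf("gene_%02d", g))
    truth[g] <- planted
  }
  names(alns) <- vapply(alns, function(a) a$gene_id, character(1))
  list(alignments = alns, is_psg_truth = truth)
}

#' Run the full selection-scan pipeline
#'
#' Executes orthology (on synthetic transcript sets, when enabled), codon
#' alignment filtering, the branch-site positive-selection scan, bootstrap
#' branch-rate comparison, category rates and enrichment, SNP tagging, and
#' the F_ST outlier scan (global plus per-transect), writing every stage
#' table under `config$outdir` with a provenance header (package version,
#' configuration hash, seed). Identical configuration and seed reproduce
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with all stage results and `summary`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[altiscan] ", ...)
  hash <- fnv1a(config[setdiff(names(config), "outdir")])
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$outdir, "outliers"), showWarnings = FALSE)
  emit <- function(df, name) write_stage_tsv(
    df, file.path(config$outdir, name), hash, config$seed)
  res <- list(config_hash = hash)

  # ---- inputs ----
  if (is.null(config$alignments)) {
    say("simulating gene set")
    gs <- synthetic_gene_set(config)
    alns <- gs$alignments
    res$is_psg_truth <- gs$is_psg_truth
  } else {
    alns <- config$alignments
  }

  # ---- orthology (synthetic transcript demo) ----
  if (is.null(config$alignments) && isTRUE(config$synthetic$run_orthology)) {
    say("ortholog inference (best reciprocal hits)")
    taxa <- config$compare_branches
    seqs_a <- vapply(alns, function(a)
      alignment_sequences(a)[taxa[1]], character(1))
    seqs_b <- vapply(alns, function(a)
      alignment_sequences(a)[taxa[2]], character(1))
    names(seqs_a) <- paste0("A_", names(alns))
    set.seed(config$seed + 1L)
    names(seqs_b) <- paste0("B_", sample(names(alns)))
    hits_ab <- translated_hit_table(seqs_a, seqs_b)
    hits_ba <- translated_hit_table(seqs_b, seqs_a)
    brh <- best_reciprocal_hits(hits_ab, hits_ba,
                                e_threshold = config$e_value)
    emit(brh, "orthologs.tsv")
    res$orthologs <- brh
  }

  # ---- filtering ----
  say("filtering alignments")
  filt <- filter_orthologs(alns, min_len_nt = config$min_len_nt,
                           max_gap_fraction = config$max_gap_fraction,
                           ds_cap = config$ds_cap)
  emit(filt$reports, "filter_report.tsv")
  res$filter <- filt
  kept <- filt$retained
  if (!length(kept)) stop("pipeline halted at stage 'filter': no gene retained")

  # ---- branch-site scan ----
  say("branch-site positive-selection scan (", length(kept), " genes)")
  lrt_tab <- do.call(rbind, lapply(kept, function(a)
    fit_branch_site(a, config$tree, foreground = config$foreground,
                    p_threshold = config$p_psg)$lrt))
  rownames(lrt_tab) <- NULL
  lrt_tab$q_value <- bh_fdr(lrt_tab$p_value)
  emit(lrt_tab, "branch_site_lrt.tsv")
  res$lrt <- lrt_tab
  psgs <- lrt_tab$gene_id[lrt_tab$is_psg]

  # ---- branch rates: per-gene foreground omega + bootstrap comparison ----
  say("branch-model rates and bootstrap comparison")
  part <- setNames(rep("background", length(branch_ids(config$tree))),
                   branch_ids(config$tree))
  part[config$compare_branches[1]] <- "high"
  part[config$compare_branches[2]] <- "low"
  per_gene <- vapply(kept, function(a)
    unname(fit_branch(a, config$tree, branch_partition = part,
                      control = list(max_sweeps = 4))$omegas["high"]),
    numeric(1))
  concat <- concatenate(kept)
  boot <- bootstrap_branch_rates(concat, config$tree,
                                 n_rep = config$n_bootstrap,
                                 seed = config$seed + 2L,
                                 branch_partition = part,
                                 control = list(max_sweeps = 3))
  p_rate <- binomial_rate_test(boot$omega[, "high"], boot$omega[, "low"])
  emit(data.frame(gene_id = names(per_gene), omega_high = unname(per_gene)),
       "gene_branch_rates.tsv")
  res$bootstrap <- boot
  res$rate_test_p <- p_rate

  # ---- annotation, category rates, enrichment ----
  ann <- config$annotation
  if (is.null(ann)) {
    set.seed(config$seed + 3L)
    cats <- sprintf("CAT%02d", 1:3)
    ann <- data.frame(
      gene_id = rep(names(alns), each = 2),
      category_id = as.vector(vapply(seq_along(alns), function(i)
        sample(cats, 2), character(2))),
      stringsAsFactors = FALSE)
  }
  say("category rates and enrichment")
  cat_rates <- category_rates(per_gene, ann, min_genes = 3,
                              n_boot = 500, seed = config$seed + 4L)
  emit(cat_rates, "category_rates.tsv")
  res$category_rates <- cat_rates
  enr <- enrichment_test(psgs, names(per_gene), ann)
  emit(enr, "enrichment.tsv")
  res$enrichment <- enr
  emit(gene_function_edges(psgs, ann), "gene_function_edges.tsv")

  # ---- SNP panel: island model, read counts, tag SNPs, outlier scan ----
  say("SNP panel and outlier scan")
  syn <- config$synthetic
  if (is.null(config$counts)) {
    alpha <- c(rep(syn$alpha, syn$n_outlier),
               rep(0, syn$n_loci - syn$n_outlier))
    imp <- island_model_params(n_pops = 5, n_loci = syn$n_loci,
                               alpha = alpha,
                               ancestral_freq_prior = c(2, 2),
                               seed = config$seed + 5L)
    sim <- simulate_allele_counts(imp)
    counts <- sim$counts
    res$outlier_truth <- sim$truth
  } else {
    counts <- config$counts
  }
  emit(data.frame(locus = counts$locus_ids, counts$a, check.names = FALSE),
       "allele_counts_alt.tsv")

  # read-count SNP calling demo on pooled frequencies of the panel loci
  freqs <- rowSums(counts$a) / rowSums(counts$n)
  reads <- simulate_read_counts(
    freqs, read_sim_params(mean_coverage = 250, error_rate = 0.001,
                           seed = config$seed + 6L),
    gene_ids = counts$locus_ids, positions = rep(1L, length(freqs)))
  snps <- call_snps(reads, min_rare_coverage = config$min_rare_coverage)
  tags <- select_tag_snps(snps)
  emit(tags, "tag_snps.tsv")
  res$tag_snps <- tags

  scans <- list()
  mc <- config$mcmc
  scan_one <- function(cts, seed_off) {
    s <- mc; s$seed <- config$seed + seed_off
    bayescan_scan(cts, s, q_threshold = config$q_outlier)
  }
  scans$global <- scan_one(counts, 7L)
  emit(scans$global$results, file.path("outliers", "global.tsv"))
  for (k in seq_along(config$transects)) {
    nm <- names(config$transects)[k]
    scans[[nm]] <- scan_one(subset_populations(counts,
                                               config$transects[[k]]),
                            7L + k)
    emit(scans[[nm]]$results,
         file.path("outliers", paste0(nm, ".tsv")))
  }
  res$scans <- scans
  consistent <- transect_consistency(scans$global$results,
                                     scans[names(config$transects)])
  emit(consistent, "consistent_outliers.tsv")
  res$consistent <- consistent

  # ---- summary ----
  fst <- wc_fst(counts)
  summary <- data.frame(
    key = c("n_input_genes", "n_orthologs", "n_retained", "n_psg",
            "rate_test_p", "global_fst", "n_tag_snps", "n_outliers_global",
            "n_consistent_outliers"),
    value = c(length(alns),
              if (!is.null(res$orthologs)) nrow(res$orthologs) else NA,
              length(kept), length(psgs), signif(p_rate, 6),
              signif(fst$global_fst, 6), nrow(tags),
              sum(scans$global$results$selection_class != "neutral"),
              nrow(consistent)),
    stringsAsFactors = FALSE)
  emit(summary, "summary.tsv")
  res$summary <- summary
  say("done: ", config$outdir)
  invisible(res)
}
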