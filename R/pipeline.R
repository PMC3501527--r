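# End-to-end drivers: the file-based pipeline (reference build ->
# per-library clean/map/quantify -> pairwise DE -> enrichment -> report
# files) and the fully in-memory simulated experiment with truth
# comparison.

#' Run the DGE analysis pipeline
#'
#' Orchestrates every stage over files: builds the reference tag library
#' from a transcriptome FASTA, cleans and quantifies each raw tag
#' library, calls differential expression for each configured pairwise
#' comparison, runs term enrichment when an annotation table is
#' supplied, and writes all tables plus a run log under `outdir`.
#'
#' The configuration is a YAML file or an equivalent nested list:
#' \preformatted{
#' transcriptome: ref.fasta
#' libraries: {eggs: eggs.tsv, larvae: larvae.tsv}
#' comparisons: [[eggs, larvae]]
#' annotation: annotation.tsv      # optional
#' outdir: results
#' params:                         # all optional
#'   strand_mode: sense_only
#'   denominator_mode: clean_total
#'   fdr_threshold: 0.001
#'   log2_threshold: 1
#'   enrichment_mode: go
#'   enrichment_alpha: 0.05
#'   min_term_size: 2
#'   copy_number_breaks: [2, 6, 11, 21, 51, 101]
#' }
#' Raw tag files are one read per line or two-column `tag`/`count` TSV.
#' The run is deterministic: identical inputs produce byte-identical
#' outputs.
#'
#' @param config path to a YAML config, or the equivalent list.
#' @return (invisibly) a list bundle of class `dge_pipeline`: the
#'   reference `library`, per-library `filters`, `expression` tables and
#'   `copy_number` distributions, the combined `stats_table`,
#'   per-comparison `de` results and `enrichment` tables, and the
#'   `config` used.
#' @export
run_dge_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  p <- config$params %||% list()
  strand_mode <- p$strand_mode %||% "sense_only"
  denominator_mode <- p$denominator_mode %||% "clean_total"
  fdr_threshold <- p$fdr_threshold %||% 0.001
  log2_threshold <- p$log2_threshold %||% 1
  enrichment_mode <- p$enrichment_mode %||% "go"
  enrichment_alpha <- p$enrichment_alpha %||% 0.05
  min_term_size <- p$min_term_size %||% 2
  breaks <- p$copy_number_breaks %||% c(2, 6, 11, 21, 51, 101)

  for (path in c(config$transcriptome, unlist(config$libraries),
                 config$annotation))
    if (!file.exists(path))
      stop("input file not found: ", path, call. = FALSE)
  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  log_lines <- c(
    sprintf("tagdge %s", as.character(utils::packageVersion("tagdge"))),
    sprintf("params: strand_mode=%s denominator_mode=%s fdr<=%g |log2|>=%g alpha=%g",
            strand_mode, denominator_mode, fdr_threshold, log2_threshold,
            enrichment_alpha))
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  tx <- read_transcriptome(config$transcriptome)
  say("transcriptome: %d genes from %s", length(tx), config$transcriptome)
  lib <- build_tag_library(tx, strand_mode = strand_mode)
  say("reference library: %d tags (%d gene-unique), %d/%d genes taggable",
      nrow(lib$tags), sum(lib$tags$is_gene_unique), lib$genes_taggable,
      lib$genes_total)
  write_tag_library(lib, file.path(outdir, "reference_tags.tsv"))

  lib_ids <- names(config$libraries)
  filters <- list(); exprs <- list(); cdists <- list(); stats_rows <- list()
  for (id in lib_ids) {
    raw <- read_raw_tags(config$libraries[[id]])
    fl <- filter_tags(raw)
    ex <- quantify_library(fl$clean, lib,
                           denominator_mode = denominator_mode)
    cd <- copy_number_distribution(fl$clean, breaks = breaks)
    say("library %s: raw=%d clean=%d (%.2f%%) mapped=%d unknown=%d",
        id, fl$stats$raw_total, fl$stats$clean_total,
        fl$stats$clean_pct_of_raw,
        attr(ex, "mapping_stats")$all_mapped_total,
        attr(ex, "mapping_stats")$unknown_total)
    write.table(as.data.frame(ex),
                file.path(outdir, paste0(id, "_expression.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(cd),
                file.path(outdir, paste0(id, "_copy_number.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    filters[[id]] <- fl$stats
    exprs[[id]] <- ex
    cdists[[id]] <- cd
    stats_rows[[id]] <- library_stats(fl$stats, attr(ex, "mapping_stats"),
                                      lib$genes_total, library_id = id)
  }
  stats_table <- library_stats_table(stats_rows)
  write.table(as.data.frame(stats_table),
              file.path(outdir, "library_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- read.delim(config$annotation, stringsAsFactors = FALSE)
    missing <- setdiff(unique(annotation$gene_id), names(tx))
    if (length(missing) > 0L)
      warning(length(missing),
              " annotated gene id(s) absent from the transcriptome")
  }

  des <- list(); enr <- list()
  for (cmp in config$comparisons %||% list()) {
    a <- cmp[[1L]]; b <- cmp[[2L]]
    key <- paste0(a, "_vs_", b)
    ea <- exprs[[a]]; eb <- exprs[[b]]
    de <- dge_test(setNames(ea$count, ea$gene_id),
                   setNames(eb$count, eb$gene_id),
                   N1 = attr(ea, "denominator"),
                   N2 = attr(eb, "denominator"),
                   fdr_threshold = fdr_threshold,
                   log2_threshold = log2_threshold)
    say("comparison %s: %d tested, %d up, %d down", key,
        nrow(de$table), sum(de$table$direction == "up"),
        sum(de$table$direction == "down"))
    write.table(de$table, file.path(outdir, paste0(key, "_deg.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    des[[key]] <- de
    if (!is.null(annotation) && any(de$table$significant)) {
      er <- enrich_terms(de$table$gene_id[de$table$significant],
                         annotation, mode = enrichment_mode,
                         alpha = enrichment_alpha,
                         min_term_size = min_term_size)
      say("enrichment %s: %d terms tested, %d significant", key,
          nrow(er), sum(er$significant))
      write.table(as.data.frame(er),
                  file.path(outdir, paste0(key, "_enrichment.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      enr[[key]] <- er
    }
  }

  writeLines(log_lines, log_path)
  invisible(structure(list(library = lib, filters = filters,
                           expression = exprs, copy_number = cdists,
                           stats_table = stats_table, de = des,
                           enrichment = enr, config = config),
                      class = "dge_pipeline"))
}

#' Simulate a two-condition DGE experiment and analyze it
#'
#' Generates a transcriptome, a ground-truth expression profile with a
#' known set of differentially expressed genes, two raw tag libraries
#' (reference and treatment) with the configured contamination and
#' sequencing-error levels, and a term annotation with the planted term
#' enriched among the true DE genes. The full analysis is then run in
#' memory and compared against the truth.
#'
#' @param n_genes,library_size,de_fraction,log2fc_values,error_rate,adapter_fraction,n_fraction,singleton_noise_fraction,n_terms
#'   generator settings; see [sim_transcriptome()], [sim_expression()],
#'   [sim_library()] and [sim_annotations()].
#' @param fdr_threshold,log2_threshold,denominator_mode analysis
#'   settings; see [dge_test()] and [quantify_library()].
#' @param high_tpm recovery metrics are additionally reported restricted
#'   to true DE genes whose reference abundance corresponds to at least
#'   this TPM (default 50).
#' @param seed integer master seed; each generator derives its own
#'   sub-seed from it, so the whole experiment is reproducible.
#' @return object of class `dge_simulation`: list with the generated
#'   `truth`, the analysis objects (`library`, `filters`, `expression`,
#'   `de`, `enrichment`), the truth-vs-called `confusion` matrix and a
#'   `metrics` list (sensitivity, sensitivity_high_tpm, empirical_fdr,
#'   tpm_truth_spearman per library, planted-term p-value and rank).
#' @export
simulate_dge_experiment <- function(n_genes = 5000,
                                    library_size = 2e5,
                                    de_fraction = 0.05,
                                    log2fc_values = c(-2, 2),
                                    error_rate = 0.005,
                                    adapter_fraction = 0.01,
                                    n_fraction = 0.005,
                                    singleton_noise_fraction = 0.005,
                                    n_terms = 20,
                                    fdr_threshold = 0.001,
                                    log2_threshold = 1,
                                    denominator_mode = "clean_total",
                                    high_tpm = 50,
                                    seed = 1) {
  tx <- sim_transcriptome(n_genes, seed = seed)
  truth <- sim_expression(tx, de_fraction = de_fraction,
                          log2fc_values = log2fc_values, seed = seed + 1)
  sims <- list(
    lib1 = sim_library(tx, truth, "lib1", library_size, error_rate,
                       adapter_fraction, n_fraction,
                       singleton_noise_fraction, seed = seed + 2),
    lib2 = sim_library(tx, truth, "lib2", library_size, error_rate,
                       adapter_fraction, n_fraction,
                       singleton_noise_fraction, seed = seed + 3))
  lib <- build_tag_library(tx)
  ann <- sim_annotations(names(tx), n_terms = n_terms,
                         target_genes = truth$de_genes, seed = seed + 4)

  filters <- lapply(sims, filter_tags)
  exprs <- lapply(filters, function(fl)
    quantify_library(fl$clean, lib, denominator_mode = denominator_mode))

  de <- dge_test(setNames(exprs$lib1$count, exprs$lib1$gene_id),
                 setNames(exprs$lib2$count, exprs$lib2$gene_id),
                 N1 = attr(exprs$lib1, "denominator"),
                 N2 = attr(exprs$lib2, "denominator"),
                 fdr_threshold = fdr_threshold,
                 log2_threshold = log2_threshold)

  called <- de$table$gene_id[de$table$significant]
  truth_de <- truth$de_genes
  all_genes <- names(tx)
  confusion <- matrix(
    c(length(intersect(called, truth_de)),   # called & true
      length(setdiff(truth_de, called)),     # missed
      length(setdiff(called, truth_de)),     # false call
      length(all_genes) - length(union(called, truth_de))),
    2L, 2L,
    dimnames = list(called = c("yes", "no"), true_de = c("yes", "no")))
  ref_tpm <- truth$abundance[, "lib1"] * 1e6
  hi <- truth_de[ref_tpm[truth_de] >= high_tpm]
  metrics <- list(
    n_true_de = length(truth_de),
    n_called = length(called),
    sensitivity = if (length(truth_de) > 0)
      confusion["yes", "yes"] / length(truth_de) else NA_real_,
    sensitivity_high_tpm = if (length(hi) > 0)
      length(intersect(called, hi)) / length(hi) else NA_real_,
    empirical_fdr = if (length(called) > 0)
      confusion["yes", "no"] / length(called) else 0,
    tpm_truth_spearman = vapply(c("lib1", "lib2"), function(id) {
      # untaggable genes emit no tag by construction; compare on the
      # genes the assay can see
      tg <- setdiff(exprs[[id]]$gene_id, attr(tx, "untaggable"))
      idx <- match(tg, exprs[[id]]$gene_id)
      cor(exprs[[id]]$tpm[idx], truth$abundance[tg, id],
          method = "spearman")
    }, numeric(1))
  )
  enr <- NULL
  if (length(called) > 0L) {
    enr <- enrich_terms(called, ann)
    planted <- which(enr$term_id == "T001")
    metrics$planted_term_rank <- planted
    metrics$planted_term_p_corrected <- enr$p_corrected[planted]
    metrics$planted_term_significant <- enr$significant[planted]
  }

  structure(list(transcriptome = tx, truth = truth, annotation = ann,
                 library = lib, sims = sims, filters = filters,
                 expression = exprs, de = de, enrichment = enr,
                 confusion = confusion, metrics = metrics, seed = seed),
            class = "dge_simulation")
}

#' @export
print.dge_simulation <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Simulated DGE experiment (seed %s): %d genes, 2 libraries\n",
              format(x$seed), length(x$transcriptome)))
  cat(sprintf("  true DE: %d; called: %d; sensitivity %.3f (%.3f at high TPM); empirical FDR %.3f\n",
              m$n_true_de, m$n_called, m$sensitivity,
              m$sensitivity_high_tpm, m$empirical_fdr))
  cat(sprintf("  TPM-truth Spearman: lib1 %.4f, lib2 %.4f\n",
              m$tpm_truth_spearman[["lib1"]],
              m$tpm_truth_spearman[["lib2"]]))
  if (!is.null(m$planted_term_p_corrected))
    cat(sprintf("  planted term: rank %d, corrected p %.3g\n",
                m$planted_term_rank, m$planted_term_p_corrected))
  invisible(x)
}
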