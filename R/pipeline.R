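# End-to-end orchestration: simulate -> filter -> annotate -> saturate
# -> test -> enrich, with a QC-report bundle and truth-based evaluation.

log_stage <- function(name, fmt, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  name, sprintf(fmt, ...)))
}

#' Random gene-to-pathway annotation for demo runs
#'
#' Assigns each pathway a Poisson-sized random subset of the gene set;
#' genes may belong to several pathways, mirroring KEGG-style maps.
#'
#' @param gene_ids genes to draw from
#' @param n_pathways number of pathways
#' @param mean_size Poisson mean pathway size
#' @param seed RNG seed
#' @return data.frame: gene_id, pathway_id, pathway_name
#' @export
synthetic_pathways <- function(gene_ids, n_pathways = 25L, mean_size = 40L,
                               seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(n_pathways), function(i) {
      size <- max(1L, stats::rpois(1, mean_size))
      size <- min(size, length(gene_ids))
      data.frame(gene_id = sample(gene_ids, size),
                 pathway_id = sprintf("ko%05d", i),
                 pathway_name = sprintf("pathway_%02d", i),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Run the full DGE tag-profiling pipeline on simulated data
#'
#' Generates a transcriptome and two tag libraries from `config`, runs
#' the filtering ladder, builds the virtual-digest index, maps tags,
#' tests differential expression, draws saturation curves, performs
#' pathway enrichment (against `annotation`, or a synthetic pathway map
#' when none is given) and evaluates calls against the planted truth.
#' Every stage logs record counts to stderr; the whole run is
#' deterministic under `config$seed`.
#'
#' @param config a [sim_config()]
#' @param outdir output directory for TSV/JSON artifacts; NULL skips
#'   writing
#' @param annotation optional gene-to-pathway data.frame
#' @param adapter adapter sequence for filtering
#' @param max_mismatch tag-mapping mismatch tolerance (0 or 1)
#' @param fdr_cut,lfc_cut DEG thresholds
#' @param tpm_floor TPM floor for log2 ratios
#' @param q_cut enrichment Q threshold
#' @param sat_grid number of saturation depths
#' @param sat_reps saturation replicates
#' @return invisible list: config, truth, tables, index, maps, counts,
#'   de, de_summary, saturation, enrichment, evaluation, files
#' @export
run_pipeline <- function(config = sim_config(), outdir = NULL,
                         annotation = NULL, adapter = GEX_ADAPTER_1,
                         max_mismatch = 1L, fdr_cut = 0.001, lfc_cut = 1,
                         tpm_floor = 0.001, q_cut = 0.05,
                         sat_grid = 10L, sat_reps = 3L) {
  stopifnot(inherits(config, "sim_config"))
  tx <- generate_transcriptome(config)
  log_stage("simulate", "%d transcripts", length(tx))
  truth <- plant_truth(config)
  libs <- simulate_libraries(tx, truth, config)
  log_stage("simulate", "%d reads per library", config$n_tags_per_library)

  tables <- lapply(c(CO = "CO", DS = "DS"), function(lib)
    filter_tags(libs$reads[[lib]], adapter = adapter, library_id = lib))
  for (lib in names(tables))
    log_stage("filter", "%s: %.0f retained / %.0f total, %d unique",
              lib, tables[[lib]]$ledger$retained_tags,
              tables[[lib]]$ledger$total_tags,
              tables[[lib]]$ledger$unique_tags)

  index <- build_tag_index(tx)
  log_stage("annotate", "index: %d tag keys over %d genes",
            nrow(index$table), index$n_genes_with_sites)
  maps <- lapply(tables, map_tags, index = index,
                 max_mismatch = max_mismatch)
  for (lib in names(maps))
    log_stage("annotate", "%s: %d/%d unique tags assigned, %d genes",
              lib, maps[[lib]]$report$matched_unique_tags,
              maps[[lib]]$report$unique_tags,
              maps[[lib]]$report$matched_genes)

  counts <- merge_gene_counts(maps$CO$genes, maps$DS$genes)
  N1 <- tables$CO$ledger$retained_tags
  N2 <- tables$DS$ledger$retained_tags
  de <- de_test(counts, N1, N2, fdr_cut = fdr_cut, lfc_cut = lfc_cut,
                tpm_floor = tpm_floor)
  de_summary <- classify_degs(de, fdr_cut, lfc_cut)$summary
  log_stage("de", "%d tested, %d up, %d down", de_summary$n_tested,
            de_summary$n_up, de_summary$n_down)

  sat <- lapply(names(tables), function(lib) {
    n_reads <- sum(tables[[lib]]$counts)
    depths <- unique(round(seq_len(sat_grid) / sat_grid * n_reads))
    saturation_curve(tables[[lib]], maps[[lib]], depths,
                     n_replicates = sat_reps,
                     seed = derive_seed(config$seed, 7L))
  })
  names(sat) <- names(tables)

  if (is.null(annotation))
    annotation <- synthetic_pathways(truth$gene_id,
                                     seed = derive_seed(config$seed, 9L))
  degs <- de$gene_id[de$call != "none"]
  enr <- enrich_all(annotation, universe = de$gene_id, degs = degs,
                    de_calls = de[, c("gene_id", "call")], q_cut = q_cut)
  log_stage("enrich", "%d pathways tested, %d enriched (q < %g)",
            nrow(enr), sum(enr$enriched), q_cut)

  evaluation <- truth_evaluation(de, truth)

  bundle <- list(config = config, truth = truth, tables = tables,
                 index = index, maps = maps, counts = counts, de = de,
                 de_summary = de_summary, saturation = sat,
                 enrichment = enr, evaluation = evaluation,
                 files = character(0))
  if (!is.null(outdir))
    bundle$files <- write_pipeline_outputs(bundle, outdir)
  invisible(bundle)
}

merge_gene_counts <- function(co, ds) {
  m <- merge(co[, c("gene_id", "count")], ds[, c("gene_id", "count")],
             by = "gene_id", all = TRUE, suffixes = c("_co", "_ds"))
  m[is.na(m)] <- 0
  data.frame(gene_id = m$gene_id, x = as.integer(m$count_co),
             y = as.integer(m$count_ds), stringsAsFactors = FALSE)
}

#' Evaluate DE calls against the planted truth
#'
#' @param de a `de_result` table (gene_id, call)
#' @param truth truth table from [plant_truth()]
#' @param min_baseline_tpm restrict recall to planted genes whose
#'   baseline abundance share corresponds to at least this TPM
#' @return list: `overall` (n_called, recall, fdp — NA when nothing is
#'   called) and `by_stratum` (per planted fold: n_planted, n_called,
#'   recall)
#' @export
truth_evaluation <- function(de, truth, min_baseline_tpm = 0) {
  if (!all(de$gene_id %in% truth$gene_id))
    stop("DE table contains gene IDs absent from the truth table")
  called <- de$gene_id[de$call != "none"]
  truth$called <- truth$gene_id %in% called
  truth$baseline_tpm <- truth$baseline_expr / sum(truth$baseline_expr) * 1e6
  n_called <- length(called)
  fdp <- if (n_called) sum(truth$called & !truth$is_de) / n_called else NA_real_
  eligible <- truth$baseline_tpm >= min_baseline_tpm
  pl <- truth[truth$is_de & eligible, , drop = FALSE]
  recall <- if (nrow(pl)) mean(pl$called) else NA_real_
  strata <- lapply(split(pl, pl$fold_change), function(s)
    data.frame(fold_change = s$fold_change[1], n_planted = nrow(s),
               n_called = sum(s$called), recall = mean(s$called)))
  by_stratum <- do.call(rbind, strata)
  if (!is.null(by_stratum)) {
    by_stratum <- by_stratum[order(by_stratum$fold_change), , drop = FALSE]
    rownames(by_stratum) <- NULL
  }
  list(overall = list(n_called = n_called, recall = recall, fdp = fdp),
       by_stratum = by_stratum)
}

write_pipeline_outputs <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  path <- function(f) file.path(outdir, f)

  # Table-1-shaped QC ledger with copy-number strata
  strata <- c(5L, 10L, 20L, 50L, 100L)
  ledger_rows <- c("total tags", "clean tags", "clean tags copy number = 1",
                   "retained tags", "unique tags",
                   paste0("unique tags copy number >", strata))
  t1 <- data.frame(row = ledger_rows)
  for (lib in names(bundle$tables)) {
    tab <- bundle$tables[[lib]]
    t1[[lib]] <- c(tab$ledger$total_tags, tab$ledger$clean_tags,
                   tab$ledger$singleton_tags, tab$ledger$retained_tags,
                   tab$ledger$unique_tags,
                   copy_number_strata(tab, strata))
  }
  utils::write.table(t1, path("table1_ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, path("table1_ledger.tsv"))

  # Table-2-shaped annotation summary
  t2 <- do.call(rbind, lapply(names(bundle$maps), function(lib) {
    rep <- bundle$maps[[lib]]$report
    rates <- annotation_rates(rep, length(bundle$index$gene_ids))
    data.frame(library = lib,
               total_tags = rep$matched_total_tags,
               total_tags_pct = rates$matched_total_pct,
               unique_tags = rep$matched_unique_tags,
               unique_tags_pct = rates$matched_unique_pct,
               match_genes = rep$matched_genes,
               match_genes_pct = rates$matched_gene_pct)
  }))
  utils::write.table(t2, path("table2_annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, path("table2_annotation.tsv"))

  de_out <- bundle$de
  utils::write.table(format(de_out, digits = 10), path("de_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, path("de_table.tsv"))

  utils::write.table(format(as.data.frame(bundle$enrichment), digits = 10),
                     path("table3_enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, path("table3_enrichment.tsv"))

  for (lib in names(bundle$saturation)) {
    f <- path(sprintf("saturation_%s.tsv", lib))
    utils::write.table(bundle$saturation[[lib]], f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }

  write_truth_tsv(bundle$truth, path("truth.tsv"))
  files <- c(files, path("truth.tsv"))

  cfg_json <- jsonlite::toJSON(unclass(bundle$config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- path("config.json")
  writeLines(cfg_json, cfg_file)
  report <- list(
    seed = bundle$config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    de_summary = bundle$de_summary,
    evaluation_overall = bundle$evaluation$overall
  )
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, cfg_file, path("report.json"))
  files
}
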