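#' One-shot pipeline: lift, QC, merge, accession, annotate, quantify
#'
#' Orchestrates the whole migration as one deterministic, logged run driven
#' by a declarative configuration. Outputs: fair/problematic/dropped BED
#' files, the merged peak set with full identifiers, the accession registry,
#' an annotation table, raw-count and TPM OSC tables, a JSON QC report, and
#' a provenance file recording the configuration and input checksums.
#'
#' @name pipeline_cli
NULL

REQUIRED_CONFIG <- c("old_peaks", "chain", "ctss", "dpi_peaks",
                     "old_assembly", "new_assembly", "out_dir")

#' Read a pipeline configuration
#'
#' YAML with at least `old_peaks`, `chain`, `ctss` (a `library_id: path`
#' map), `dpi_peaks`, `old_assembly`, `new_assembly`, `out_dir`; optional
#' `curation`, `transcripts`, `registry`, `species_prefix` (default from
#' the old assembly label), `min_match` (default 1), `window_pol2` (500),
#' `window_non_pol2` (50).
#'
#' @param path YAML file.
#' @return named configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  missing <- setdiff(REQUIRED_CONFIG, names(cfg))
  if (length(missing) > 0L) {
    stop(sprintf("pipeline config is missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(names(cfg$ctss)) || any(!nzchar(names(cfg$ctss)))) {
    stop("config field 'ctss' must map library ids to CTSS BED paths",
         call. = FALSE)
  }
  cfg$min_match <- cfg$min_match %||% 1.0
  cfg$window_pol2 <- cfg$window_pol2 %||% 500L
  cfg$window_non_pol2 <- cfg$window_non_pol2 %||% 50L
  cfg$species_prefix <- cfg$species_prefix %||%
    if (startsWith(cfg$old_assembly, "mm")) "mm" else "hg"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[peaklift:%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full migration pipeline
#'
#' @param config configuration list (see [read_pipeline_config()]) or a
#'   path to a YAML configuration file.
#' @return invisibly, a list with the classified peaks, merged set,
#'   registry, annotations, expression matrices and QC report; all files
#'   are written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  pipeline_log("lift", "reading peaks from %s", cfg$old_peaks)
  peaks <- run_stage("read_peaks",
                     read_peaks(cfg$old_peaks, cfg$old_assembly))
  chains <- run_stage("parse_chains", parse_chains(cfg$chain))
  lifted <- run_stage("lift", lift_peaks(peaks, chains,
                                         min_match = cfg$min_match,
                                         new_assembly_label = cfg$new_assembly))
  pipeline_log("lift", "%d mapped, %d dropped", nrow(lifted$mapped),
               nrow(lifted$dropped))

  ctss_list <- run_stage("read_ctss", {
    stats::setNames(lapply(seq_along(cfg$ctss), function(j) {
      read_ctss(cfg$ctss[[j]], names(cfg$ctss)[j])
    }), names(cfg$ctss))
  })
  pooled <- pool_ctss(ctss_list)

  curation <- if (!is.null(cfg$curation)) {
    run_stage("read_curation", read_curation(cfg$curation))
  } else NULL
  qc <- run_stage("qc", classify_peaks(lifted, pooled, curation))
  pipeline_log("qc", "%d fair, %d problematic, %d dropped",
               qc$report$n_fair, qc$report$n_problematic,
               qc$report$n_dropped)

  fair <- qc$peaks[qc$peaks$state == "fair", , drop = FALSE]
  dpi <- run_stage("read_dpi", read_peaks(cfg$dpi_peaks, cfg$new_assembly))
  merged <- run_stage("merge", merge_new_peaks(fair, dpi))
  summary <- overlap_summary(fair, dpi)
  pipeline_log("merge", "%d fair + %d new = %d merged peaks", nrow(fair),
               sum(merged$state == "new"), nrow(merged))

  registry <- if (!is.null(cfg$registry) && file.exists(cfg$registry)) {
    read_registry(cfg$registry)
  } else new_registry()
  acc <- run_stage("accession",
                   assign_accessions(merged, registry, cfg$species_prefix))
  merged <- acc$peaks

  quant <- run_stage("quantify", quantify_peaks(merged, ctss_list))

  annotations <- NULL
  if (!is.null(cfg$transcripts)) {
    tx <- run_stage("read_transcripts", read_transcripts(cfg$transcripts))
    annotations <- run_stage("annotate", {
      ann <- associate_peaks(merged, tx, cfg$window_pol2,
                             cfg$window_non_pol2)
      assign_short_names(ann,
                         pooled_expression = rowSums(quant$raw_counts))
    })
    pipeline_log("annotate", "%d/%d peaks annotated",
                 sum(annotations$annotated), nrow(merged))
  }

  pipeline_log("write", "writing outputs to %s", out)
  fair <- merged[merged$state == "fair", , drop = FALSE]  # with accessions
  write_peaks(fair, file.path(out, "fair.bed"))
  write_peaks(qc$peaks[qc$peaks$state == "problematic", , drop = FALSE],
              file.path(out, "problematic.bed"), use_full_id = FALSE)
  write_peaks(qc$dropped, file.path(out, "dropped.bed"),
              use_full_id = FALSE)
  write_peaks(merged, file.path(out, "merged.bed"))
  write_registry(acc$registry, file.path(out, "accessions.tsv"))
  rn <- merged$coord_id
  raw <- quant$raw_counts; rownames(raw) <- rn
  tpm <- quant$tpm; rownames(tpm) <- rn
  write_osc(raw, file.path(out, "expression_raw.osc"), value_type = "raw")
  write_osc(tpm, file.path(out, "expression_tpm.osc"), value_type = "tpm")
  if (!is.null(annotations)) {
    write_annotation(annotations, merged, file.path(out, "annotation.tsv"))
  }
  report <- c(
    unclass(qc$report)[c("n_input", "n_fair", "n_problematic", "n_dropped")],
    list(n_new = sum(merged$state == "new"), n_merged = nrow(merged),
         overlap_summary = summary,
         problematic_by_chrom = qc$report$problematic_by_chrom,
         dropped_by_chrom = qc$report$dropped_by_chrom,
         overlap_groups = qc$report$overlap_groups,
         length_changed = qc$report$length_changed)
  )
  jsonlite::write_json(report, file.path(out, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  inputs <- unlist(cfg[c("old_peaks", "chain", "dpi_peaks", "curation",
                         "transcripts")])
  inputs <- c(inputs, unlist(cfg$ctss))
  provenance <- list(config = cfg,
                     input_md5 = as.list(tools::md5sum(inputs[!is.na(inputs)])))
  jsonlite::write_json(provenance, file.path(out, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(peaks = qc$peaks, dropped = qc$dropped, fair = fair,
                 merged = merged, registry = acc$registry,
                 annotations = annotations, expression = quant,
                 report = qc$report, overlap_summary = summary))
}
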