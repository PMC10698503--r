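#' Table schemas used across the package
#'
#' Named list of required columns per logical table type. `l*` stands for the
#' lanthanide-ratio columns `l1..lL`, whose count is data-dependent.
#'
#' @format list of character vectors
#' @keywords internal
table_schemas <- list(
  bead      = c("bead_id", "intensity", "condition", "replicate_id", "sample_id"),
  code      = c("code_id"),
  library   = c("peptide_id", "code_id", "sequence"),
  site      = c("site_id", "protein_id", "position", "acceptor", "localized",
                "multiplicity", "unique_protein_match", "window"),
  interactor = c("protein_id", "bait", "method")
)

lanthanide_cols <- function(df) {
  grep("^l[0-9]+$", names(df), value = TRUE)
}

#' Validate and load a delimited table against a named schema
#'
#' Reads a TSV and checks that the columns a downstream stage requires are
#' present and correctly typed. Numeric columns containing non-numeric text
#' are reported with their first offending row. Row and column counts are
#' reported via `inform()` so pipeline runs leave an audit trail.
#'
#' @param path file path to a tab-separated table.
#' @param schema one of `names(table_schemas)`: `"bead"`, `"code"`,
#'   `"library"`, `"site"`, `"interactor"`.
#' @param quiet suppress the row/column count message.
#' @return a tibble with the file's contents.
#' @export
validate_table <- function(path, schema, quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  schema <- match.arg(schema, names(table_schemas))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- table_schemas[[schema]]
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("schema '", schema, "': missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  numeric_cols <- switch(schema,
    bead = c("intensity", "condition", lanthanide_cols(df)),
    code = lanthanide_cols(df),
    site = "position",
    character(0)
  )
  for (col in numeric_cols) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))
      abort(paste0("column '", col, "' must be numeric; first bad row: ",
                   if (length(bad)) bad[1] else "coercion failed"))
    }
  }
  if (schema == "bead" && length(lanthanide_cols(df)) == 0) {
    abort("bead table has no lanthanide columns l1..lL")
  }
  if (!quiet) {
    inform(paste0("loaded ", schema, " table: ", nrow(df), " rows, ",
                  ncol(df), " columns"))
  }
  df
}

#' Write a table as TSV
#'
#' Thin wrapper used by all modules so every emitted table shares one dialect
#' (tab-separated, no quoting surprises, `NA` for missing).
#'
#' @param df data frame to write.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects every tunable threshold of the pipeline in one place, with
#' defaults equal to the values used throughout the package's analyses:
#' QC multiplier 1.5, `n_final = 3` end points for scoring, saturation
#' threshold 12,000 intensity units, alpha 0.05, `log2fc_min = 0.58`
#' (1.5-fold), interactor fold gate 2, window flank 7, motif-region boundary
#' 1,000 residues, temperature 298.15 K.
#'
#' @param ... overrides for any default element.
#' @return a named list of parameters (class `phosbead_config`).
#' @export
run_config <- function(...) {
  cfg <- list(
    qc_sd_multiplier = 1.5,
    n_final = 3,
    statistic = "mean",
    saturation_threshold = 12000,
    saturation_mode = "absolute",
    alpha = 0.05,
    log2fc_min = 0.58,
    interactor_fold_min = 2,
    impute_width = 0.3,
    impute_downshift = 1.8,
    flank = 7,
    boundary = 1000,
    temperature_K = 298.15,
    kd_aggregate = "mean",
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown config parameter(s): ", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "phosbead_config")
}

#' Run the dephosphorylation pipeline end to end
#'
#' Convenience driver: decode beads, aggregate per code, apply the QC gate,
#' score and fit every peptide for one enzyme, and aggregate replicates.
#' Returns the scored table plus a machine-readable run summary in which
#' every parameter used is echoed verbatim.
#'
#' @param beads bead table (see [summarize_codes()] for columns).
#' @param codes spectral code reference table.
#' @param library_tbl peptide library (`peptide_id`, `code_id`, `sequence`).
#' @param negative_control_code code id of the phosphate-free control.
#' @param enzyme label stored in the result.
#' @param config a [run_config()] list.
#' @return list with `results` (per-peptide [aggregate_replicates()] output),
#'   `qc` (QC report), and `summary` (named list: parameters and counts).
#' @export
run_dephos_pipeline <- function(beads, codes, library_tbl,
                                negative_control_code, enzyme = "enzyme",
                                config = run_config()) {
  assigned <- assign_codes(beads, codes)
  kept <- dplyr::filter(assigned, !is.na(.data$code_id))
  summaries <- summarize_codes(kept, statistic = config$statistic)
  qc <- qc_gate(kept, negative_control_code,
                sd_multiplier = config$qc_sd_multiplier,
                statistic = config$statistic)
  pass_codes <- qc$code_id[qc$passed]
  tcs <- build_timecourses(summaries, library_tbl, enzyme = enzyme,
                           keep_codes = pass_codes)
  res <- score_timecourses(tcs, n_final = config$n_final)
  agg <- aggregate_replicates(res)
  summary <- list(
    parameters = unclass(config),
    n_beads_in = nrow(beads),
    n_beads_assigned = nrow(kept),
    n_codes_pass_qc = length(pass_codes),
    n_codes_fail_qc = sum(!qc$passed),
    n_peptides_scored = nrow(agg),
    enzyme = enzyme
  )
  list(results = agg, qc = qc, summary = summary)
}

#' Write a run summary as JSON
#'
#' @param summary named list (e.g. from [run_dephos_pipeline()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
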