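#' Assign beads to spectral codes by nearest reference vector
#'
#' Each bead carries a vector of lanthanide intensity ratios (columns
#' `l1..lL`); each spectral code has a reference vector of the same length.
#' A bead is assigned to the code whose reference minimises the Euclidean
#' distance, provided that distance is within `max_distance` and the minimum
#' is unique. Otherwise the bead is left unassigned with a reason
#' (`"too-far"` or `"ambiguous-tie"`).
#'
#' @param beads bead tibble with columns `bead_id`, `l1..lL`, `intensity`,
#'   `condition`, `replicate_id`, `sample_id`.
#' @param codes code tibble with columns `code_id`, `l1..lL`.
#' @param max_distance assignment radius; default is half the minimum
#'   distance between any two reference vectors (conservative,
#'   parameter-free decoding).
#' @return `beads` with columns `code_id` (NA if unassigned),
#'   `assign_distance`, and `assign_reason` (`"ok"`, `"too-far"`,
#'   `"ambiguous-tie"`).
#' @export
assign_codes <- function(beads, codes, max_distance = NULL) {
  lcols <- lanthanide_cols(codes)
  if (nrow(codes) == 0 || length(lcols) == 0) {
    abort("empty code table: no references to assign against")
  }
  if (!all(lcols %in% names(beads))) {
    abort("bead lanthanide columns do not match the code table")
  }
  ref <- as.matrix(codes[lcols])
  if (anyDuplicated(ref)) abort("code reference vectors must be distinct")
  if (is.null(max_distance)) {
    if (nrow(ref) >= 2) {
      d <- as.matrix(stats::dist(ref))
      diag(d) <- Inf
      max_distance <- min(d) / 2
    } else {
      max_distance <- Inf
    }
  }
  bv <- as.matrix(beads[lcols])
  # squared distances via ||b||^2 - 2 b.r + ||r||^2
  cross <- bv %*% t(ref)
  d2 <- outer(rowSums(bv^2), rep(1, nrow(ref))) - 2 * cross +
    outer(rep(1, nrow(bv)), rowSums(ref^2))
  d2[d2 < 0] <- 0
  best <- max.col(-d2, ties.method = "first")
  best_d2 <- d2[cbind(seq_len(nrow(d2)), best)]
  # a tie exists when another reference is equally close (within float noise)
  tie_tol <- 1e-9 * pmax(best_d2, 1e-12)
  n_at_min <- rowSums(d2 <= best_d2 + tie_tol)
  dist_best <- sqrt(best_d2)
  reason <- rep("ok", nrow(beads))
  reason[dist_best > max_distance] <- "too-far"
  reason[n_at_min > 1] <- "ambiguous-tie"
  beads$code_id <- ifelse(reason == "ok", codes$code_id[best], NA_character_)
  beads$assign_distance <- dist_best
  beads$assign_reason <- reason
  beads
}

#' Aggregate per-bead intensities to per-code summaries
#'
#' Computes one summary per (code, condition, replicate): bead count, a
#' central intensity (mean or median) and a dispersion (standard deviation
#' or plain median absolute deviation, respectively). Negative intensities —
#' possible after upstream background subtraction — are clipped to zero and
#' the clipped count reported via `inform()`.
#'
#' @param beads assigned bead tibble (must carry `code_id`).
#' @param statistic `"mean"` (default, used for dephosphorylation scoring)
#'   or `"median"` (robust alternative used in figure-style reporting).
#' @return tibble: `code_id`, `condition`, `replicate_id`, `n_beads`,
#'   `central_intensity`, `dispersion`.
#' @export
summarize_codes <- function(beads, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (any(is.na(beads$code_id))) {
    abort("all beads must carry an assigned code; filter unassigned first")
  }
  n_neg <- sum(beads$intensity < 0)
  if (n_neg > 0) {
    inform(paste0("clipped ", n_neg, " negative intensit",
                  if (n_neg == 1) "y" else "ies", " to 0"))
    beads$intensity <- pmax(beads$intensity, 0)
  }
  central <- if (statistic == "mean") mean else median
  spread <- if (statistic == "mean") {
    function(x) if (length(x) > 1) sd(x) else 0
  } else {
    function(x) mad(x, constant = 1)
  }
  beads |>
    group_by(.data$code_id, .data$condition, .data$replicate_id) |>
    summarise(n_beads = n(),
              central_intensity = central(.data$intensity),
              dispersion = spread(.data$intensity),
              .groups = "drop")
}

#' Synthesis-failure quality-control gate
#'
#' Codes whose starting (initial-condition) intensity is indistinguishable
#' from a phosphate-free negative-control peptide are flagged as failed
#' syntheses and excluded from scoring. The threshold is computed from the
#' per-bead intensity distribution of the negative control at the initial
#' condition: `median + sd_multiplier * SD`. A code passes iff its starting
#' central intensity is at or above the threshold.
#'
#' @param beads assigned bead tibble.
#' @param negative_control_code code id of the phosphate-free control.
#' @param sd_multiplier multiplier on the control SD (default 1.5).
#' @param statistic aggregation statistic for the per-code start intensity.
#' @param initial_condition condition value taken as "start"; defaults to
#'   the smallest condition present (time 0).
#' @return tibble: `code_id`, `start_intensity`, `threshold`, `passed`.
#' @export
qc_gate <- function(beads, negative_control_code, sd_multiplier = 1.5,
                    statistic = c("mean", "median"),
                    initial_condition = NULL) {
  statistic <- match.arg(statistic)
  if (is.null(initial_condition)) initial_condition <- min(beads$condition)
  start <- dplyr::filter(beads, .data$condition == initial_condition)
  neg <- dplyr::filter(start, .data$code_id == negative_control_code)
  if (nrow(neg) < 2) {
    abort(paste0("negative-control code '", negative_control_code,
                 "' needs >= 2 beads at the initial condition (found ",
                 nrow(neg), "); the QC gate cannot be computed"))
  }
  threshold <- median(neg$intensity) + sd_multiplier * sd(neg$intensity)
  central <- if (statistic == "mean") mean else median
  start |>
    dplyr::filter(.data$code_id != negative_control_code) |>
    group_by(.data$code_id) |>
    summarise(start_intensity = central(.data$intensity), .groups = "drop") |>
    mutate(threshold = threshold,
           passed = .data$start_intensity >= threshold)
}

#' Join per-code summaries to the peptide library as time courses
#'
#' @param summaries output of [summarize_codes()] where `condition` is time
#'   in minutes.
#' @param library_tbl annotated peptide library.
#' @param enzyme enzyme label to attach.
#' @param keep_codes optional character vector of QC-passing codes; others
#'   are dropped (dropped ids reported).
#' @return long tibble: `peptide_id`, `enzyme`, `replicate_id`, `time`,
#'   `intensity`, ordered by time within each series.
#' @export
build_timecourses <- function(summaries, library_tbl, enzyme = "enzyme",
                              keep_codes = NULL) {
  if (!is.null(keep_codes)) {
    dropped <- setdiff(unique(summaries$code_id), keep_codes)
    if (length(dropped) > 0) {
      inform(paste0("dropping ", length(dropped), " code(s) not in keep_codes"))
    }
    summaries <- dplyr::filter(summaries, .data$code_id %in% keep_codes)
  }
  summaries |>
    inner_join(library_tbl[c("peptide_id", "code_id")], by = "code_id") |>
    mutate(enzyme = enzyme) |>
    select("peptide_id", "enzyme", "replicate_id",
           time = "condition", intensity = "central_intensity") |>
    arrange(.data$peptide_id, .data$replicate_id, .data$time)
}
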