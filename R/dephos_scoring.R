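check_timecourse <- function(time, intensity, n_min = 2) {
  if (length(time) != length(intensity)) abort("time/intensity length mismatch")
  if (any(!is.finite(intensity))) abort("non-finite intensities in time course")
  if (any(diff(time) <= 0)) abort("times must be strictly increasing")
  if (time[1] != 0) abort("time course must include the t = 0 point first")
  if (length(time) < n_min) {
    abort(paste0("time course needs >= ", n_min, " points"))
  }
  invisible(TRUE)
}

#' Dephosphorylation score of one time course
#'
#' The score is one minus the fraction of phosphosignal remaining at the end
#' of the assay: the mean of the last `n_final` intensities divided by the
#' intensity before enzyme addition (t = 0). Larger scores mean more
#' dephosphorylation; a fully dephosphorylated peptide scores 1, an
#' untouched one 0. Scores below 0 (signal increase, a staining artifact)
#' are retained, not clipped, so they stay visible for diagnostics. The
#' score is invariant under rescaling the whole course by a positive
#' constant.
#'
#' @param time numeric vector of times (minutes), starting at 0, increasing.
#' @param intensity per-code central intensities at those times.
#' @param n_final number of final points averaged into the "end" value
#'   (default 3, matching a 0/15/30/60/120/240-minute grid where the signal
#'   has typically plateaued).
#' @return a single numeric score in (-Inf, 1].
#' @export
#' @examples
#' dephos_score(c(0, 15, 30, 60, 120, 240), c(1000, 800, 600, 400, 300, 200))
dephos_score <- function(time, intensity, n_final = 3) {
  check_timecourse(time, intensity, n_min = n_final + 1)
  i0 <- intensity[1]
  if (i0 <= 0) abort("t = 0 intensity must be > 0 for a defined score")
  final <- mean(tail(intensity, n_final))
  1 - final / i0
}

#' Fit a single-exponential decay to a time course
#'
#' Fits `I(t) = C + A * exp(-k * t)` by bounded nonlinear least squares
#' (`minpack.lm::nlsLM`, all three parameters constrained nonnegative).
#' Initial values: `A = I(0) - I(end)`, `C = I(end)`, and `k` from a
#' log-linear regression on baseline-subtracted intensities. The fit is
#' advisory — scores never depend on it — so failure is reported, not
#' raised: `fit_ok` is `FALSE` and the rate `NA` when the solver fails or
#' the rate collapses onto its lower bound (flat signal).
#'
#' @param time,intensity as in [dephos_score()]; at least 4 points.
#' @return list with `A`, `k`, `C`, `rmse`, `fit_ok`.
#' @export
fit_exponential <- function(time, intensity) {
  check_timecourse(time, intensity, n_min = 4)
  i0 <- intensity[1]
  iend <- tail(intensity, 1)
  a0 <- max(i0 - iend, 1e-6)
  c0 <- max(iend, 0)
  # log-linear initial rate from baseline-subtracted values
  sub <- intensity - c0 * 0.99
  pos <- sub > 0 & time >= 0
  k0 <- if (sum(pos) >= 2) {
    sl <- stats::coef(stats::lm(log(sub[pos]) ~ time[pos]))[2]
    max(-sl, 1e-4)
  } else 1e-2
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ C + A * exp(-k * time),
      start = list(A = a0, k = k0, C = c0),
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(A = NA_real_, k = NA_real_, C = NA_real_, rmse = NA_real_,
                fit_ok = FALSE))
  }
  p <- coef(fit)
  rmse <- sqrt(mean(resid(fit)^2))
  # rate pinned at the lower bound means "no resolvable decay"
  k_at_bound <- p[["k"]] < 1e-8
  list(A = unname(p[["A"]]),
       k = if (k_at_bound) NA_real_ else unname(p[["k"]]),
       C = unname(p[["C"]]),
       rmse = rmse,
       fit_ok = !k_at_bound)
}

#' Score and fit every time course in a long table
#'
#' @param tcs long tibble from [build_timecourses()]: `peptide_id`,
#'   `enzyme`, `replicate_id`, `time`, `intensity`.
#' @param n_final passed to [dephos_score()].
#' @param fit also run [fit_exponential()] per series (default TRUE).
#' @return tibble with one row per (peptide, enzyme, replicate): `score`,
#'   and fit columns `A`, `k`, `C`, `rmse`, `fit_ok`.
#' @export
score_timecourses <- function(tcs, n_final = 3, fit = TRUE) {
  tcs |>
    group_by(.data$peptide_id, .data$enzyme, .data$replicate_id) |>
    summarise(
      score = dephos_score(.data$time, .data$intensity, n_final = n_final),
      fitres = list(
        if (fit) fit_exponential(.data$time, .data$intensity)
        else list(A = NA_real_, k = NA_real_, C = NA_real_,
                  rmse = NA_real_, fit_ok = NA)
      ),
      .groups = "drop"
    ) |>
    mutate(A = map_dbl(.data$fitres, "A"),
           k = map_dbl(.data$fitres, "k"),
           C = map_dbl(.data$fitres, "C"),
           rmse = map_dbl(.data$fitres, "rmse"),
           fit_ok = map_lgl(.data$fitres, "fit_ok")) |>
    select(-"fitres")
}

#' Aggregate replicate scores and rates per peptide
#'
#' Reports the mean and standard deviation of dephosphorylation scores
#' across replicates, and — over replicates whose exponential fit succeeded
#' — the mean and SD of the fitted rate. A single-replicate peptide gets
#' `score_sd = 0` and `low_confidence = TRUE`.
#'
#' @param results tibble from [score_timecourses()].
#' @return tibble per (peptide, enzyme): `n_replicates`, `score_mean`,
#'   `score_sd`, `k_mean`, `k_sd`, `n_fit_ok`, `low_confidence`.
#' @export
aggregate_replicates <- function(results) {
  if (nrow(results) == 0) abort("no replicate scores to aggregate")
  results |>
    group_by(.data$peptide_id, .data$enzyme) |>
    summarise(
      n_replicates = n(),
      score_mean = mean(.data$score),
      score_sd = if (n() > 1) sd(.data$score) else 0,
      k_mean = {
        ok <- !is.na(.data$fit_ok) & .data$fit_ok
        if (any(ok)) mean(.data$k[ok]) else NA_real_
      },
      k_sd = {
        ok <- !is.na(.data$fit_ok) & .data$fit_ok
        if (sum(ok) > 1) sd(.data$k[ok]) else NA_real_
      },
      n_fit_ok = sum(.data$fit_ok, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(low_confidence = .data$n_replicates < 2)
}

#' Per-peptide score differences between two enzymes
#'
#' Joins two aggregated score tables on their shared peptide universe and
#' reports the per-peptide difference `delta = score_A - score_B` (e.g. a
#' PP1-minus-B55 differential). Peptides present in only one table are
#' dropped and reported.
#'
#' @param results_a,results_b tibbles from [aggregate_replicates()] (or any
#'   table with `peptide_id` and `score_mean`).
#' @param labels length-2 character used to suffix the score columns.
#' @return tibble: `peptide_id`, `score_<a>`, `score_<b>`, `delta`.
#' @export
differential_matrix <- function(results_a, results_b,
                                labels = c("A", "B")) {
  a <- results_a[c("peptide_id", "score_mean")]
  b <- results_b[c("peptide_id", "score_mean")]
  shared <- intersect(a$peptide_id, b$peptide_id)
  if (length(shared) == 0) abort("no shared peptides between the two tables")
  dropped <- setdiff(union(a$peptide_id, b$peptide_id), shared)
  if (length(dropped) > 0) {
    inform(paste0("dropping ", length(dropped),
                  " peptide(s) absent from one table"))
  }
  out <- inner_join(a, b, by = "peptide_id",
                    suffix = paste0("_", labels))
  names(out) <- c("peptide_id", paste0("score_", labels))
  out$delta <- out[[2]] - out[[3]]
  out
}

#' Group scores by peptide design attributes
#'
#' Convenience layout for acceptor (pS vs pT) and +1-proline comparisons:
#' joins scores to the library annotations and returns per-group means.
#'
#' @param results aggregated score tibble (with `score_mean`).
#' @param library_tbl annotated library.
#' @param by grouping attribute: `"acceptor"` or `"plus1_pro"`.
#' @return tibble of group means, SDs and sizes.
#' @export
score_group_means <- function(results, library_tbl,
                              by = c("acceptor", "plus1_pro")) {
  by <- match.arg(by)
  joined <- inner_join(results, library_tbl, by = "peptide_id") |>
    dplyr::filter(.data$acceptor != "none")
  if (by == "plus1_pro") {
    joined$group <- ifelse(joined$plus1_residue == "P", "+1P", "other")
  } else {
    joined$group <- joined$acceptor
  }
  joined |>
    group_by(.data$group) |>
    summarise(n = n(), score_mean = mean(.data$score_mean),
              score_sd = sd(.data$score_mean), .groups = "drop")
}
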