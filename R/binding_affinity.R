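langmuir <- function(conc, y_max, kd) y_max * conc / (conc + kd)

check_binding_curve <- function(concentration, intensity, n_min = 4) {
  if (length(concentration) != length(intensity)) {
    abort("concentration/intensity length mismatch")
  }
  if (any(!is.finite(intensity))) abort("non-finite intensities in curve")
  if (any(concentration < 0)) abort("concentrations must be >= 0")
  if (any(diff(concentration) <= 0)) {
    abort("concentrations must be strictly increasing")
  }
  if (length(concentration) < n_min) {
    abort(paste0("binding curve needs >= ", n_min, " concentration points"))
  }
  invisible(TRUE)
}

#' Local (two-parameter) Langmuir isotherm fit
#'
#' Fits the single-site saturation model `y = y_max * c / (c + K_d)` to one
#' concentration series, estimating both the saturation intensity `y_max`
#' and the dissociation constant `K_d` by bounded nonlinear least squares.
#' Bounds: `y_max` in (0, 10 x max intensity], `K_d` in [0.01, 1e6] nM.
#' Initialisation: `y_max` at the maximum observed intensity, `K_d` at the
#' concentration whose intensity is nearest half-maximum. The zero-
#' concentration point participates in the fit (the model passes through
#' the origin; there is no nonspecific-binding term).
#'
#' @param concentration strictly increasing concentrations (nM), >= 4 points.
#' @param intensity bound-protein fluorescence at those concentrations.
#' @return list: `y_max`, `kd`, `y_max_fixed = FALSE`, `residual_norm`,
#'   `fit_ok`. A monotonically decreasing curve is flagged `fit_ok = FALSE`
#'   with a warning (no binding signal to fit).
#' @export
fit_langmuir_local <- function(concentration, intensity) {
  check_binding_curve(concentration, intensity)
  failed <- list(y_max = NA_real_, kd = NA_real_, y_max_fixed = FALSE,
                 residual_norm = NA_real_, fit_ok = FALSE)
  if (all(diff(intensity) <= 0) && any(diff(intensity) < 0)) {
    warn("monotonically decreasing curve: no binding signal to fit")
    return(failed)
  }
  ymax0 <- max(intensity)
  if (ymax0 <= 0) {
    warn("all intensities <= 0: nothing to fit")
    return(failed)
  }
  half <- ymax0 / 2
  nz <- concentration > 0
  kd0 <- concentration[nz][which.min(abs(intensity[nz] - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ y_max * concentration / (concentration + kd),
      start = list(y_max = ymax0, kd = kd0),
      lower = c(1e-9, 0.01), upper = c(10 * ymax0, 1e6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn("Langmuir solver failed")
    return(failed)
  }
  p <- coef(fit)
  list(y_max = unname(p[["y_max"]]), kd = unname(p[["kd"]]),
       y_max_fixed = FALSE,
       residual_norm = sqrt(sum(resid(fit)^2)), fit_ok = TRUE)
}

#' Select peptides that saturate at the top assay concentration
#'
#' Saturating peptides anchor the shared `y_max` used for global fitting.
#' In `"absolute"` mode a peptide is saturating when its intensity at the
#' highest concentration exceeds `threshold` (default 12,000, an
#' instrument-scale value); in `"relative"` mode, when that intensity is at
#' or above the `q`-th percentile of all top-concentration intensities —
#' portable across instruments and the sensible default for simulated data.
#'
#' @param curves long tibble: `peptide_id`, `replicate_id`, `concentration`,
#'   `intensity`.
#' @param threshold absolute intensity cutoff (absolute mode).
#' @param mode `"absolute"` or `"relative"`.
#' @param q percentile (0-100) for relative mode.
#' @return character vector of saturating peptide ids. Empty selection is an
#'   error: the shared saturation value would be undefined.
#' @export
select_saturating <- function(curves, threshold = 12000,
                              mode = c("absolute", "relative"), q = 75) {
  mode <- match.arg(mode)
  top <- curves |>
    group_by(.data$peptide_id) |>
    summarise(top_intensity = mean(.data$intensity[
      .data$concentration == max(.data$concentration)]), .groups = "drop")
  sel <- if (mode == "absolute") {
    top$peptide_id[top$top_intensity > threshold]
  } else {
    cutoff <- quantile(top$top_intensity, q / 100, names = FALSE)
    top$peptide_id[top$top_intensity >= cutoff]
  }
  if (length(sel) == 0) {
    abort("no peptide saturates: shared y_max is undefined")
  }
  sel
}

#' Shared saturation intensity across saturating peptides
#'
#' @param local_fits tibble with columns `peptide_id`, `y_max` (local fits).
#' @param saturating character vector from [select_saturating()].
#' @return mean locally fitted `y_max` over the saturating subset.
#' @export
global_ymax <- function(local_fits, saturating) {
  sub <- local_fits$y_max[local_fits$peptide_id %in% saturating &
                            !is.na(local_fits$y_max)]
  if (length(sub) == 0) abort("no local y_max values among saturating peptides")
  mean(sub)
}

#' Global (one-parameter) K_d fit with a frozen saturation value
#'
#' With `y_max` fixed to the experiment-wide shared value, only `K_d`
#' remains free; the one-dimensional least-squares problem is solved by
#' golden-section search on log10(K_d) over [0.01, 1e6] nM. This makes
#' `K_d` identifiable even for weak binders whose curves never approach
#' saturation. Estimates landing above 5 x the top assay concentration are
#' flagged `censored`: the data only support a lower bound on `K_d`.
#'
#' @inheritParams fit_langmuir_local
#' @param shared_ymax frozen saturation intensity (> 0).
#' @return list: `kd`, `y_max`, `y_max_fixed = TRUE`, `residual_norm`,
#'   `censored`, `fit_ok`.
#' @export
fit_kd_global <- function(concentration, intensity, shared_ymax) {
  check_binding_curve(concentration, intensity)
  if (!is.finite(shared_ymax) || shared_ymax <= 0) {
    abort("shared_ymax must be a positive number")
  }
  sse <- function(log10kd) {
    kd <- 10^log10kd
    sum((intensity - langmuir(concentration, shared_ymax, kd))^2)
  }
  opt <- optimize(sse, interval = c(-2, 6), tol = 1e-10)
  kd <- 10^opt$minimum
  at_upper <- opt$minimum > 6 - 1e-6
  censored <- at_upper || kd > 5 * max(concentration)
  list(kd = kd, y_max = shared_ymax, y_max_fixed = TRUE,
       residual_norm = sqrt(opt$objective), censored = censored,
       fit_ok = TRUE)
}

#' Aggregate replicate K_d estimates
#'
#' Default is the arithmetic mean on the nM scale; `"median"` is the robust
#' alternative. With `log_space = TRUE` the aggregation happens on
#' log10(K_d) and is back-transformed (the geometric mean/median), which is
#' less biased when replicate noise is multiplicative. Spread is the SD (or
#' the SD of log10 K_d back-propagated) across replicates.
#'
#' @param kd numeric vector of per-replicate K_d values (nM).
#' @param mode `"mean"` or `"median"`.
#' @param log_space aggregate on the log scale.
#' @return list: `kd_final`, `kd_spread`, `n`.
#' @export
aggregate_kd <- function(kd, mode = c("mean", "median"), log_space = FALSE) {
  mode <- match.arg(mode)
  kd <- kd[is.finite(kd)]
  if (length(kd) == 0) abort("no finite K_d values to aggregate")
  agg <- if (mode == "mean") mean else median
  if (log_space) {
    lk <- log10(kd)
    list(kd_final = 10^agg(lk),
         kd_spread = if (length(kd) > 1) 10^sd(lk) else 0,
         n = length(kd))
  } else {
    list(kd_final = agg(kd),
         kd_spread = if (length(kd) > 1) sd(kd) else 0,
         n = length(kd))
  }
}

#' Binding free-energy difference relative to a reference
#'
#' `ddG = R T ln(K_d,variant / K_d,reference)` in kcal/mol, with
#' `R = 1.9872e-3` kcal/(mol K). Positive values mean weaker binding than
#' the reference (destabilising substitution). The quantity is additive over
#' chained K_d ratios by construction.
#'
#' @param kd_variant,kd_reference dissociation constants (same units), > 0.
#' @param temperature_K absolute temperature; default 298.15 K.
#' @return ddG in kcal/mol (vectorised over `kd_variant`).
#' @export
#' @examples
#' delta_delta_g(1250, 125) # 10x weaker: +1.364 kcal/mol at 298.15 K
delta_delta_g <- function(kd_variant, kd_reference, temperature_K = 298.15) {
  if (any(kd_variant <= 0) || any(kd_reference <= 0)) {
    abort("K_d values must be > 0")
  }
  GAS_CONSTANT_KCAL * temperature_K * log(kd_variant / kd_reference)
}

#' Position-by-residue substitution ddG table
#'
#' Lays out per-peptide ddG values (relative to a designated reference
#' peptide) on a substitution grid: motif-register position x residue.
#' Every non-reference peptide must be annotated with the single
#' substitution it carries (`sub_position`, `sub_residue`; phosphoresidues
#' in lowercase). Cells never measured are absent (`NA`); the reference's
#' own residue at each annotated position scores 0 by definition. Two
#' peptides claiming the same cell is a conflict error.
#'
#' @param affinities tibble: `peptide_id`, `kd_final`, `sub_position`,
#'   `sub_residue` (`NA` for the reference row).
#' @param reference_id peptide id of the reference sequence.
#' @param ref_residues optional named character vector mapping register
#'   position to the reference residue there (adds the zero cells).
#' @param temperature_K passed to [delta_delta_g()].
#' @return tibble: `sub_position`, `sub_residue`, `ddG`, `peptide_id`
#'   (`NA` peptide for reference zero cells).
#' @export
substitution_table <- function(affinities, reference_id, ref_residues = NULL,
                               temperature_K = 298.15) {
  if (!reference_id %in% affinities$peptide_id) {
    abort(paste0("reference peptide '", reference_id, "' not in table"))
  }
  kd_ref <- affinities$kd_final[affinities$peptide_id == reference_id][1]
  variants <- dplyr::filter(affinities, .data$peptide_id != reference_id)
  if (nrow(variants) > 0 &&
      any(is.na(variants$sub_position) | is.na(variants$sub_residue))) {
    abort("every variant needs a sub_position and sub_residue annotation")
  }
  cell <- paste(variants$sub_position, variants$sub_residue)
  if (anyDuplicated(cell)) {
    clash <- cell[duplicated(cell)][1]
    ids <- variants$peptide_id[cell == clash]
    abort(paste0("cell conflict at (position residue) ", clash, ": peptides ",
                 paste(ids, collapse = ", ")))
  }
  out <- tibble(
    sub_position = variants$sub_position,
    sub_residue = variants$sub_residue,
    ddG = delta_delta_g(variants$kd_final, kd_ref, temperature_K),
    peptide_id = variants$peptide_id
  )
  if (!is.null(ref_residues)) {
    zero <- tibble(
      sub_position = as.integer(names(ref_residues)),
      sub_residue = unname(ref_residues),
      ddG = 0, peptide_id = NA_character_
    )
    zero <- anti_join(zero, out, by = c("sub_position", "sub_residue"))
    out <- bind_rows(zero, out)
  }
  arrange(out, .data$sub_position, .data$sub_residue)
}

#' Fit a whole binding panel: local fits, shared y_max, global refits
#'
#' Runs the full affinity workflow on a long curve table: per replicate,
#' local two-parameter fits for every peptide, selection of the saturating
#' subset, the shared `y_max` (mean over that subset), and one-parameter
#' global refits of every peptide; per-replicate K_d values are then
#' aggregated per peptide.
#'
#' @inheritParams select_saturating
#' @param aggregate `"mean"` (default) or `"median"` across replicates.
#' @param log_space aggregate K_d on the log scale.
#' @return list: `affinities` (tibble per peptide: `kd_final`, `kd_spread`,
#'   `n_replicates`, `censored` — TRUE if censored in every replicate),
#'   `per_replicate` (tibble with per-replicate kd and shared y_max),
#'   `shared_ymax` (named per replicate).
#' @export
fit_affinity_panel <- function(curves, threshold = 12000,
                               mode = c("absolute", "relative"), q = 75,
                               aggregate = c("mean", "median"),
                               log_space = FALSE) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  reps <- unique(curves$replicate_id)
  per_rep <- list()
  ymaxes <- c()
  for (r in reps) {
    sub <- dplyr::filter(curves, .data$replicate_id == r)
    locals <- sub |>
      group_by(.data$peptide_id) |>
      summarise(fit = list(fit_langmuir_local(.data$concentration,
                                              .data$intensity)),
                .groups = "drop") |>
      mutate(y_max = map_dbl(.data$fit, "y_max"),
             kd_local = map_dbl(.data$fit, "kd")) |>
      select(-"fit")
    sat <- select_saturating(sub, threshold = threshold, mode = mode, q = q)
    ym <- global_ymax(locals, sat)
    ymaxes[as.character(r)] <- ym
    glob <- sub |>
      group_by(.data$peptide_id) |>
      summarise(gfit = list(fit_kd_global(.data$concentration,
                                          .data$intensity, ym)),
                .groups = "drop") |>
      mutate(kd = map_dbl(.data$gfit, "kd"),
             censored = map_lgl(.data$gfit, "censored")) |>
      select(-"gfit")
    glob$replicate_id <- r
    glob$shared_ymax <- ym
    per_rep[[as.character(r)]] <- left_join(
      glob, locals, by = "peptide_id")
  }
  per_rep <- bind_rows(per_rep)
  affinities <- per_rep |>
    group_by(.data$peptide_id) |>
    summarise(
      agg = list(aggregate_kd(.data$kd, mode = aggregate,
                              log_space = log_space)),
      censored = all(.data$censored),
      .groups = "drop"
    ) |>
    mutate(kd_final = map_dbl(.data$agg, "kd_final"),
           kd_spread = map_dbl(.data$agg, "kd_spread"),
           n_replicates = map_dbl(.data$agg, "n")) |>
    select(-"agg")
  list(affinities = affinities, per_replicate = per_rep,
       shared_ymax = ymaxes)
}
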