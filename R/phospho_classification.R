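#' Normalise TMT reporter intensities across channels
#'
#' Each channel (column) is scaled by its total intensity relative to the
#' mean channel total, so that after adjustment every channel sums to the
#' same value, then log2-transformed. This removes loading differences
#' between multiplexed samples.
#'
#' @param mat numeric matrix, sites x channels, linear-scale intensities.
#' @return matrix of log2 normalised intensities (same dimensions).
#' @export
normalize_tmt <- function(mat) {
  mat <- as.matrix(mat)
  totals <- colSums(mat, na.rm = TRUE)
  if (any(totals <= 0)) {
    bad <- colnames(mat)[totals <= 0] %||% which(totals <= 0)
    abort(paste0("zero or negative total intensity in channel(s): ",
                 paste(bad, collapse = ", ")))
  }
  factors <- totals / mean(totals)
  log2(sweep(mat, 2, factors, "/"))
}

welch_p <- function(x, y) {
  # two-tailed Welch test; degenerate zero-variance cases resolved by the
  # mean difference (identical groups are maximally unsurprising)
  out <- tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
                  error = function(e) NA_real_)
  if (is.na(out)) {
    out <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  }
  out
}

#' Call a regulated phosphosite in one arm
#'
#' A site is regulated when it passes both gates: a two-tailed Welch
#' (unequal-variance) t-test of inhibitor vs control replicates at
#' `p < alpha`, and a log2 fold change (inhibitor minus control means)
#' above `log2fc_min` (default 0.58, i.e. 1.5-fold). The conjunction
#' enforces direction — phosphosites must *increase* when the phosphatase
#' is inhibited — while the test itself stays two-tailed.
#'
#' @param inhibitor,control numeric vectors of log2 intensities
#'   (>= 2 replicates each).
#' @param alpha significance level (default 0.05).
#' @param log2fc_min fold-change gate on the log2 scale (default 0.58).
#' @return list: `log2fc`, `p_value`, `regulated`.
#' @export
call_regulated <- function(inhibitor, control, alpha = 0.05,
                           log2fc_min = 0.58) {
  inhibitor <- inhibitor[is.finite(inhibitor)]
  control <- control[is.finite(control)]
  if (length(inhibitor) < 2 || length(control) < 2) {
    abort("call_regulated needs >= 2 finite replicates per group")
  }
  log2fc <- mean(inhibitor) - mean(control)
  p <- welch_p(inhibitor, control)
  list(log2fc = log2fc, p_value = p,
       regulated = (p < alpha) && (log2fc > log2fc_min))
}

arm_columns <- function(sites, arm, group) {
  cols <- grep(paste0("^", arm, "_", group, "_"), names(sites), value = TRUE)
  if (length(cols) < 2) {
    abort(paste0("need >= 2 replicate columns matching '", arm, "_", group,
                 "_*' (found ", length(cols), ")"))
  }
  cols
}

#' Call regulated sites across a whole table, both arms
#'
#' The site table is wide-format: intensity columns named
#' `<arm>_<group>_<replicate>`, e.g. `PP1_inhibitor_1`, `PP1_control_2`,
#' `B55_inhibitor_3`. Each arm is tested independently with
#' [call_regulated()] and the two arms are combined into a specificity
#' class by [classify_specificity()].
#'
#' @param sites site tibble (`site_id`, `protein_id`, `position`,
#'   `acceptor`, `window`, plus intensity columns).
#' @param arms character vector of arm prefixes (default
#'   `c("PP1", "B55")`).
#' @param alpha,log2fc_min gates passed to [call_regulated()].
#' @return `sites` with, per arm, `<arm>_log2fc`, `<arm>_p`,
#'   `<arm>_regulated`, plus a `class` column.
#' @export
call_regulated_sites <- function(sites, arms = c("PP1", "B55"),
                                 alpha = 0.05, log2fc_min = 0.58) {
  for (arm in arms) {
    inh_cols <- arm_columns(sites, arm, "inhibitor")
    ctl_cols <- arm_columns(sites, arm, "control")
    inh <- as.matrix(sites[inh_cols])
    ctl <- as.matrix(sites[ctl_cols])
    res <- lapply(seq_len(nrow(sites)), function(i) {
      call_regulated(inh[i, ], ctl[i, ], alpha = alpha,
                     log2fc_min = log2fc_min)
    })
    sites[[paste0(arm, "_log2fc")]] <- vapply(res, `[[`, 0, "log2fc")
    sites[[paste0(arm, "_p")]] <- vapply(res, `[[`, 0, "p_value")
    sites[[paste0(arm, "_regulated")]] <- vapply(res, `[[`, TRUE, "regulated")
  }
  if (length(arms) == 2) {
    sites$class <- classify_specificity(
      sites[[paste0(arms[1], "_regulated")]],
      sites[[paste0(arms[2], "_regulated")]],
      labels = arms
    )
  }
  sites
}

#' Phosphatase specificity class from two regulation calls
#'
#' Four-way partition: a site regulated in only one arm is specific to that
#' phosphatase; regulated in both arms is `"ambiguous"`; in neither,
#' `"unregulated"`.
#'
#' @param regulated_a,regulated_b logical vectors (one element per site).
#' @param labels class labels for the two arms.
#' @return character vector of classes.
#' @export
classify_specificity <- function(regulated_a, regulated_b,
                                 labels = c("PP1", "B55")) {
  dplyr::case_when(
    regulated_a & regulated_b ~ "ambiguous",
    regulated_a ~ labels[1],
    regulated_b ~ labels[2],
    .default = "unregulated"
  )
}

#' Class, acceptor and overlap summary statistics
#'
#' @param calls output of [call_regulated_sites()] (needs `class` and
#'   `acceptor` columns).
#' @return list: `class_counts` (named), `overlap_fraction` (ambiguous
#'   among all regulated), `acceptor_percent` (tibble: class x acceptor
#'   percentage).
#' @export
summary_statistics <- function(calls) {
  class_counts <- table(factor(calls$class,
                               levels = c(setdiff(unique(calls$class),
                                                  c("ambiguous", "unregulated")),
                                          "ambiguous", "unregulated")))
  regulated <- calls$class != "unregulated"
  overlap <- if (sum(regulated) > 0) {
    sum(calls$class == "ambiguous") / sum(regulated)
  } else NA_real_
  acceptor_percent <- calls |>
    group_by(.data$class, .data$acceptor) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(percent = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  list(class_counts = c(class_counts), overlap_fraction = overlap,
       acceptor_percent = acceptor_percent)
}

#' Downshifted-normal imputation of missing label-free intensities
#'
#' Missing values in each sample (column) are drawn from a normal
#' distribution centred `downshift` standard deviations below that sample's
#' observed mean, with width `width_factor` times the observed SD — the
#' standard model for intensities missing because they fell below the
#' detection limit. Reproducible under `seed`.
#'
#' @param mat numeric matrix, proteins x samples, log-scale intensities with
#'   `NA` for missing; each column needs >= 10 observed values.
#' @param width_factor imputation width as a fraction of the sample SD
#'   (default 0.3).
#' @param downshift centre shift in sample SDs (default 1.8).
#' @param seed integer seed.
#' @return completed matrix (no `NA`).
#' @export
impute_missing <- function(mat, width_factor = 0.3, downshift = 1.8,
                           seed = 1L) {
  mat <- as.matrix(mat)
  set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    obs <- mat[, j][is.finite(mat[, j])]
    miss <- which(!is.finite(mat[, j]))
    if (length(obs) == 0) {
      abort(paste0("sample column ", j, " is entirely missing"))
    }
    if (length(miss) == 0) next
    if (length(obs) < 10) {
      abort(paste0("sample column ", j, " has < 10 observed values; ",
                   "imputation parameters would be unstable"))
    }
    mu <- mean(obs); sigma <- sd(obs)
    mat[miss, j] <- rnorm(length(miss), mu - downshift * sigma,
                          width_factor * sigma)
  }
  mat
}

#' Call bait-specific interactors from enrichment tables
#'
#' A protein is an interactor of a bait when its (imputed, log2) intensity
#' is enriched over the control by at least `fold_min` and a two-tailed
#' Welch t-test gives `p < alpha`. Calls are per bait and method; the union
#' over methods forms the bait's interactome.
#'
#' @param tbl tibble with `protein_id`, `bait`, `method` and replicate
#'   intensity columns `bait_1..` and `ctrl_1..` (log2 scale, imputed).
#' @param fold_min minimum fold enrichment (linear scale; default 2).
#' @param alpha significance level (default 0.05).
#' @return `tbl` plus `log2_enrichment`, `p_value`, `interactor`.
#' @export
call_interactors <- function(tbl, fold_min = 2, alpha = 0.05) {
  bait_cols <- grep("^bait_", names(tbl), value = TRUE)
  ctrl_cols <- grep("^ctrl_", names(tbl), value = TRUE)
  if (length(bait_cols) < 2 || length(ctrl_cols) < 2) {
    abort("need >= 2 bait_* and >= 2 ctrl_* replicate columns")
  }
  b <- as.matrix(tbl[bait_cols]); ctl <- as.matrix(tbl[ctrl_cols])
  enr <- rowMeans(b) - rowMeans(ctl)
  p <- vapply(seq_len(nrow(tbl)), function(i) welch_p(b[i, ], ctl[i, ]),
              numeric(1))
  tbl$log2_enrichment <- enr
  tbl$p_value <- p
  tbl$interactor <- (enr >= log2(fold_min)) & (p < alpha)
  tbl
}

#' Union interactome per bait across methods
#'
#' @param interactors output of [call_interactors()].
#' @return tibble `bait`, `protein_id` of proteins called in any method.
#' @export
interactome_union <- function(interactors) {
  interactors |>
    dplyr::filter(.data$interactor) |>
    distinct(.data$bait, .data$protein_id)
}

#' Count regulated sites on interacting proteins
#'
#' Joins regulated-site calls to a bait's interactome by protein id and
#' reports, per bait, how many of that phosphatase's specific sites sit on
#' interacting proteins (and the complement on non-interactors, useful as a
#' motif-contrast background). Site protein ids can be translated into the
#' interactome namespace with a two-column `mapping` table
#' (`from`, `to`); unmapped proteins are excluded and counted.
#'
#' @param calls classified site table (`class`, `protein_id`, `site_id`).
#' @param interactome tibble from [interactome_union()].
#' @param mapping optional tibble with columns `from`, `to`.
#' @param class_for_bait named character: which site class pairs with which
#'   bait (default `c(PP1 = "PP1", B55 = "B55")`).
#' @return list: `counts` (tibble bait, n_regulated, n_on_interactors,
#'   n_off_interactors, n_unmapped), `sites_on_interactors` (site listing).
#' @export
join_sites_interactome <- function(calls, interactome, mapping = NULL,
                                   class_for_bait = c(PP1 = "PP1",
                                                      B55 = "B55")) {
  calls <- calls[c("site_id", "protein_id", "class")]
  n_unmapped <- 0L
  if (!is.null(mapping)) {
    calls <- left_join(calls, mapping, by = c(protein_id = "from"))
    n_unmapped <- sum(is.na(calls$to))
    if (n_unmapped > 0) {
      inform(paste0(n_unmapped, " site protein id(s) had no mapping; excluded"))
    }
    calls <- calls |>
      dplyr::filter(!is.na(.data$to)) |>
      mutate(protein_id = .data$to) |>
      select(-"to")
  }
  counts <- lapply(names(class_for_bait), function(bait) {
    cls <- class_for_bait[[bait]]
    reg <- dplyr::filter(calls, .data$class == cls)
    inter <- interactome$protein_id[interactome$bait == bait]
    on <- reg$protein_id %in% inter
    tibble(bait = bait, n_regulated = nrow(reg),
           n_on_interactors = sum(on), n_off_interactors = sum(!on),
           n_unmapped = n_unmapped)
  }) |> bind_rows()
  on_sites <- lapply(names(class_for_bait), function(bait) {
    cls <- class_for_bait[[bait]]
    inter <- interactome$protein_id[interactome$bait == bait]
    calls |>
      dplyr::filter(.data$class == cls, .data$protein_id %in% inter) |>
      mutate(bait = bait)
  }) |> bind_rows()
  list(counts = counts, sites_on_interactors = on_sites)
}
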