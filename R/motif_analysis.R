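#' Extract a centred sequence window around a phosphosite
#'
#' Returns the `2 * flank + 1`-residue window centred on `position`,
#' padding with `"_"` where the flank runs past a terminus. The centre
#' residue must be S, T or Y (case-insensitive, so canonical phospho
#' notation is accepted).
#'
#' @param sequence protein sequence (one-letter codes).
#' @param position 1-based position of the phosphosite.
#' @param flank residues on each side (default 7, giving 15-mers).
#' @return character window of length `2 * flank + 1`, uppercase, with
#'   `"_"` padding.
#' @export
#' @examples
#' extract_window("MKKSPQR", 4, flank = 2)
extract_window <- function(sequence, position, flank = 7) {
  n <- nchar(sequence)
  if (position < 1 || position > n) abort("position outside sequence")
  centre <- toupper(substr(sequence, position, position))
  if (!centre %in% c("S", "T", "Y")) {
    abort(paste0("centre residue at ", position, " is '", centre,
                 "', not S/T/Y"))
  }
  lo <- position - flank
  hi <- position + flank
  core <- toupper(substr(sequence, max(lo, 1), min(hi, n)))
  paste0(strrep(PAD_CHAR, max(0, 1 - lo)), core,
         strrep(PAD_CHAR, max(0, hi - n)))
}

window_offsets <- function(width) {
  flank <- (width - 1) / 2
  seq(-flank, flank)
}

#' Position-specific residue frequencies of a window set
#'
#' Counts residues per window position over non-pad symbols and normalises
#' each position to sum to 1. Optionally weights each position by its
#' information content (`log2(20)` minus the positional entropy), the
#' standard display transform for sequence logos.
#'
#' @param windows character vector of equal-length, odd-length windows.
#' @param information_content return frequencies scaled by positional
#'   information content instead of raw frequencies.
#' @return numeric matrix, positions (rownames `-k..k`) x 20 residues.
#' @export
frequency_logo <- function(windows, information_content = FALSE) {
  if (length(windows) == 0) abort("need at least one window")
  widths <- unique(nchar(windows))
  if (length(widths) != 1) abort("windows have mixed lengths")
  if (widths %% 2 != 1) abort("windows must have odd length")
  chars <- matrix(unlist(strsplit(toupper(windows), "")),
                  nrow = length(windows), byrow = TRUE)
  offs <- window_offsets(widths)
  freq <- matrix(0, nrow = widths, ncol = length(AA20),
                 dimnames = list(offs, AA20))
  for (j in seq_len(widths)) {
    col <- chars[, j]
    col <- col[col != PAD_CHAR]
    if (length(col) == 0) next
    tab <- table(factor(col, levels = AA20))
    freq[j, ] <- as.numeric(tab) / length(col)
  }
  if (information_content) {
    ic <- apply(freq, 1, function(f) {
      nz <- f[f > 0]
      log2(20) + sum(nz * log2(nz))
    })
    freq <- freq * ic
  }
  freq
}

two_prop_z <- function(x1, n1, x2, n2) {
  # pooled two-proportion z-test, two-sided, no continuity correction
  p_pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  if (!is.finite(se) || se == 0) return(1)
  z <- (x1 / n1 - x2 / n2) / se
  2 * pnorm(-abs(z))
}

#' Residue enrichment logo: foreground vs background windows
#'
#' For every (position, residue) cell, compares the foreground frequency to
#' the background frequency: the enrichment score is the frequency
#' difference (positive = enriched, negative = deselected), the fold change
#' uses Laplace smoothing with `pseudocount` (default `1/(n_fg + 20)`), and
#' significance comes from a two-sided two-proportion z-test (Fisher's
#' exact test selectable). Cells with `p >= alpha` are marked not
#' significant rather than dropped, so deselection is reported
#' symmetrically. Pad symbols never enter the counts. No multiple-testing
#' correction is applied by default; `adjust = "BH"` switches the
#' significance mask to Benjamini-Hochberg-adjusted p-values.
#'
#' @param foreground,background character vectors of equal-length windows.
#' @param alpha significance level for the display mask.
#' @param pseudocount smoothing constant for the fold layer.
#' @param test `"z"` (default) or `"fisher"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return tibble: `position`, `residue`, `f_fg`, `f_bg`, `enrichment`,
#'   `fold`, `p_value`, `significant`.
#' @export
enrichment_logo <- function(foreground, background, alpha = 0.05,
                            pseudocount = NULL, test = c("z", "fisher"),
                            adjust = c("none", "BH")) {
  test <- match.arg(test)
  adjust <- match.arg(adjust)
  if (length(foreground) == 0 || length(background) == 0) {
    abort("foreground and background must both be nonempty")
  }
  if (length(background) < 20) {
    warn("background has < 20 windows; enrichment estimates are unstable")
  }
  w <- unique(nchar(c(foreground, background)))
  if (length(w) != 1) abort("foreground/background window lengths differ")
  if (is.null(pseudocount)) pseudocount <- 1 / (length(foreground) + 20)
  fg_chars <- matrix(unlist(strsplit(toupper(foreground), "")),
                     nrow = length(foreground), byrow = TRUE)
  bg_chars <- matrix(unlist(strsplit(toupper(background), "")),
                     nrow = length(background), byrow = TRUE)
  offs <- window_offsets(w)
  rows <- list()
  for (j in seq_len(w)) {
    fg_col <- fg_chars[, j]; fg_col <- fg_col[fg_col != PAD_CHAR]
    bg_col <- bg_chars[, j]; bg_col <- bg_col[bg_col != PAD_CHAR]
    n_fg <- length(fg_col); n_bg <- length(bg_col)
    fg_tab <- table(factor(fg_col, levels = AA20))
    bg_tab <- table(factor(bg_col, levels = AA20))
    for (aa in AA20) {
      x1 <- fg_tab[[aa]]; x2 <- bg_tab[[aa]]
      f1 <- if (n_fg > 0) x1 / n_fg else 0
      f2 <- if (n_bg > 0) x2 / n_bg else 0
      p <- if (n_fg == 0 || n_bg == 0) 1
           else if (test == "z") two_prop_z(x1, n_fg, x2, n_bg)
           else fisher.test(matrix(c(x1, n_fg - x1, x2, n_bg - x2), 2))$p.value
      rows[[length(rows) + 1]] <- tibble(
        position = offs[j], residue = aa, f_fg = f1, f_bg = f2,
        enrichment = f1 - f2,
        fold = (f1 + pseudocount) / (f2 + pseudocount),
        p_value = p
      )
    }
  }
  out <- bind_rows(rows)
  p_mask <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$significant <- p_mask < alpha
  out
}

#' Is a window proline-directed?
#'
#' TRUE iff the residue immediately C-terminal of the central phosphosite
#' is proline. A terminal (padded) +1 position is FALSE.
#'
#' @param window odd-length window string (or vector of them).
#' @return logical vector.
#' @export
classify_proline_directed <- function(window) {
  w <- nchar(window)
  centre <- (w + 1) / 2
  toupper(substr(window, centre + 1, centre + 1)) == "P"
}

rvxf_patterns <- function(strict = FALSE, no_proline = TRUE) {
  pos1 <- if (strict) "R" else "[RK]"
  posV <- if (strict) "V" else "[VI]"
  posF <- if (strict) "F" else "[FW]"
  wild <- if (no_proline) "[ACDEFGHIKLMNQRSTVWY]" else "[ACDEFGHIKLMNPQRSTVWY]"
  list(RVxF = paste0(pos1, posV, wild, posF),
       RxVxF = paste0(pos1, wild, posV, wild, posF))
}

#' Scan a protein sequence for RVxF-class docking motifs
#'
#' The motif architecture is Rx(0-1)VxF: a basic residue, an optional
#' wildcard, a branched hydrophobic, a wildcard, and an aromatic. The
#' default alphabet is the degenerate one used for motif discovery —
#' `[RK]`, `[VI]`, `[FW]` — with proline disallowed at wildcard positions
#' (`no_proline = TRUE`); `strict = TRUE` restricts the anchor residues to
#' the literal letters R, V, F. All overlapping matches of both the 4-mer
#' (RVxF) and 5-mer (RxVxF) forms are reported. Lowercase phospho notation
#' is honoured: phosphosites falling at offsets -1..+4 of a match are
#' listed with it. An `X` in the sequence never matches any slot.
#'
#' @param sequence protein or peptide sequence (canonical phospho notation
#'   allowed).
#' @param strict literal R/V/F anchors instead of the degenerate alphabet.
#' @param no_proline disallow proline at wildcard positions.
#' @return tibble: `start`, `end` (1-based inclusive), `matched_text`,
#'   `variant` (`"RVxF"` or `"RxVxF"`), `phospho_inside` (list column of
#'   positions).
#' @export
#' @examples
#' scan_rvxf("AKNSRVTFSEDDEII")
#' scan_rvxf("AKNRAVTFSEDDEII")
scan_rvxf <- function(sequence, strict = FALSE, no_proline = TRUE) {
  upper <- toupper(sequence)
  ppos <- phospho_positions(sequence)
  pats <- rvxf_patterns(strict = strict, no_proline = no_proline)
  rows <- list()
  for (variant in names(pats)) {
    width <- if (variant == "RVxF") 4L else 5L
    hits <- gregexpr(paste0("(?=", pats[[variant]], ")"), upper,
                     perl = TRUE)[[1]]
    if (hits[1] == -1) next
    for (s in as.integer(hits)) {
      e <- s + width - 1L
      inside <- ppos[ppos >= s - 1L & ppos <= s + 4L]
      rows[[length(rows) + 1]] <- tibble(
        start = s, end = e,
        matched_text = substr(upper, s, e),
        variant = variant,
        phospho_inside = list(inside)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(start = integer(), end = integer(),
                  matched_text = character(), variant = character(),
                  phospho_inside = list()))
  }
  arrange(bind_rows(rows), .data$start, .data$end)
}

#' Scan every sequence of a FASTA proteome for RVxF-class motifs
#'
#' @param fasta_path path to a protein FASTA file.
#' @inheritParams scan_rvxf
#' @return tibble as from [scan_rvxf()] with a leading `protein_id` column.
#' @export
scan_proteome <- function(fasta_path, strict = FALSE, no_proline = TRUE) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  res <- lapply(seq_along(seqs), function(i) {
    m <- scan_rvxf(as.character(seqs[[i]]), strict = strict,
                   no_proline = no_proline)
    if (nrow(m) > 0) m$protein_id <- sub("\\s.*", "", names(seqs)[i])
    m
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) return(out)
  select(out, "protein_id", dplyr::everything())
}

#' Predict a variant's ddG from a substitution table, assuming additivity
#'
#' Compares a query sequence to the reference it is registered against and
#' sums the substitution table's ddG cells for every deviating position
#' (lowercase phosphoresidues are distinct from their unmodified letters,
#' so phosphorylation is "a substitution" with its own cell). Multi-term
#' sums are flagged `additivity_assumed`; deviations without a measured
#' cell make the prediction `partial`.
#'
#' @param query,reference equal-length sequences in canonical notation.
#' @param sub_table tibble from [substitution_table()].
#' @param positions register labels for the sequence positions (default
#'   `1..nchar`); must match the table's `sub_position` convention.
#' @return list: `ddG`, `n_terms`, `partial`, `additivity_assumed`,
#'   `missing_cells` (tibble of unmeasured deviations).
#' @export
predict_motif_ddg <- function(query, reference, sub_table,
                              positions = seq_len(nchar(reference))) {
  if (nchar(query) != nchar(reference)) {
    abort("query and reference must have equal length (registered alignment)")
  }
  q <- strsplit(query, "")[[1]]
  r <- strsplit(reference, "")[[1]]
  dev <- which(q != r)
  if (length(dev) == 0) {
    return(list(ddG = 0, n_terms = 0L, partial = FALSE,
                additivity_assumed = FALSE,
                missing_cells = tibble(sub_position = integer(),
                                       sub_residue = character())))
  }
  total <- 0; n_terms <- 0L
  missing <- list()
  for (i in dev) {
    cell <- dplyr::filter(sub_table, .data$sub_position == positions[i],
                          .data$sub_residue == q[i])
    if (nrow(cell) == 1 && is.finite(cell$ddG)) {
      total <- total + cell$ddG
      n_terms <- n_terms + 1L
    } else {
      missing[[length(missing) + 1]] <- tibble(sub_position = positions[i],
                                               sub_residue = q[i])
    }
  }
  list(ddG = total, n_terms = n_terms,
       partial = length(missing) > 0,
       additivity_assumed = n_terms > 1,
       missing_cells = if (length(missing)) bind_rows(missing)
                       else tibble(sub_position = integer(),
                                   sub_residue = character()))
}

#' Stratify a protein's phosphosites by motif region
#'
#' Splits sites on one protein into `"near"` and `"far"` groups relative to
#' its docking motif(s), either by a fixed residue boundary (default: sites
#' at positions `<= boundary` are near, inclusive — the convention for a
#' single N-terminal motif on a very large protein) or by radial distance
#' from the nearest motif midpoint (`mode = "radial"`, `cutoff` residues).
#' With no motif present every site is `"far"` and a warning is raised.
#'
#' @param sites tibble with `position` (and typically `window`, `acceptor`).
#' @param matches motif matches for the protein (from [scan_rvxf()]).
#' @param boundary fixed boundary (default 1000).
#' @param mode `"boundary"` or `"radial"`.
#' @param cutoff radial cutoff in residues (radial mode).
#' @return `sites` with a `region` column (`"near"`/`"far"`).
#' @export
stratify_by_motif_distance <- function(sites, matches, boundary = 1000,
                                       mode = c("boundary", "radial"),
                                       cutoff = 500) {
  mode <- match.arg(mode)
  if (nrow(matches) == 0) {
    warn("no motif match: all sites classed 'far'")
    sites$region <- "far"
    return(sites)
  }
  if (mode == "boundary") {
    sites$region <- ifelse(sites$position <= boundary, "near", "far")
  } else {
    mids <- (matches$start + matches$end) / 2
    d <- vapply(sites$position, function(p) min(abs(p - mids)), numeric(1))
    sites$region <- ifelse(d <= cutoff, "near", "far")
  }
  sites
}

#' Per-region composition summary for stratified sites
#'
#' @param sites output of [stratify_by_motif_distance()] with `acceptor`
#'   and `window` columns.
#' @return tibble per region: site count, acceptor percentages, fraction
#'   proline-directed.
#' @export
region_composition <- function(sites) {
  sites |>
    group_by(.data$region) |>
    summarise(
      n = n(),
      pct_S = 100 * mean(.data$acceptor == "S"),
      pct_T = 100 * mean(.data$acceptor == "T"),
      frac_plus1_pro = mean(classify_proline_directed(.data$window)),
      .groups = "drop"
    )
}
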