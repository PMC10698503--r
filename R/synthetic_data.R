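#' Simulation configuration with planted ground truth parameters
#'
#' Collects every knob of the synthetic-data generators. Defaults emulate
#' the assay design the analysis modules were built for: a 0/15/30/60/120/
#' 240-minute dephosphorylation time grid, a 0-2,000 nM nine-point titration
#' grid, ~55 beads per spectral code over 96 codes, lognormal per-bead
#' starting intensities, multiplicative (CV) plus additive intensity noise,
#' a 5% failed-synthesis code fraction, threonine dephosphorylated ~3x
#' faster than serine with a strong +1-proline penalty, and a
#' phosphoproteome with 10%/20%/2% PP1-/B55-/dually-regulated sites whose
#' sequence windows carry class-specific positional biases.
#'
#' @param seed integer seed; the same seed yields identical outputs.
#' @param ... overrides for any default element (nested lists are replaced
#'   wholesale).
#' @return a named list (class `sim_config`).
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_codes = 96,
    beads_per_code = 55,
    lanthanide_channels = 4,
    lanthanide_jitter = 0.02,      # SD as fraction of inter-code spacing
    time_grid = c(0, 15, 30, 60, 120, 240),
    conc_grid = c(0, 15, 31, 62, 125, 250, 500, 1000, 2000),
    start_intensity = list(meanlog = log(10000), sdlog = 0.25),
    baseline = 500,                # plateau / background intensity C
    noise = list(cv = 0.05, additive_sd = 100),
    failed_code_fraction = 0.05,
    rate_model = list(base = 0.012,      # 1/min, pS in a neutral context
                      pT = 3,            # threonine multiplier
                      plus1_pro = 0.3,   # +1 proline penalty
                      basic_context = 1.8,   # K/R at -2 or -3
                      acidic_plus2 = 0.5),   # D/E at +2
    kd_model = list(kd_ref = 125,        # nM, reference peptide
                    y_max = 15000,
                    noise_frac = 0.03,   # additive SD as fraction of y_max
                    temperature_K = 298.15),
    proteome_model = list(n_proteins = 250,
                          n_sites = 5000,
                          frac_pp1 = 0.10, frac_b55 = 0.20, frac_both = 0.02,
                          effect_log2 = 2.0, effect_sd = 0.3,
                          replicate_sd = 0.25,
                          n_replicates = 3,
                          base_log2 = 20, base_sd = 2),
    interactome_model = list(n_proteins = 400,
                             frac_interactors = 0.05,
                             effect_log2 = 2, noise_sd = 0.5,
                             n_replicates = 3,
                             missing_rate = 0.15)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("unknown sim_config element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "sim_config")
}

#' Reference spectral code table
#'
#' Lays `n_codes` reference lanthanide-ratio vectors on a regular grid in
#' `[0, 1]^L` so that inter-code spacing is uniform and decoding is
#' unambiguous at the configured jitter.
#'
#' @param n_codes number of codes.
#' @param channels number of lanthanide ratio channels L.
#' @return tibble: `code_id`, `l1..lL`; attribute `spacing` holds the grid
#'   step.
#' @export
make_code_table <- function(n_codes, channels = 4) {
  levels_per <- ceiling(n_codes^(1 / channels))
  vals <- seq(0, 1, length.out = max(levels_per, 2))
  grid <- as.matrix(expand.grid(rep(list(vals), channels)))[seq_len(n_codes), ,
                                                            drop = FALSE]
  out <- as_tibble(grid, .name_repair = ~ paste0("l", seq_len(channels)))
  out <- bind_cols(tibble(code_id = sprintf("code_%03d", seq_len(n_codes))),
                   out)
  attr(out, "spacing") <- vals[2] - vals[1]
  out
}

#' True dephosphorylation rate implied by a peptide's sequence context
#'
#' Multiplicative rate model: a base pS rate modified by acceptor identity,
#' +1 proline, basic residues at -2/-3 and acidic residues at +2.
#' Unphosphorylated peptides get rate 0.
#'
#' @param lib annotated library tibble.
#' @param rate_model list as in [sim_config()]`$rate_model`.
#' @return numeric vector of rates (1/min), one per peptide.
#' @export
true_dephos_rates <- function(lib, rate_model) {
  vapply(seq_len(nrow(lib)), function(i) {
    if (lib$acceptor[i] == "none") return(0)
    k <- rate_model$base
    if (lib$acceptor[i] == "pT") k <- k * rate_model$pT
    if (!is.na(lib$plus1_residue[i]) && lib$plus1_residue[i] == "P") {
      k <- k * rate_model$plus1_pro
    }
    chars <- toupper(strsplit(lib$sequence[i], "")[[1]])
    pp <- lib$phospho_position[i]
    ctx <- function(off) {
      j <- pp + off
      if (j >= 1 && j <= length(chars)) chars[j] else ""
    }
    if (ctx(-2) %in% c("K", "R") || ctx(-3) %in% c("K", "R")) {
      k <- k * rate_model$basic_context
    }
    if (ctx(2) %in% c("D", "E")) k <- k * rate_model$acidic_plus2
    k
  }, numeric(1))
}

sim_beads_for_code <- function(code_row, code_id, n_beads, values_fn,
                               conditions, replicate_id, cfg, id_offset) {
  rows <- list()
  for (ci in seq_along(conditions)) {
    clean <- values_fn(conditions[ci])
    per_bead <- clean * (1 + rnorm(n_beads, 0, cfg$noise$cv)) +
      rnorm(n_beads, 0, cfg$noise$additive_sd)
    lv <- matrix(rep(unlist(code_row, use.names = FALSE), each = n_beads),
                 nrow = n_beads)
    lv <- lv + matrix(rnorm(length(lv), 0,
                            cfg$lanthanide_jitter * attr_spacing(cfg)),
                      nrow = n_beads)
    df <- as_tibble(lv, .name_repair = ~ paste0("l", seq_along(code_row)))
    df$bead_id <- sprintf("bead_%07d", id_offset + (ci - 1) * n_beads +
                            seq_len(n_beads))
    df$intensity <- pmax(per_bead, 0)
    df$condition <- conditions[ci]
    df$replicate_id <- replicate_id
    df$sample_id <- paste0("rep", replicate_id)
    df$true_code <- code_id
    rows[[ci]] <- df
  }
  bind_rows(rows)
}

attr_spacing <- function(cfg) {
  # grid spacing of the code table implied by the config
  levels_per <- ceiling(cfg$n_codes^(1 / cfg$lanthanide_channels))
  1 / (max(levels_per, 2) - 1)
}

#' Simulate a dephosphorylation bead experiment with planted kinetics
#'
#' Emits a per-bead intensity table over the configured time grid. Each
#' peptide's signal follows `I(t) = C + A_bead * exp(-k_peptide * t)` with
#' per-bead lognormal starting amplitudes, a shared baseline plateau, and
#' multiplicative plus additive noise. A random `failed_code_fraction` of
#' phosphopeptide codes is planted as failed syntheses (signal drawn from
#' the background level at all times, like the phosphate-free negative
#' control).
#'
#' @param config a [sim_config()].
#' @param library_tbl annotated library; defaults to [dephos_panel()] sized
#'   to `config$n_codes - 1` phosphopeptides plus the control.
#' @param n_replicates number of independent replicates.
#' @return list: `beads` (tibble with lanthanide columns, `intensity`,
#'   `condition` = time, `replicate_id`, `true_code`), `codes`
#'   (reference table), `library`, `truth` (list: `rates` tibble, `failed`
#'   code ids, `negative_control_code`, `baseline`).
#' @export
simulate_dephos <- function(config = sim_config(), library_tbl = NULL,
                            n_replicates = 3) {
  set.seed(config$seed)
  if (is.null(library_tbl)) library_tbl <- dephos_panel(config$n_codes - 1)
  codes <- make_code_table(nrow(library_tbl), config$lanthanide_channels)
  library_tbl$code_id <- codes$code_id
  rates <- true_dephos_rates(library_tbl, config$rate_model)
  ctrl_code <- library_tbl$code_id[library_tbl$acceptor == "none"][1]
  phospho_codes <- setdiff(library_tbl$code_id, ctrl_code)
  n_failed <- round(config$failed_code_fraction * length(phospho_codes))
  failed <- sample(phospho_codes, n_failed)
  lcols <- lanthanide_cols(codes)
  all_rows <- list()
  offset <- 0
  for (rep_i in seq_len(n_replicates)) {
    for (i in seq_len(nrow(library_tbl))) {
      cid <- library_tbl$code_id[i]
      n_beads <- max(rpois(1, config$beads_per_code), 2)
      is_bg <- cid == ctrl_code || cid %in% failed
      A <- rlnorm(1, config$start_intensity$meanlog,
                  config$start_intensity$sdlog)
      k <- rates[i]
      values_fn <- if (is_bg) {
        function(t) config$baseline
      } else {
        function(t) config$baseline + A * exp(-k * t)
      }
      all_rows[[length(all_rows) + 1]] <- sim_beads_for_code(
        codes[i, lcols], cid, n_beads, values_fn, config$time_grid,
        rep_i, config, offset)
      offset <- offset + n_beads * length(config$time_grid)
    }
  }
  beads <- bind_rows(all_rows)
  list(
    beads = beads, codes = codes, library = library_tbl,
    truth = list(
      rates = tibble(peptide_id = library_tbl$peptide_id,
                     code_id = library_tbl$code_id, k = rates),
      failed = failed,
      negative_control_code = ctrl_code,
      baseline = config$baseline
    )
  )
}

#' RVxF variant panel with planted substitution ddG truths
#'
#' Builds the reference docking peptide `AKNSRVTFSEDDEII` plus single-
#' substitution variants at positions around and inside the motif
#' (register: RVxF core at 5-8). Each variant's true ddG is drawn once
#' (seeded) from a uniform distribution, except proline inside the core,
#' which is planted strongly destabilising; phosphoserine/-threonine
#' substitutions (lowercase) get their own cells.
#'
#' @param seed integer seed for the planted truths.
#' @param positions register positions to mutate.
#' @param residues substitution alphabet (lowercase = phosphoresidue).
#' @param ddg_range uniform range (kcal/mol) for ordinary substitutions.
#' @param proline_range uniform range for core prolines.
#' @return list: `panel` (tibble `peptide_id`, `sequence`, `sub_position`,
#'   `sub_residue`, `ddg_true`), `reference_id`, `reference` sequence.
#' @export
rvxf_variant_panel <- function(seed = 1L,
                               positions = 4:9,
                               residues = c("A", "D", "E", "G", "K", "L",
                                            "P", "Q", "s", "t"),
                               ddg_range = c(-0.5, 2.0),
                               proline_range = c(2.0, 3.0)) {
  set.seed(seed)
  reference <- "AKNSRVTFSEDDEII"
  ref_chars <- strsplit(reference, "")[[1]]
  rows <- list(tibble(peptide_id = "ref", sequence = reference,
                      sub_position = NA_integer_, sub_residue = NA_character_,
                      ddg_true = 0))
  for (pos in positions) {
    for (res in residues) {
      if (toupper(res) == ref_chars[pos]) next
      s <- ref_chars
      s[pos] <- res
      core <- pos >= 5 && pos <= 8
      ddg <- if (res == "P" && core) runif(1, proline_range[1], proline_range[2])
             else runif(1, ddg_range[1], ddg_range[2])
      rows[[length(rows) + 1]] <- tibble(
        peptide_id = paste0("var_", pos, res),
        sequence = paste(s, collapse = ""),
        sub_position = as.integer(pos), sub_residue = res,
        ddg_true = ddg
      )
    }
  }
  panel <- bind_rows(rows)
  list(panel = panel, reference_id = "ref", reference = reference)
}

#' Simulate a concentration-titration binding experiment
#'
#' Emits Langmuir-shaped binding curves on the configured concentration
#' grid for an RVxF variant panel. True dissociation constants are composed
#' from the reference K_d and each variant's planted ddG via
#' `K_d = K_ref * exp(ddG / RT)`; intensities get additive Gaussian noise
#' with SD `noise_frac * y_max`.
#'
#' @param config a [sim_config()].
#' @param panel optional panel list from [rvxf_variant_panel()]; defaults
#'   to one generated with the config's seed.
#' @param n_replicates number of replicates.
#' @return list: `curves` (tibble `peptide_id`, `replicate_id`,
#'   `concentration`, `intensity`), `panel`, `truth` (tibble `peptide_id`,
#'   `kd_true`, `ddg_true`; plus `y_max`, `kd_ref`, `reference_id`).
#' @export
simulate_binding <- function(config = sim_config(), panel = NULL,
                             n_replicates = 3) {
  set.seed(config$seed)
  if (is.null(panel)) panel <- rvxf_variant_panel(seed = config$seed)
  km <- config$kd_model
  rt <- GAS_CONSTANT_KCAL * km$temperature_K
  kd_true <- km$kd_ref * exp(panel$panel$ddg_true / rt)
  curves <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (i in seq_len(nrow(panel$panel))) {
      clean <- langmuir(config$conc_grid, km$y_max, kd_true[i])
      noisy <- clean + rnorm(length(clean), 0, km$noise_frac * km$y_max)
      curves[[length(curves) + 1]] <- tibble(
        peptide_id = panel$panel$peptide_id[i],
        replicate_id = rep_i,
        concentration = config$conc_grid,
        intensity = noisy
      )
    }
  }
  list(
    curves = bind_rows(curves),
    panel = panel,
    truth = list(
      kd = tibble(peptide_id = panel$panel$peptide_id, kd_true = kd_true,
                  ddg_true = panel$panel$ddg_true),
      y_max = km$y_max, kd_ref = km$kd_ref,
      reference_id = panel$reference_id
    )
  )
}

random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

apply_window_bias <- function(chars, pos, class) {
  # class-specific positional biases written into the protein sequence
  if (class %in% c("PP1", "ambiguous")) {
    if (runif(1) < 0.40) chars[pos - 2] <- sample(c("K", "R"), 1)
    if (runif(1) < 0.40) chars[pos - 3] <- sample(c("K", "R"), 1)
  }
  if (class %in% c("B55", "ambiguous")) {
    if (runif(1) < 0.50) chars[pos + 1] <- "P"
    if (chars[pos + 2] %in% c("D", "E") && runif(1) < 0.8) {
      chars[pos + 2] <- sample(setdiff(AA20, c("D", "E")), 1)
    }
  }
  chars
}

#' Simulate a phosphoproteomic screen with planted regulation classes
#'
#' Builds a synthetic proteome (random sequences), plants phosphosites with
#' class-specific sequence signatures (PP1-regulated: threonine-tolerant
#' with basic residues enriched at -2/-3; B55-regulated: +1 proline
#' enriched, acidic +2 deselected), and emits a wide TMT-style site table
#' with triplicate inhibitor/control intensities per arm. Regulated sites
#' gain a planted log2 effect in the matching arm's inhibitor channels.
#' Also emits a label-free interactor table (with intensity-dependent
#' missingness for imputation) and one long protein carrying a single RVxF
#' motif near its N terminus, with phosphoserine/basic-context sites
#' planted before residue 1,000 and phosphothreonine sites after, for the
#' motif-distance stratification analysis.
#'
#' @param config a [sim_config()].
#' @param fasta_path optional path; if given, the proteome is written there
#'   as FASTA.
#' @return list: `sites` (wide tibble ready for
#'   [call_regulated_sites()]), `proteins` (named character vector),
#'   `interactors` (tibble for [call_interactors()], per bait),
#'   `truth` (list: per-site `class_true`, interactor flags, the long
#'   protein's id and motif coordinates).
#' @export
simulate_phosphoproteome <- function(config = sim_config(),
                                     fasta_path = NULL) {
  set.seed(config$seed)
  pm <- config$proteome_model
  n_sites <- pm$n_sites
  per_protein <- ceiling(n_sites / pm$n_proteins)
  prot_len <- 20 * (per_protein + 1)
  proteins <- stats::setNames(
    vapply(seq_len(pm$n_proteins), function(i) random_protein(prot_len),
           character(1)),
    sprintf("prot_%04d", seq_len(pm$n_proteins))
  )
  # planted classes
  classes <- sample(c(
    rep("PP1", round(pm$frac_pp1 * n_sites)),
    rep("B55", round(pm$frac_b55 * n_sites)),
    rep("ambiguous", round(pm$frac_both * n_sites)),
    rep("unregulated",
        n_sites - round(pm$frac_pp1 * n_sites) -
          round(pm$frac_b55 * n_sites) - round(pm$frac_both * n_sites))
  ))
  site_rows <- list()
  idx <- 1
  prot_chars <- lapply(proteins, function(p) strsplit(p, "")[[1]])
  for (i in seq_len(n_sites)) {
    prot_i <- ((i - 1) %% pm$n_proteins) + 1
    slot <- ((i - 1) %/% pm$n_proteins) + 1
    pos <- 20 * slot
    cls <- classes[i]
    # acceptor: regulated PP1 sites are threonine-rich, background mostly Ser
    p_thr <- switch(cls, PP1 = 0.42, B55 = 0.35, ambiguous = 0.40, 0.25)
    acc <- if (runif(1) < p_thr) "T" else "S"
    ch <- prot_chars[[prot_i]]
    ch[pos] <- acc
    ch <- apply_window_bias(ch, pos, cls)
    prot_chars[[prot_i]] <- ch
    site_rows[[idx]] <- tibble(
      site_id = sprintf("site_%05d", i),
      protein_id = names(proteins)[prot_i],
      position = pos, acceptor = acc,
      localized = TRUE, multiplicity = "single",
      unique_protein_match = TRUE,
      class_true = cls
    )
    idx <- idx + 1
  }
  sites <- bind_rows(site_rows)
  proteins <- stats::setNames(
    vapply(prot_chars, paste, character(1), collapse = ""),
    names(proteins))
  sites$window <- vapply(seq_len(nrow(sites)), function(i) {
    extract_window(proteins[[sites$protein_id[i]]], sites$position[i])
  }, character(1))
  # intensities: base level + arm-specific planted effects
  base <- rnorm(nrow(sites), pm$base_log2, pm$base_sd)
  effect <- rnorm(nrow(sites), pm$effect_log2, pm$effect_sd)
  for (arm in c("PP1", "B55")) {
    hit <- sites$class_true %in% c(arm, "ambiguous")
    for (r in seq_len(pm$n_replicates)) {
      sites[[paste0(arm, "_control_", r)]] <-
        base + rnorm(nrow(sites), 0, pm$replicate_sd)
      sites[[paste0(arm, "_inhibitor_", r)]] <-
        base + ifelse(hit, effect, 0) + rnorm(nrow(sites), 0, pm$replicate_sd)
    }
  }
  # long protein with one N-terminal RVxF motif; near sites pS with basic
  # context, far sites pT (for the stratification contrast)
  long_id <- "prot_long"
  long_chars <- strsplit(random_protein(3000), "")[[1]]
  long_chars[504:508] <- c("R", "A", "V", "S", "F")
  long_sites <- list()
  for (j in 1:40) {
    near <- j <= 20
    pos <- if (near) 100 + 20 * j else 1400 + 30 * (j - 20)
    long_chars[pos] <- if (near) "S" else "T"
    if (near) {
      long_chars[pos - 2] <- "K"
      long_chars[pos - 3] <- "R"
    }
    long_sites[[j]] <- tibble(
      site_id = sprintf("site_long_%02d", j), protein_id = long_id,
      position = pos, acceptor = if (near) "S" else "T",
      localized = TRUE, multiplicity = "single",
      unique_protein_match = TRUE, class_true = "PP1"
    )
  }
  long_sites <- bind_rows(long_sites)
  long_seq <- paste(long_chars, collapse = "")
  long_sites$window <- vapply(seq_len(nrow(long_sites)), function(i) {
    extract_window(long_seq, long_sites$position[i])
  }, character(1))
  lb <- rnorm(nrow(long_sites), pm$base_log2, pm$base_sd)
  le <- rnorm(nrow(long_sites), pm$effect_log2, pm$effect_sd)
  for (arm in c("PP1", "B55")) {
    for (r in seq_len(pm$n_replicates)) {
      long_sites[[paste0(arm, "_control_", r)]] <-
        lb + rnorm(nrow(long_sites), 0, pm$replicate_sd)
      long_sites[[paste0(arm, "_inhibitor_", r)]] <-
        lb + (if (arm == "PP1") le else 0) +
        rnorm(nrow(long_sites), 0, pm$replicate_sd)
    }
  }
  proteins <- c(proteins, stats::setNames(long_seq, long_id))
  sites <- bind_rows(sites, long_sites)
  # label-free interactome with planted true interactors and MNAR holes
  im <- config$interactome_model
  inter_rows <- list()
  truth_inter <- list()
  for (bait in c("PP1", "B55")) {
    prot_ids <- c(sample(names(proteins), min(im$n_proteins / 2,
                                              length(proteins))),
                  sprintf("bg_%s_%03d", bait,
                          seq_len(im$n_proteins -
                                    min(im$n_proteins / 2, length(proteins)))))
    is_true <- runif(length(prot_ids)) < im$frac_interactors
    base_i <- rnorm(length(prot_ids), 22, 2)
    tbl <- tibble(protein_id = prot_ids, bait = bait, method = "AP-MS")
    for (r in seq_len(im$n_replicates)) {
      b <- base_i + ifelse(is_true, im$effect_log2, 0) +
        rnorm(length(prot_ids), 0, im$noise_sd)
      ctl <- base_i + rnorm(length(prot_ids), 0, im$noise_sd)
      # intensity-dependent (MNAR) missingness: low values drop out more
      pm_b <- stats::plogis(-(b - (22 - 2)) ) * im$missing_rate * 4
      pm_c <- stats::plogis(-(ctl - (22 - 2))) * im$missing_rate * 4
      b[runif(length(b)) < pm_b] <- NA
      ctl[runif(length(ctl)) < pm_c] <- NA
      tbl[[paste0("bait_", r)]] <- b
      tbl[[paste0("ctrl_", r)]] <- ctl
    }
    inter_rows[[bait]] <- tbl
    truth_inter[[bait]] <- tibble(protein_id = prot_ids, bait = bait,
                                  interactor_true = is_true)
  }
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), fasta_path)
  }
  list(
    sites = sites,
    proteins = proteins,
    interactors = bind_rows(inter_rows),
    truth = list(
      classes = sites[c("site_id", "class_true")],
      interactors = bind_rows(truth_inter),
      long_protein = long_id,
      motif_range = c(504, 508),
      near_far_boundary = 1000
    )
  )
}
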