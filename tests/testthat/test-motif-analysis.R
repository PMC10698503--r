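test_that("window extraction centres the site and pads termini", {
  expect_equal(extract_window("MKKSPQR", 4, flank = 2), "KKSPQ")
  expect_equal(extract_window("SKKPQ", 1, flank = 2), "__SKK")
  expect_equal(extract_window("MKKSP", 4, flank = 2), "KKSP_")
  expect_error(extract_window("MKKSPQR", 2, flank = 2), "not S/T/Y")
  expect_error(extract_window("MKKS", 9), "outside")
  # lowercase phospho notation is accepted at the centre
  expect_equal(extract_window("MKKsPQR", 4, flank = 1), "KSP")
})

test_that("frequency logos are column-normalised and pad-blind", {
  f1 <- frequency_logo("KKSPQ")
  expect_equal(sum(f1["0", ]), 1)
  expect_equal(f1["0", "S"], 1)

  f2 <- frequency_logo(c("KKSAQ", "KKSRQ"))
  expect_equal(f2["1", "A"], 0.5)
  expect_equal(f2["1", "R"], 0.5)
  expect_true(all(abs(rowSums(f2) - 1) < 1e-12))

  # pads do not distort: a fully padded flank column sums to zero
  f3 <- frequency_logo(c("__SKK", "__SRK"))
  expect_equal(sum(f3["-2", ]), 0)
  expect_error(frequency_logo(c("KKSPQ", "KKSP")), "mixed lengths")
})

test_that("uniformly drawn windows have near-maximal positional entropy", {
  set.seed(6)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  wins <- replicate(1000, {
    w <- sample(aa, 5, replace = TRUE)
    w[3] <- "S"
    paste(w, collapse = "")
  })
  f <- frequency_logo(wins)
  ent <- -sum(ifelse(f["2", ] > 0, f["2", ] * log2(f["2", ]), 0))
  expect_gt(ent, log2(20) - 0.15)
})

test_that("a set enriched against itself is null everywhere", {
  set.seed(7)
  wins <- replicate(60, paste(c(sample(LETTERS[LETTERS %in% c("A", "K", "R", "D")],
                                       2, TRUE), "S",
                                sample(c("P", "A", "G", "E"), 2, TRUE)),
                              collapse = ""))
  el <- enrichment_logo(wins, wins)
  expect_true(all(el$enrichment == 0))
  expect_true(all(el$fold == 1))
  expect_true(all(!el$significant))
})

test_that("an extreme +1 proline signature is maximally enriched", {
  set.seed(8)
  AA <- c("A", "G", "K", "D")
  fg <- replicate(100, paste(c(sample(AA, 2, TRUE),
                               "S", "P",
                               sample(AA, 1)), collapse = ""))
  bg <- replicate(100, paste(c(sample(AA, 2, TRUE), "S",
                               sample(c("P", "A", "G", "E"), 1),
                               sample(AA, 1)), collapse = ""))
  el <- enrichment_logo(fg, bg)
  cell <- el[el$position == 1 & el$residue == "P", ]
  expect_gt(cell$enrichment, 0.5)
  expect_lt(cell$p_value, 1e-10)
  expect_true(cell$significant)
})

test_that("planted -2/-3 basic enrichment is detected with the right sign", {
  set.seed(10)
  aa <- c("A", "G", "Q", "E", "L", "V")
  make <- function(p_basic) {
    replicate(500, {
      w <- sample(aa, 7, replace = TRUE)
      w[4] <- "S"
      if (runif(1) < p_basic) w[2] <- sample(c("K", "R"), 1)
      if (runif(1) < p_basic) w[1] <- sample(c("K", "R"), 1)
      paste(w, collapse = "")
    })
  }
  fg <- make(0.40)
  bg <- make(0.10)
  el <- enrichment_logo(fg, bg)
  basic <- el[el$position %in% c(-2, -3) & el$residue %in% c("K", "R"), ]
  expect_true(all(basic$enrichment > 0))
  expect_true(any(basic$significant))
  # effect size ~ 0.15 per residue per position, within binomial CI
  expect_equal(sum(basic$enrichment), 2 * 0.30, tolerance = 0.1)
})

test_that("two-proportion z p-values rank like Fisher's exact test", {
  set.seed(11)
  p_z <- c(); p_f <- c()
  for (i in 1:60) {
    x1 <- sample(0:12, 1); x2 <- sample(0:12, 1)
    n1 <- 40; n2 <- 40
    p_z <- c(p_z, phosbead:::two_prop_z(x1, n1, x2, n2))
    p_f <- c(p_f, fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), 2))$p.value)
  }
  expect_gt(cor(p_z, p_f, method = "spearman"), 0.95)
})

test_that("proline-directed classification reads the +1 slot", {
  expect_true(classify_proline_directed("KKTPQ"))
  expect_false(classify_proline_directed("KKTAQ"))
  expect_false(classify_proline_directed("KKT__"))  # terminal site
})

test_that("RVxF scanning finds the canonical reference motifs", {
  ref <- scan_rvxf("AKNSRVTFSEDDEII")
  expect_equal(nrow(ref), 1)
  expect_equal(ref$start, 5L)
  expect_equal(ref$end, 8L)
  expect_equal(ref$matched_text, "RVTF")
  expect_equal(ref$variant, "RVxF")

  var <- scan_rvxf("AKNRAVTFSEDDEII")
  expect_equal(nrow(var), 1)
  expect_equal(var$start, 4L)
  expect_equal(var$end, 8L)
  expect_equal(var$variant, "RxVxF")

  # proline rule and strict-alphabet toggles
  expect_equal(nrow(scan_rvxf("RPVAF")), 0)
  strict_noP <- scan_rvxf("RPVAF", strict = TRUE, no_proline = FALSE)
  expect_equal(strict_noP$variant, "RxVxF")
  # degenerate alphabet admits K/I/W anchors; strict mode does not
  expect_equal(nrow(scan_rvxf("AKIAW")), 1)
  expect_equal(nrow(scan_rvxf("AKIAW", strict = TRUE)), 0)
  # X never matches, even at wildcard slots
  expect_equal(nrow(scan_rvxf("RVXF")), 0)
})

test_that("phosphosites near a match are annotated with it", {
  m <- scan_rvxf("AKNsRVTFsEDDEII")
  expect_equal(m$phospho_inside[[1]], c(4L, 9L))
})

test_that("the scanner equals the brute-force oracle on random sequences", {
  set.seed(12)
  for (i in 1:500) {
    sq <- paste(sample(c(phosbead:::AA20, "X"), 30, replace = TRUE),
                collapse = "")
    strict <- i %% 2 == 0
    nop <- i %% 3 > 0
    got <- scan_rvxf(sq, strict = strict, no_proline = nop)
    want <- oracle_scan_rvxf(sq, strict = strict, no_proline = nop)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      ord <- order(want[, 1], want[, 2])
      expect_equal(got$start, want[ord, 1])
      expect_equal(got$end, want[ord, 2])
    }
  }
})

test_that("additive ddG prediction sums measured cells and flags gaps", {
  st <- tibble::tibble(
    sub_position = c(4L, 6L), sub_residue = c("E", "K"),
    ddG = c(1.0, 1.0), peptide_id = c("v1", "v2")
  )
  ref <- "AKNSRVTFSEDDEII"
  expect_equal(predict_motif_ddg(ref, ref, st)$ddG, 0)

  one <- predict_motif_ddg("AKNERVTFSEDDEII", ref, st)
  expect_equal(one$ddG, 1.0)
  expect_false(one$additivity_assumed)
  expect_false(one$partial)

  two <- predict_motif_ddg("AKNERKTFSEDDEII", ref, st)
  expect_equal(two$ddG, 2.0)
  expect_true(two$additivity_assumed)

  gap <- predict_motif_ddg("AKNWRVTFSEDDEII", ref, st)
  expect_true(gap$partial)
  expect_equal(gap$missing_cells$sub_residue, "W")
})

test_that("motif-distance stratification partitions sites", {
  m <- tibble::tibble(start = 504L, end = 508L, matched_text = "RVTFA",
                      variant = "RxVxF", phospho_inside = list(integer()))
  sites <- tibble::tibble(position = c(300, 1000, 1500),
                          acceptor = c("S", "S", "T"),
                          window = c("KKKSAAA", "AAASAAA", "AAATPAA"))
  out <- stratify_by_motif_distance(sites, m, boundary = 1000)
  expect_equal(out$region, c("near", "near", "far"))  # boundary inclusive
  expect_setequal(unique(out$region), c("near", "far"))

  rad <- stratify_by_motif_distance(sites, m, mode = "radial", cutoff = 250)
  expect_equal(rad$region, c("near", "far", "far"))

  expect_warning(none <- stratify_by_motif_distance(sites, m[0, ]), "no motif")
  expect_true(all(none$region == "far"))
})

test_that("planted near/far composition contrast is recovered", {
  sim <- simulate_phosphoproteome(small_sim_config(
    seed = 19, proteome_model = list(
      n_proteins = 30, n_sites = 300, frac_pp1 = 0.1, frac_b55 = 0.2,
      frac_both = 0.02, effect_log2 = 2.0, effect_sd = 0.3,
      replicate_sd = 0.25, n_replicates = 3, base_log2 = 20, base_sd = 2)))
  long <- sim$sites[sim$sites$protein_id == sim$truth$long_protein, ]
  m <- scan_rvxf(sim$proteins[[sim$truth$long_protein]])
  expect_true(any(m$start == sim$truth$motif_range[1]))
  strat <- stratify_by_motif_distance(long, m,
                                      boundary = sim$truth$near_far_boundary)
  comp <- region_composition(strat)
  expect_equal(comp$pct_S[comp$region == "near"], 100)
  expect_equal(comp$pct_T[comp$region == "far"], 100)
  # near windows carry the planted basic context
  near_logo <- frequency_logo(strat$window[strat$region == "near"])
  expect_gt(near_logo["-2", "K"], 0.9)
})

test_that("proteome FASTA scanning returns per-protein matches", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "AKNSRVTFSEDDEII", ">p2", "GGGGGGGG"), path)
  hits <- scan_proteome(path)
  expect_equal(unique(hits$protein_id), "p1")
  expect_equal(hits$start, 5L)
})
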