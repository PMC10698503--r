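test_that("TMT normalisation equalises channel totals", {
  m <- matrix(c(10, 30, 5, 15), 2, dimnames = list(NULL, c("c1", "c2")))
  # totals 40 and 20: the low channel is scaled up 2x relative to the high one
  out <- normalize_tmt(m)
  expect_equal(2^out[, "c2"], c(5, 15) * 30 / 20)
  expect_equal((2^out[, "c2"]) / (2^out[, "c1"]),
               2 * c(5, 15) / c(10, 30))
  lin <- 2^out
  expect_equal(colSums(lin)[[1]], colSums(lin)[[2]], tolerance = 1e-9)

  # equal totals: identity up to log2 (and the global rescale of 1)
  m2 <- matrix(c(10, 30, 25, 15), 2)
  expect_equal(normalize_tmt(m2), log2(m2))

  # random tables equalise to 1e-9 relative
  set.seed(2)
  m3 <- matrix(rlnorm(600, 10, 1), 100, 6)
  lin3 <- 2^normalize_tmt(m3)
  expect_lt(diff(range(colSums(lin3))) / mean(colSums(lin3)), 1e-9)

  expect_error(normalize_tmt(matrix(c(1, 1, 0, 0), 2,
                                    dimnames = list(NULL, c("a", "bad")))),
               "bad")
})

test_that("Welch p-values match the hand-coded t/df formula to 1e-10", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(sample(3:6, 1), 5, runif(1, 0.1, 2))
    y <- rnorm(sample(3:6, 1), 5.5, runif(1, 0.1, 2))
    got <- call_regulated(x, y, alpha = 1, log2fc_min = -Inf)
    expect_equal(got$p_value, oracle_welch(x, y)$p, tolerance = 1e-10)
  }
})

test_that("the conjunctive gate requires both significance and fold change", {
  # zero fold change: never regulated
  r0 <- call_regulated(c(5.0, 5.1, 4.9), c(5.0, 5.0, 5.0))
  expect_equal(r0$log2fc, 0)
  expect_false(r0$regulated)

  # clear 2-fold effect: regulated, p agrees with the oracle
  r1 <- call_regulated(c(6.0, 6.1, 5.9), c(5.0, 5.1, 4.9))
  expect_equal(r1$log2fc, 1)
  expect_lt(r1$p_value, 0.05)
  expect_equal(r1$p_value,
               oracle_welch(c(6.0, 6.1, 5.9), c(5.0, 5.1, 4.9))$p,
               tolerance = 1e-10)
  expect_true(r1$regulated)

  # significant but sub-threshold fold: rejected by the gate
  r2 <- call_regulated(c(5.50, 5.51, 5.49), c(5.0, 5.01, 4.99))
  expect_lt(r2$p_value, 0.05)
  expect_false(r2$regulated)

  # zero variance in both groups with equal means: p = 1
  r3 <- call_regulated(c(5, 5, 5), c(5, 5, 5))
  expect_equal(r3$p_value, 1)
  expect_false(r3$regulated)

  expect_error(call_regulated(1, c(1, 2)), ">= 2")
})

test_that("Welch p-values rank like an exact permutation oracle", {
  set.seed(9)
  n_sites <- 40
  p_welch <- numeric(n_sites)
  p_perm <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    eff <- sample(c(0, 0.5, 1, 2), 1)
    x <- rnorm(5, 5 + eff, 0.5)
    y <- rnorm(5, 5, 0.5)
    p_welch[i] <- call_regulated(x, y, alpha = 1, log2fc_min = -Inf)$p_value
    p_perm[i] <- oracle_permutation_p(x, y)
  }
  expect_gt(cor(p_welch, p_perm, method = "spearman"), 0.95)
})

test_that("specificity classes partition sites four ways", {
  expect_equal(classify_specificity(TRUE, FALSE), "PP1")
  expect_equal(classify_specificity(FALSE, TRUE), "B55")
  expect_equal(classify_specificity(TRUE, TRUE), "ambiguous")
  expect_equal(classify_specificity(FALSE, FALSE), "unregulated")
})

test_that("planted class proportions are recovered on a simulated table", {
  cfg <- sim_config(seed = 13)
  cfg$proteome_model$n_sites <- 1500
  sim <- simulate_phosphoproteome(cfg)
  calls <- call_regulated_sites(sim$sites)
  # four classes partition the evaluated sites
  expect_equal(sum(table(calls$class)), nrow(calls))
  core <- calls[!grepl("long", calls$site_id), ]
  truth <- sim$truth$classes[!grepl("long", sim$truth$classes$site_id), ]
  n <- nrow(core)
  for (cls in c("PP1", "B55", "ambiguous")) {
    p_true <- mean(truth$class_true == cls)
    p_hat <- mean(core$class == cls)
    # within binomial error (3 SE) of the planted fraction
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n) + 1e-9)
  }
})

test_that("the global null produces no spurious inflation of p-values", {
  cfg <- sim_config(seed = 17)
  cfg$proteome_model$n_sites <- 2000
  cfg$proteome_model$frac_pp1 <- 0
  cfg$proteome_model$frac_b55 <- 0
  cfg$proteome_model$frac_both <- 0
  sim <- simulate_phosphoproteome(cfg)
  core <- sim$sites[!grepl("long", sim$sites$site_id), ]
  calls <- call_regulated_sites(core)
  rate <- mean(calls$PP1_p < 0.05)
  # the rate never exceeds alpha (no inflation); at triplicate depth the
  # Welch approximation is mildly conservative, so the rate sits below 0.05
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(core)))
  expect_gt(rate, 0.02)
  # and the fold gate keeps the called-regulated rate far below alpha
  expect_lt(mean(calls$PP1_regulated), 0.02)
})

test_that("summary statistics report counts, acceptors and overlap", {
  calls <- tibble::tibble(
    class = c("PP1", "PP1", "PP1", "B55", "B55", "ambiguous"),
    acceptor = c("S", "S", "S", "T", "S", "S")
  )
  st <- summary_statistics(calls)
  expect_equal(st$overlap_fraction, 1 / 6)
  expect_equal(st$class_counts[["PP1"]], 3)
  pp1 <- st$acceptor_percent[st$acceptor_percent$class == "PP1", ]
  expect_equal(pp1$percent, 100)  # all-Ser class
})

test_that("downshifted-normal imputation is calibrated and reproducible", {
  m <- matrix(rnorm(200, 20, 2), 100, 2)
  expect_identical(impute_missing(m, seed = 3), m)  # nothing missing

  set.seed(44)
  big <- matrix(rnorm(20000, 20, 2), ncol = 2)
  holes <- big
  holes[sample(length(holes), 10000)] <- NA
  done <- impute_missing(holes, seed = 3)
  imputed <- done[is.na(holes)]
  obs <- holes[, 1][!is.na(holes[, 1])]
  expect_equal(mean(imputed), mean(obs) - 1.8 * sd(obs), tolerance = 0.05)
  expect_equal(sd(imputed), 0.3 * sd(obs), tolerance = 0.05)
  # determinism under the seed
  expect_identical(done, impute_missing(holes, seed = 3))
  expect_false(identical(done, impute_missing(holes, seed = 4)))

  allmiss <- matrix(NA_real_, 20, 1)
  expect_error(impute_missing(allmiss), "entirely missing")
})

test_that("interactor calls apply the fold and significance gates jointly", {
  tbl <- tibble::tibble(
    protein_id = c("p1", "p2"), bait = "PP1", method = "AP-MS",
    bait_1 = c(24.0, 24.0), bait_2 = c(24.1, 22.0), bait_3 = c(23.9, 26.0),
    ctrl_1 = c(22.0, 22.0), ctrl_2 = c(22.1, 24.0), ctrl_3 = c(21.9, 20.0)
  )
  out <- call_interactors(tbl)
  # p1: 4-fold, tight -> interactor; p2: 4-fold but noisy p -> not
  expect_true(out$interactor[1])
  expect_gt(out$p_value[2], 0.05)
  expect_false(out$interactor[2])
})

test_that("planted interactors are detected with sensitivity >= 0.8", {
  set.seed(23)
  n <- 600
  is_true <- runif(n) < 0.05
  base <- rnorm(n, 22, 2)
  tbl <- tibble::tibble(protein_id = sprintf("p%03d", seq_len(n)),
                        bait = "PP1", method = "AP-MS")
  for (r in 1:3) {
    tbl[[paste0("bait_", r)]] <- base + ifelse(is_true, 2, 0) + rnorm(n, 0, 0.5)
    tbl[[paste0("ctrl_", r)]] <- base + rnorm(n, 0, 0.5)
  }
  out <- call_interactors(tbl)
  expect_gt(mean(out$interactor[is_true]), 0.8)
  # false-call rate among nulls consistent with the conjunctive gate
  expect_lt(mean(out$interactor[!is_true]), 0.05)
})

test_that("site-interactome joins count exactly, with mapping bookkeeping", {
  calls <- tibble::tibble(
    site_id = c("s1", "s2", "s3"),
    protein_id = c("pa", "pb", "pc"),
    class = "PP1"
  )
  inter <- tibble::tibble(bait = "PP1", protein_id = c("pa", "pb"))
  j <- join_sites_interactome(calls, inter,
                              class_for_bait = c(PP1 = "PP1"))
  expect_equal(j$counts$n_on_interactors, 2)
  expect_equal(j$counts$n_off_interactors, 1)

  # empty interactome -> zero joins
  j0 <- join_sites_interactome(calls, inter[0, ],
                               class_for_bait = c(PP1 = "PP1"))
  expect_equal(j0$counts$n_on_interactors, 0)

  # unmapped proteins are excluded and counted
  mapping <- tibble::tibble(from = c("pa", "pb"), to = c("A", "B"))
  inter2 <- tibble::tibble(bait = "PP1", protein_id = "A")
  expect_message(
    j2 <- join_sites_interactome(calls, inter2, mapping = mapping,
                                 class_for_bait = c(PP1 = "PP1")),
    "no mapping")
  expect_equal(j2$counts$n_unmapped, 1)
  expect_equal(j2$counts$n_on_interactors, 1)
})

test_that("simulated regulated-site/interactome joins match the bookkeeping", {
  cfg <- sim_config(seed = 29)
  cfg$proteome_model$n_sites <- 800
  sim <- simulate_phosphoproteome(cfg)
  truth <- dplyr::inner_join(sim$sites[c("site_id", "protein_id")],
                             sim$truth$classes, by = "site_id")
  inter_true <- sim$truth$interactors |>
    dplyr::filter(interactor_true) |>
    dplyr::select("bait", "protein_id")
  j <- join_sites_interactome(
    dplyr::rename(truth, class = "class_true"), inter_true)
  # oracle: direct count over the ground-truth tables
  for (bait in c("PP1", "B55")) {
    expected <- sum(truth$class_true == bait &
                      truth$protein_id %in%
                        inter_true$protein_id[inter_true$bait == bait])
    expect_equal(j$counts$n_on_interactors[j$counts$bait == bait], expected)
  }
})
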