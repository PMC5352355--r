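# Three-level qPCR caller: delta-Ct arithmetic, cutoffs, subtype panel,
# integrated calls.

test_that("marker delta-Ct arithmetic and censoring sentinels", {
  expect_equal(as.numeric(delta_ct_marker(30, 24, 26)), 5.0)
  expect_equal(as.numeric(delta_ct_marker(24, 24, 24)), 0.0)
  cens <- delta_ct_marker(NA, 24, 26, max_ct = 40)
  expect_equal(as.numeric(cens), 15.0)
  expect_true(attr(cens, "censored"))
  qc <- delta_ct_marker(30, NA, 26)
  expect_true(is.na(as.numeric(qc)))
  expect_true(attr(qc, "qc_fail"))
})

test_that("3'/5' imbalance delta-Ct arithmetic and censoring sentinels", {
  expect_equal(as.numeric(delta_ct_imbalance(25, 32)), -7.0)
  expect_equal(as.numeric(delta_ct_imbalance(30, 30)), 0.0)
  cens <- delta_ct_imbalance(26, NA, max_ct = 40)
  expect_equal(as.numeric(cens), -14.0)
  expect_true(attr(cens, "censored"))
  und <- delta_ct_imbalance(NA, NA)
  expect_true(is.na(as.numeric(und)))
  expect_true(attr(und, "undefined"))
})

test_that("combined score is the plain sum", {
  expect_equal(combined_score(5, -7), -2)
  expect_equal(combined_score(0, 0), 0)
  expect_equal(combined_score(15, 0), 15)
})

test_that("delta-Ct metrics are invariant to per-sample Ct shifts and
           monotone in the marker Ct", {
  # a global efficiency shift adds a constant to every Ct of a sample
  expect_equal(as.numeric(delta_ct_marker(30 + 2.5, 24 + 2.5, 26 + 2.5)),
               as.numeric(delta_ct_marker(30, 24, 26)))
  expect_equal(as.numeric(delta_ct_imbalance(25 + 2.5, 32 + 2.5)),
               as.numeric(delta_ct_imbalance(25, 32)))
  # decreasing the marker Ct strictly decreases marker delta-Ct and combined
  cts <- seq(36, 20, by = -2)
  dm <- as.numeric(delta_ct_marker(cts, 24, 26))
  expect_true(all(diff(dm) < 0))
  expect_true(all(diff(combined_score(dm, -3)) < 0))
})

test_that("cutoff choice: separable midpoint, degraded fallback, Youden grid", {
  scores <- c(-3, -2, -1, 12, 13, 14)
  labels <- rep(c("positive", "negative"), each = 3)
  cut <- choose_cutoff(scores, labels)
  expect_equal(as.numeric(cut), (-1 + 12) / 2)
  expect_true(attr(cut, "separable"))

  same <- choose_cutoff(c(1, 2, 3, 1, 2, 3), labels)
  expect_true(attr(same, "degraded"))
  expect_equal(as.numeric(same), 2)

  expect_error(choose_cutoff(1:5, rep("negative", 5)),
               class = "alkscreen_validation_error")

  # overlapping Gaussians: the chosen threshold attains the empirical-J
  # maximum found by a fine-grid brute-force search
  set.seed(23)
  pos <- rnorm(200, -2, 1.5)
  neg <- rnorm(200, 2, 1.5)
  cut <- choose_cutoff(c(pos, neg), rep(c("positive", "negative"), each = 200))
  jfun <- function(cc) mean(pos < cc) + mean(neg >= cc) - 1
  grid <- seq(min(pos, neg) - 1, max(pos, neg) + 1, length.out = 20000)
  expect_equal(jfun(as.numeric(cut)), max(sapply(grid, jfun)),
               tolerance = 1e-12)
  # and lands near the analytic crossover of the two densities (x = 0)
  expect_lt(abs(as.numeric(cut)), 0.5)
})

test_that("subtype calling applies Ct ceiling, Tm gate and tie rules", {
  panel <- default_panel()
  mk <- function(targets, ct, tm) {
    data.frame(sample_id = "S1", target_id = targets, ct = ct, tm = tm,
               stringsAsFactors = FALSE)
  }
  tm_of <- function(p) panel$expected_tm[panel$pair_id == p]

  one <- call_subtype(mk("KIF5B_P1", 28, tm_of("KIF5B_P1") + 0.2), panel)
  expect_equal(one$variants, "KIF5B-ALK")
  expect_false(one$multi)

  none <- call_subtype(mk("KIF5B_P1", NA, NA), panel)
  expect_length(none$variants, 0L)

  # melt temperature outside tolerance vetoes an otherwise strong Ct
  off <- call_subtype(mk("KIF5B_P1", 28, tm_of("KIF5B_P1") + 1.2), panel)
  expect_length(off$variants, 0L)

  # two detected pairs: lowest Ct wins, multi-detection flagged
  two <- call_subtype(mk(c("KIF5B_P1", "STRN_P1"), c(31, 28),
                         c(tm_of("KIF5B_P1"), tm_of("STRN_P1"))), panel)
  expect_equal(two$variants, "STRN-ALK")
  expect_true(two$multi)

  # a pair covering two variants returns the covering set, flagged ambiguous
  amb <- call_subtype(mk("EML4_P01", 27, tm_of("EML4_P01")), panel)
  expect_true(amb$ambiguous)
  expect_equal(amb$variants, c("EML4-ALK_v01", "EML4-ALK_v02"))
})

test_that("integrated call covers the three canonical outcomes", {
  cutoffs <- c(marker = 2, imbalance = -1, combined = 5)
  sub <- structure(list(variants = "EML4-ALK_v01", pair_id = "EML4_P01",
                        ambiguous = FALSE, multi = FALSE,
                        detected_pairs = "EML4_P01"), class = "subtype_call")
  allpos <- integrate_call(1, -6, -5, cutoffs, subtype = sub)
  expect_equal(allpos$status, "positive")
  expect_true(allpos$flag_marker && allpos$flag_imbalance && allpos$flag_subtype)
  expect_false(allpos$discordant)

  neg <- integrate_call(8, 4, 12, cutoffs, subtype = NULL)
  expect_equal(neg$status, "negative")
  expect_false(any(neg$flag_marker, neg$flag_imbalance, neg$flag_subtype))

  # subtype detected but score above cutoff: the low-tumor-content scenario
  disc <- integrate_call(8, 4, 12, cutoffs, subtype = sub)
  expect_equal(disc$status, "positive")
  expect_true(disc$discordant)
  expect_equal(disc$variant_id, "EML4-ALK_v01")

  ind <- integrate_call(NA, NA, NA, cutoffs, qc_fail = TRUE)
  expect_equal(ind$status, "indeterminate")
  # a positive call always carries at least one evidence flag
  corner <- integrate_call(2.4, -0.7, 1.7, c(marker = 2, imbalance = -1, combined = 2))
  expect_equal(corner$status, "positive")
  expect_true(corner$flag_marker || corner$flag_imbalance || corner$flag_subtype)
})

test_that("fitted caller separates the default synthetic cohort perfectly", {
  cfg <- sim_config(seed = 19L, n_probesets = 20L)
  co <- simulate_cohort(cfg)
  status <- setNames(co$truth$true_status, co$truth$sample_id)
  fit <- alk_caller(co$ct, status)
  expect_named(coef(fit), c("marker", "imbalance", "combined"))
  calls <- predict(fit, ct = co$ct, panel = co$panel)
  expect_equal(calls$status, unname(status[calls$sample_id]))
  # positives carry subtype evidence; the combined score dominates components
  pos <- calls$status == "positive"
  expect_true(all(calls$flag_subtype[pos]))
  sc <- fit$scores
  a_comb <- auc_mann_whitney(-sc$combined[pos], -sc$combined[!pos])
  a_mark <- auc_mann_whitney(-sc$dct_marker[pos], -sc$dct_marker[!pos])
  a_imb <- auc_mann_whitney(-sc$dct_imbalance[pos], -sc$dct_imbalance[!pos])
  expect_gte(a_comb, max(a_mark, a_imb) - 0.02)
  expect_equal(a_comb, 1.0)
})

test_that("a censored reference gene yields an indeterminate call", {
  cfg <- sim_config(seed = 4L, n_probesets = 20L,
                    group_sizes = c(alk = 3, egfr = 3, kras = 0, tn = 0, normal = 0))
  co <- simulate_cohort(cfg)
  broken <- as.data.frame(co$ct)
  broken$ct[broken$sample_id == "S001" & broken$target_id == "hprt1"] <- NA
  ct2 <- ct_table(broken, max_ct = cfg$max_ct)
  status <- setNames(co$truth$true_status, co$truth$sample_id)
  fit <- alk_caller(ct2, status)
  calls <- predict(fit)
  expect_equal(calls$status[calls$sample_id == "S001"], "indeterminate")
  expect_match(calls$qc[calls$sample_id == "S001"], "reference")
})

test_that("missing reference targets fail loudly", {
  df <- data.frame(sample_id = "S1",
                   target_id = c("sweyjawbu", "alk5p", "alk3p"),
                   ct = c(30, 35, 28), tm = NA_real_)
  expect_error(alk_scores(ct_table(df)), regexp = "hprt1.*esd",
               class = "alkscreen_validation_error")
})

test_that("low tumor fraction reproduces the PCR+/FISH- discordance mechanism", {
  hits <- 0L
  for (s in 1:15) {
    cfg <- sim_config(seed = s, n_probesets = 20L,
                      group_sizes = c(alk = 6, egfr = 10, kras = 0, tn = 0,
                                      normal = 0))
    truth <- assign_truth(cfg)
    truth$tumor_fraction[1] <- 0.03      # the ~3% positive-cell specimen
    ct <- simulate_ct_table(cfg, truth, default_panel())
    sub <- call_subtype(ct[ct$sample_id == "S001", ], default_panel())
    fish <- simulate_fish(truth, seed = s)
    if (length(sub$variants) > 0 &&
        fish$call[fish$sample_id == "S001"] == "negative")
      hits <- hits + 1L
    # the combined score has drifted toward the negative class
    sc <- alk_scores(ct)
    expect_gt(sc$combined[sc$sample_id == "S001"],
              max(sc$combined[2:6]))
  }
  expect_equal(hits, 15L)
})
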