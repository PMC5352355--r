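# Marker-discovery operations: quantile normalization, median polish, SAM,
# fold change, correlation, probe matching.

test_that("quantile normalization maps columns onto the mean sorted profile", {
  m <- matrix(c(1, 3, 4, 2), nrow = 2)   # columns (1,3) and (4,2)
  expect_equal(quantile_normalize(m), matrix(c(1.5, 3.5, 3.5, 1.5), nrow = 2))
  # identical columns are a fixed point; a single column is untouched
  id <- matrix(rep(c(5, 1, 3), 3), ncol = 3)
  expect_equal(quantile_normalize(id), id)
  one <- matrix(c(9, 2, 7), ncol = 1)
  expect_equal(quantile_normalize(one), one)
  expect_error(quantile_normalize(matrix(c(1, NA), 1)),
               class = "alkscreen_validation_error")
})

test_that("quantile normalization is idempotent with equal column sums", {
  set.seed(31)
  m <- matrix(rnorm(60 * 8, 8, 2), nrow = 60)
  q1 <- quantile_normalize(m)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  expect_lt(diff(range(colSums(q1))), 1e-9)
})

test_that("median polish summarization matches hand and brute-force oracles", {
  # hand-polished 2x2: overall 2.5, rows (-1,+1), cols (-0.5,+0.5)
  v <- matrix(c(1, 3, 2, 4), nrow = 2,
              dimnames = list(c("a_p1", "a_p2"), c("s1", "s2")))
  pm <- probe_matrix(v, c(a_p1 = "a", a_p2 = "a"),
                     c(s1 = "alk", s2 = "egfr"))
  expr <- median_polish_summarize(pm)
  expect_equal(unname(expr$values["a", ]), c(2.0, 3.0))

  # single-probe sets pass through
  v1 <- matrix(rnorm(4), nrow = 1, dimnames = list("b_p1", paste0("s", 1:4)))
  pm1 <- probe_matrix(v1, c(b_p1 = "b"),
                      setNames(rep("alk", 4), paste0("s", 1:4)))
  expect_equal(median_polish_summarize(pm1)$values["b", ], v1[1, ])

  # random 4x6 sub-matrices against the independent iterative-median oracle
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rnorm(24, 8, 2), nrow = 4,
                dimnames = list(paste0("g_p", 1:4), paste0("s", 1:6)))
    pm <- probe_matrix(x, setNames(rep("g", 4), rownames(x)),
                       setNames(rep(c("alk", "egfr"), 3), colnames(x)))
    mine <- median_polish_summarize(pm, tol = 1e-12, maxiter = 200)$values["g", ]
    oracle <- brute_medpolish(x)
    expect_equal(unname(mine), unname(oracle$overall + oracle$col),
                 tolerance = 1e-8)
    # at convergence the last sweep zeroed the column medians, and one more
    # full polish cycle no longer moves the reported expression
    expect_lt(max(abs(apply(oracle$residuals, 2, median))), 1e-10)
    again <- brute_medpolish(x, maxiter = 600L)
    expect_equal(oracle$overall + oracle$col, again$overall + again$col,
                 tolerance = 1e-8)
  }
})

test_that("SAM degenerates correctly on the exact null", {
  x <- matrix(rep(c(3, 5, 1, 4), each = 6), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  expr <- expr_matrix(x, setNames(rep(c("alk", "egfr"), each = 3),
                                  colnames(x)))
  fit <- sam(expr, "alk", n_perm = 50, seed = 1)
  expect_true(all(fit$results$d_stat == 0))
  expect_true(all(fit$results$q_value == 1))
})

test_that("SAM q-values equal exhaustive-permutation enumeration on 3-vs-3", {
  set.seed(11)
  x <- matrix(rnorm(60, 8, 1), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:6)))
  x[1, 1:3] <- x[1, 1:3] + 3
  labels <- setNames(rep(c("alk", "egfr"), each = 3), colnames(x))
  expr <- expr_matrix(x, labels)
  fit <- sam(expr, "alk", n_perm = 1000, seed = 1, s0 = 0.2)
  expect_true(fit$exhaustive)
  expect_equal(fit$n_perm, choose(6, 3))
  oracle <- sam_oracle(x, labels == "alk", s0 = 0.2)
  res <- fit$results[match(rownames(x), fit$results$probeset_id), ]
  expect_equal(res$d_stat, unname(oracle$d), tolerance = 1e-12)
  expect_equal(res$q_value, unname(oracle$q), tolerance = 1e-12)
})

test_that("with s0 = 0 and equal class sizes d is the classical t statistic", {
  set.seed(5)
  x <- matrix(rnorm(80, 6, 1.5), nrow = 10,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:8)))
  labels <- setNames(rep(c("alk", "egfr"), each = 4), colnames(x))
  fit <- sam(expr_matrix(x, labels), "alk", n_perm = 10, seed = 1, s0 = 0)
  tstat <- apply(x, 1, function(row)
    t.test(row[labels == "alk"], row[labels != "alk"],
           var.equal = TRUE)$statistic)
  res <- fit$results[match(rownames(x), fit$results$probeset_id), ]
  expect_equal(res$d_stat, unname(tstat), tolerance = 1e-10)
})

test_that("SAM rejects invalid inputs", {
  x <- matrix(rnorm(20), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  expr <- expr_matrix(x, setNames(rep("alk", 4), colnames(x)))
  expect_error(sam(expr, "alk", n_perm = 10), class = "alkscreen_validation_error")
  expr2 <- expr_matrix(x, setNames(rep(c("alk", "egfr"), 2), colnames(x)))
  expect_error(sam(expr2, "alk", n_perm = 0), class = "alkscreen_validation_error")
})

test_that("fold change is 2^(log2 mean difference) and location invariant", {
  x <- matrix(c(5, 5, 5 + log2(37.4), 5 + log2(37.4),
                7, 7, 6, 6,
                4, 4, 5, 5), nrow = 3, byrow = TRUE,
              dimnames = list(c("up", "down", "half"), paste0("s", 1:4)))
  labels <- setNames(c("egfr", "egfr", "alk", "alk"), paste0("s", 1:4))
  fc <- fold_change(expr_matrix(x, labels), "alk")
  expect_equal(unname(fc["up"]), 37.4)
  expect_equal(unname(fc["down"]), 0.5)
  expect_equal(unname(fc["half"]), 2)
  shifted <- expr_matrix(x + 3.7, labels)    # per-chip constant cancels
  expect_equal(fold_change(shifted, "alk"), fc)
  expect_error(fold_change(expr_matrix(x, setNames(rep("alk", 4), colnames(x))), "alk"),
               class = "alkscreen_validation_error")
})

test_that("pearson correlation handles the definitional cases", {
  x <- c(1, 2, 3)
  expect_equal(pearson_correlation(x, x), 1.0)
  expect_equal(pearson_correlation(x, -x), -1.0)
  expect_equal(pearson_correlation(x, c(2, 4, 6)), 1.0)
  expect_error(pearson_correlation(x, c(2, 2, 2)),
               class = "alkscreen_validation_error")
  expect_error(pearson_correlation(x, c(1, 2)),
               class = "alkscreen_validation_error")
})

test_that("probe matching honors the Hamming boundary and the N rule", {
  hits <- match_probes(c(p = "ACGT"), c(t1 = "ACGT"), max_mismatch = 0,
                       search_reverse_complement = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$mismatches, 0L)

  expect_equal(nrow(match_probes(c(p = "ACGT"), c(t1 = "AGGT"),
                                 max_mismatch = 1,
                                 search_reverse_complement = FALSE)), 1L)
  expect_equal(nrow(match_probes(c(p = "ACGT"), c(t1 = "AGGT"),
                                 max_mismatch = 0,
                                 search_reverse_complement = FALSE)), 0L)

  # N matches nothing, not even N
  withN <- match_probes(c(p = "ACNT"), c(t1 = "ACNT"), max_mismatch = 1,
                        search_reverse_complement = FALSE)
  expect_equal(withN$mismatches, 1L)
  expect_equal(nrow(match_probes(c(p = "ACNT"), c(t1 = "ACNT"),
                                 max_mismatch = 0,
                                 search_reverse_complement = FALSE)), 0L)

  # reverse-complement hits are found and labelled
  rc <- match_probes(c(p = "AACCG"), c(t1 = "TTCGGTT"), max_mismatch = 0)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 2L)

  # probe longer than transcript: silently no hits
  expect_equal(nrow(match_probes(c(p = "ACGTACGT"), c(t1 = "ACG"))), 0L)
  expect_error(match_probes(c(p = "ACGU"), c(t1 = "ACGT")),
               class = "alkscreen_validation_error")
})

test_that("probe matching equals a position-wise brute-force scan", {
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:3) {
    tx <- paste(sample(bases, 1000, replace = TRUE), collapse = "")
    # half random probes, half planted with 0-2 mutations
    probes <- character(6)
    for (i in 1:6) {
      if (i <= 3) {
        probes[i] <- paste(sample(bases, 25, replace = TRUE), collapse = "")
      } else {
        s <- sample(976, 1)
        p <- strsplit(substr(tx, s, s + 24), "")[[1]]
        nmut <- i - 4
        if (nmut > 0) {
          at <- sample(25, nmut)
          p[at] <- sapply(p[at], function(b) sample(setdiff(bases, b), 1))
        }
        probes[i] <- paste(p, collapse = "")
      }
    }
    names(probes) <- paste0("p", 1:6)
    hits <- match_probes(probes, c(tx1 = tx), max_mismatch = 1)
    for (i in seq_along(probes)) {
      oracle <- brute_probe_scan(probes[i], tx, max_mm = 1)
      mine <- hits[hits$probe_id == names(probes)[i], ]
      if (is.null(oracle)) {
        expect_equal(nrow(mine), 0L)
      } else {
        oracle <- oracle[order(oracle$start, oracle$strand), ]
        expect_equal(mine$start, oracle$start)
        expect_equal(mine$mismatches, oracle$mismatches)
        expect_equal(mine$strand, oracle$strand)
      }
    }
  }
})
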