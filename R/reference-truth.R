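# Simulated confirmatory assays — break-apart FISH and binary IHC — driven
# by tumor-cell fraction, plus concordance between PCR calls and the
# reference calls.

#' Simulate break-apart FISH scoring
#'
#' For each sample, `n_cells` tumor cells are scored and each shows a
#' rearrangement signal independently with probability equal to the sample's
#' tumor-cell fraction (true positives) or a small false-signal rate
#' (negatives).  The specimen is FISH-positive when strictly more than
#' `threshold` of the scored cells are positive — with the conventional 50
#' cells and 15% threshold, at least 8 positive cells are required (7/50 =
#' 14% fails).
#'
#' @param truth truth data frame from [assign_truth()] (needs `sample_id`,
#'   `true_status`, `tumor_fraction`).
#' @param n_cells tumor cells scored per specimen.
#' @param threshold positive-cell proportion that must be exceeded.
#' @param false_rate per-cell false-signal probability in true negatives.
#' @param seed integer seed.
#' @return data frame with `sample_id`, `cells_scored`, `cells_positive`,
#'   `call`.
#' @export
simulate_fish <- function(truth, n_cells = 50L, threshold = 0.15,
                          false_rate = 0, seed = 1L) {
  if (!is_count(n_cells) || n_cells < 1)
    stop_validation("n_cells must be a count >= 1")
  if (!is.finite(threshold) || threshold <= 0 || threshold >= 1)
    stop_validation("threshold must lie in (0, 1)")
  f <- ifelse(truth$true_status == "positive", truth$tumor_fraction, false_rate)
  k <- with_seed(seed, stats::rbinom(nrow(truth), n_cells, f))
  data.frame(sample_id = truth$sample_id,
             cells_scored = n_cells,
             cells_positive = k,
             call = ifelse(k > threshold * n_cells, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Exact probability of a FISH-positive call
#'
#' Closed-form binomial tail `P(K > threshold * n_cells)` for
#' `K ~ Binomial(n_cells, f)`; the analytic counterpart of
#' [simulate_fish()].  At the conventional 50-cell, 15% rule a specimen with
#' 3% rearrangement-positive cells is called positive with probability about
#' 3e-4 — the mechanism behind PCR-positive / FISH-negative discordance.
#'
#' @param f per-cell positive probability in \[0, 1\].
#' @param n_cells cells scored.
#' @param threshold proportion that must be exceeded.
#' @export
fish_positive_probability <- function(f, n_cells = 50L, threshold = 0.15) {
  if (any(f < 0 | f > 1)) stop_validation("f must lie in [0, 1]")
  kmin <- floor(threshold * n_cells * (1 + 1e-12)) + 1
  stats::pbinom(kmin - 1, n_cells, f, lower.tail = FALSE)
}

#' Simulate binary IHC scoring
#'
#' Staining intensity is scored 0-3; a specimen is IHC-positive at 2+ or 3+.
#' Scores are drawn from a per-status categorical distribution
#' (`score_probs`), defaulting to the deterministic rule: true positives
#' score 3, negatives 0.  Regardless of the draw, a positive specimen whose
#' tumor-cell fraction does not exceed 10% is capped at score 1 (staining
#' must appear in more than 10% of tumor cells), and is therefore called
#' negative.
#'
#' @param truth truth data frame from [assign_truth()].
#' @param score_probs optional list with elements `positive` and `negative`,
#'   each a length-4 probability vector over scores 0-3.
#' @param seed integer seed.
#' @return data frame with `sample_id`, `score`, `call`.
#' @export
simulate_ihc <- function(truth, score_probs = NULL, seed = 1L) {
  if (is.null(score_probs))
    score_probs <- list(positive = c(0, 0, 0, 1), negative = c(1, 0, 0, 0))
  pos <- truth$true_status == "positive"
  score <- with_seed(seed, {
    s <- integer(nrow(truth))
    if (any(pos))
      s[pos] <- sample(0:3, sum(pos), replace = TRUE, prob = score_probs$positive)
    if (any(!pos))
      s[!pos] <- sample(0:3, sum(!pos), replace = TRUE, prob = score_probs$negative)
    s
  })
  score[pos & truth$tumor_fraction <= 0.10] <-
    pmin(score[pos & truth$tumor_fraction <= 0.10], 1L)
  data.frame(sample_id = truth$sample_id, score = score,
             call = ifelse(score >= 2, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Concordance between PCR calls and a reference assay
#'
#' Cross-tabulates the PCR index calls against reference (e.g. FISH) calls.
#' Indeterminate PCR calls are excluded from the 2x2 table and counted
#' separately.
#'
#' @param calls an `alk_calls` data frame (needs `sample_id`, `status`).
#' @param reference reference calls (needs `sample_id`, `call`).
#' @return object of class `concordance`: counts `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `n_indeterminate`, `discordant_ids`.
#' @export
concordance <- function(calls, reference) {
  if (!setequal(calls$sample_id, reference$sample_id))
    stop_validation("calls and reference must cover the same sample ids")
  ref <- reference$call[match(calls$sample_id, reference$sample_id)]
  ind <- calls$status == "indeterminate"
  idx <- calls$status[!ind]
  ref <- ref[!ind]
  ids <- calls$sample_id[!ind]
  tp <- sum(idx == "positive" & ref == "positive")
  fp <- sum(idx == "positive" & ref == "negative")
  fn <- sum(idx == "negative" & ref == "positive")
  tn <- sum(idx == "negative" & ref == "negative")
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 n_indeterminate = sum(ind),
                 discordant_ids = sort(ids[idx != ref])),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("concordance vs reference: tp=%d fp=%d fn=%d tn=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sensitivity %.4f | specificity %.4f | indeterminate %d\n",
              x$sensitivity, x$specificity, x$n_indeterminate))
  if (length(x$discordant_ids))
    cat("discordant:", paste(x$discordant_ids, collapse = ", "), "\n")
  invisible(x)
}
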