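# Three-level ALK-status computation from Ct tables: marker delta-Ct against
# the HPRT1/ESD reference genes, 5'/3' ALK transcript imbalance, their sum as
# the combined score, and fusion-subtype panel interpretation.  Lower scores
# indicate rearrangement (lower Ct = higher expression).

#' Marker delta-Ct against the HPRT1/ESD reference pair
#'
#' `dCt = Ct_marker - (Ct_HPRT1 + Ct_ESD) / 2`.  A censored marker Ct (NA,
#' no amplification within `max_ct` cycles) is scored at the `max_ct`
#' sentinel and flagged via the `"censored"` attribute; a censored reference
#' gene is a sample-level QC failure and yields NA with the `"qc_fail"`
#' attribute set — no call can be made for that sample.
#'
#' @param ct_marker,ct_hprt1,ct_esd Ct values in cycles; NA = censored.
#' @param max_ct censoring limit (cycles).
#' @return numeric vector of delta-Ct values with logical attributes
#'   `censored` and `qc_fail`.
#' @export
delta_ct_marker <- function(ct_marker, ct_hprt1, ct_esd, max_ct = 40) {
  qc_fail <- is.na(ct_hprt1) | is.na(ct_esd)
  censored <- !qc_fail & is.na(ct_marker)
  marker <- ifelse(is.na(ct_marker), max_ct, ct_marker)
  out <- ifelse(qc_fail, NA_real_, marker - (ct_hprt1 + ct_esd) / 2)
  structure(out, censored = censored, qc_fail = qc_fail)
}

#' 3'/5' ALK transcript imbalance delta-Ct
#'
#' `dCt = Ct_ALK3' - Ct_ALK5'`: negative when the 3' (kinase-domain) side
#' retained in fusions is overexpressed relative to the 5' side.  One
#' censored side is scored at `max_ct` and flagged; both sides censored
#' leaves the imbalance undefined (NA, `undefined` attribute), and the
#' sample contributes no imbalance evidence.
#'
#' @param ct_alk3p,ct_alk5p Ct values in cycles; NA = censored.
#' @param max_ct censoring limit (cycles).
#' @return numeric vector with logical attributes `censored` and
#'   `undefined`.
#' @export
delta_ct_imbalance <- function(ct_alk3p, ct_alk5p, max_ct = 40) {
  undefined <- is.na(ct_alk3p) & is.na(ct_alk5p)
  censored <- !undefined & (is.na(ct_alk3p) | is.na(ct_alk5p))
  a3 <- ifelse(is.na(ct_alk3p), max_ct, ct_alk3p)
  a5 <- ifelse(is.na(ct_alk5p), max_ct, ct_alk5p)
  out <- ifelse(undefined, NA_real_, a3 - a5)
  structure(out, censored = censored, undefined = undefined)
}

#' Combined three-level score
#'
#' Sum of the marker delta-Ct and the 3'/5' imbalance delta-Ct; the best
#' single discriminator of rearrangement status.
#'
#' @param dct_marker,dct_imbalance delta-Ct components, cycles.
#' @export
combined_score <- function(dct_marker, dct_imbalance) {
  as.numeric(dct_marker) + as.numeric(dct_imbalance)
}

#' Derive a score cutoff from labelled samples
#'
#' Positives score low.  When the classes separate, the cutoff is the
#' midpoint between the maximum positive-class score and the minimum
#' negative-class score.  Otherwise the threshold maximizing Youden's J
#' (sensitivity + specificity - 1) over midpoints of adjacent distinct
#' scores is chosen, ties broken toward higher specificity (the lower
#' threshold); if no threshold improves on chance, the cutoff falls back to
#' the median score and the fit is flagged as degraded.
#'
#' @param scores numeric scores, one per sample.
#' @param labels class label per sample.
#' @param positive_label label identifying true positives.
#' @return cutoff (call positive when score < cutoff) with attributes
#'   `separable`, `youden` and `degraded`.
#' @export
choose_cutoff <- function(scores, labels, positive_label = "positive") {
  keep <- is.finite(scores)
  scores <- scores[keep]; labels <- labels[keep]
  pos <- scores[labels == positive_label]
  neg <- scores[labels != positive_label]
  if (length(pos) == 0L || length(neg) == 0L)
    stop_validation("cutoff derivation needs both classes present")
  if (max(pos) < min(neg)) {
    cut <- (max(pos) + min(neg)) / 2
    return(structure(cut, separable = TRUE, youden = 1, degraded = FALSE))
  }
  u <- sort(unique(scores))
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  j <- vapply(cand, function(cc)
    mean(pos < cc) + mean(neg >= cc) - 1, numeric(1))
  if (max(j) <= 0) {
    return(structure(stats::median(scores), separable = FALSE, youden = 0,
                     degraded = TRUE))
  }
  best <- cand[j == max(j)][1L]  # candidates ascend; first = fewest positives
  structure(best, separable = FALSE, youden = max(j), degraded = FALSE)
}

#' Interpret the fusion-subtype panel for one sample
#'
#' A primer pair is detected iff its amplicon Ct is at most `ct_detect` and
#' its melt temperature lies within `tm_tol` of the pair's expected Tm.
#' Among several detected pairs, the one with the lowest Ct wins (ties by
#' lexicographic variant id) and the multi-detection flag is set.  A winning
#' pair covering several variants cannot be resolved uniquely: the covering
#' set is returned with the ambiguity flag.
#'
#' @param sample_ct rows of a [ct_table()] for one sample (panel targets;
#'   other targets are ignored).
#' @param panel an `alk_panel`.
#' @param ct_detect detection Ct ceiling, cycles.
#' @param tm_tol melt-temperature tolerance, degrees C.
#' @return list of class `subtype_call`: `variants` (character, possibly
#'   length 0 or a covering set), `pair_id`, `ambiguous`, `multi`,
#'   `detected_pairs`.
#' @export
call_subtype <- function(sample_ct, panel, ct_detect = 35, tm_tol = 0.5) {
  panel <- validate_panel(panel)
  rows <- sample_ct[sample_ct$target_id %in% panel$pair_id, , drop = FALSE]
  exp_tm <- panel$expected_tm[match(rows$target_id, panel$pair_id)]
  det <- !is.na(rows$ct) & rows$ct <= ct_detect &
    !is.na(rows$tm) & abs(rows$tm - exp_tm) <= tm_tol
  detected <- rows[det, , drop = FALSE]
  if (nrow(detected) == 0L)
    return(structure(list(variants = character(0), pair_id = NA_character_,
                          ambiguous = FALSE, multi = FALSE,
                          detected_pairs = character(0)),
                     class = "subtype_call"))
  vars_of <- function(pid) panel_variants(panel)[[match(pid, panel$pair_id)]]
  o <- order(detected$ct,
             vapply(detected$target_id, function(p) min(vars_of(p)), character(1)))
  winner <- detected$target_id[o[1L]]
  vars <- sort(vars_of(winner))
  structure(list(variants = vars, pair_id = winner,
                 ambiguous = length(vars) > 1L,
                 multi = nrow(detected) > 1L,
                 detected_pairs = sort(detected$target_id)),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  if (length(x$variants) == 0L) cat("subtype: none detected\n")
  else cat(sprintf("subtype: %s (pair %s)%s%s\n",
                   paste(x$variants, collapse = " | "), x$pair_id,
                   if (x$ambiguous) " [ambiguous covering set]" else "",
                   if (x$multi) " [multiple pairs detected]" else ""))
  invisible(x)
}

#' Per-sample ALK scoring metrics from a Ct table
#'
#' Computes, for every sample, the marker delta-Ct, the 3'/5' imbalance and
#' the combined score together with censoring/QC flags.  The table must
#' contain the targets `sweyjawbu`, `alk5p`, `alk3p` and the reference genes
#' `hprt1` and `esd`.
#'
#' @param ct a [ct_table()].
#' @param max_ct censoring limit; defaults to the table's own attribute.
#' @return data frame, one row per sample.
#' @export
alk_scores <- function(ct, max_ct = attr(ct, "max_ct") %||% 40) {
  need <- CORE_TARGETS
  have <- unique(ct$target_id)
  if (!all(c("hprt1", "esd") %in% have))
    stop_validation(paste("reference gene targets 'hprt1' and 'esd' are",
                          "required for delta-Ct normalization"))
  if (!all(need %in% have))
    stop_validation("ct table is missing target(s): %s",
                    paste(setdiff(need, have), collapse = ", "))
  samples <- unique(ct$sample_id)
  get <- function(tg) {
    sub <- ct[ct$target_id == tg, ]
    sub$ct[match(samples, sub$sample_id)]
  }
  dm <- delta_ct_marker(get("sweyjawbu"), get("hprt1"), get("esd"), max_ct)
  di <- delta_ct_imbalance(get("alk3p"), get("alk5p"), max_ct)
  data.frame(sample_id = samples,
             dct_marker = as.numeric(dm),
             marker_censored = attr(dm, "censored"),
             qc_fail = attr(dm, "qc_fail"),
             dct_imbalance = as.numeric(di),
             imbalance_censored = attr(di, "censored"),
             imbalance_undefined = attr(di, "undefined"),
             combined = combined_score(dm, di),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the three-level ALK rearrangement caller
#'
#' Trains the caller on a labelled Ct table: per-sample marker delta-Ct,
#' 3'/5' imbalance and combined scores are computed, and a cutoff is derived
#' for each via [choose_cutoff()].  The combined-score cutoff governs the
#' status call; the component cutoffs set the per-level evidence flags.
#'
#' @param ct a [ct_table()] with known-status samples.
#' @param status character vector of `"positive"`/`"negative"`, either named
#'   by sample id or in the order of the table's unique samples.
#' @param max_ct censoring limit, cycles.
#' @return object of class `alk_caller` with components `cutoffs` (named
#'   numeric: marker, imbalance, combined), `scores` (training metrics),
#'   `status`.
#' @seealso [predict.alk_caller()] to produce calls.
#' @export
alk_caller <- function(ct, status, max_ct = attr(ct, "max_ct") %||% 40) {
  sc <- alk_scores(ct, max_ct)
  if (!is.null(names(status))) status <- status[sc$sample_id]
  if (length(status) != nrow(sc) || any(is.na(status)))
    stop_validation("status must label every sample in the ct table")
  ok <- !sc$qc_fail
  cutoffs <- c(
    marker = as.numeric(choose_cutoff(sc$dct_marker[ok], status[ok])),
    imbalance = as.numeric(choose_cutoff(sc$dct_imbalance[ok], status[ok])),
    combined = as.numeric(choose_cutoff(sc$combined[ok], status[ok])))
  structure(list(cutoffs = cutoffs, scores = sc, status = status,
                 max_ct = max_ct, call = match.call()),
            class = "alk_caller")
}

#' @export
print.alk_caller <- function(x, ...) {
  cat("Three-level ALK rearrangement caller\n")
  cat(sprintf("trained on %d samples (%d positive / %d negative)\n",
              nrow(x$scores), sum(x$status == "positive"),
              sum(x$status != "positive")))
  cat("cutoffs (call positive below):\n")
  print(round(x$cutoffs, 3))
  invisible(x)
}

#' @export
coef.alk_caller <- function(object, ...) object$cutoffs

#' @export
summary.alk_caller <- function(object, ...) {
  print(object)
  pos <- object$status == "positive"
  for (m in c("dct_marker", "dct_imbalance", "combined")) {
    v <- object$scores[[m]]
    cat(sprintf("%-13s positive mean %6.2f | negative mean %6.2f cycles\n",
                m, mean(v[pos], na.rm = TRUE), mean(v[!pos], na.rm = TRUE)))
  }
  tr <- predict(object)
  cat("resubstitution confusion:\n")
  print(table(truth = object$status, call = tr$status))
  invisible(object)
}

#' Strip chart of combined scores by class
#'
#' @param x an `alk_caller`.
#' @param ... passed to [graphics::stripchart()].
#' @export
plot.alk_caller <- function(x, ...) {
  graphics::stripchart(split(x$scores$combined, x$status), vertical = TRUE,
                       method = "jitter", pch = 19,
                       ylab = "combined delta-Ct (cycles)", ...)
  graphics::abline(h = x$cutoffs["combined"], lty = 2)
  invisible(x)
}

#' Integrate the three evidence levels into one call
#'
#' Evidence flags are set independently: `marker` when the marker delta-Ct
#' falls below its cutoff, `imbalance` likewise, `subtype` when the panel
#' detected a variant.  Status is positive when the combined score falls
#' below its cutoff or a subtype was detected; a detected subtype with a
#' score at or above the cutoff is called positive with a discordance
#' annotation — the signature of a specimen with very few
#' rearrangement-positive cells.  QC failures yield an indeterminate call.
#' A positive call always carries at least one evidence flag: in the corner
#' case where only the combined score is below cutoff, the component with
#' the smaller margin to its own cutoff is flagged.
#'
#' @param dct_marker,dct_imbalance,combined per-sample metrics, cycles.
#' @param cutoffs named numeric with entries `marker`, `imbalance`,
#'   `combined`.
#' @param subtype optional [call_subtype()] result.
#' @param qc_fail sample failed reference-gene QC.
#' @return one-row data frame with status, flags and annotations.
#' @export
integrate_call <- function(dct_marker, dct_imbalance, combined, cutoffs,
                           subtype = NULL, qc_fail = FALSE) {
  has_subtype <- !is.null(subtype) && length(subtype$variants) > 0L
  variant <- if (has_subtype) paste(subtype$variants, collapse = "|") else NA_character_
  if (isTRUE(qc_fail)) {
    return(data.frame(dct_marker = NA_real_, dct_imbalance = NA_real_,
                      combined = NA_real_, status = "indeterminate",
                      variant_id = variant, flag_marker = FALSE,
                      flag_imbalance = FALSE, flag_subtype = has_subtype,
                      discordant = FALSE, ambiguous_subtype = isTRUE(subtype$ambiguous),
                      qc = "reference gene censored", stringsAsFactors = FALSE))
  }
  fm <- is.finite(dct_marker) && dct_marker < cutoffs[["marker"]]
  fi <- is.finite(dct_imbalance) && dct_imbalance < cutoffs[["imbalance"]]
  score_pos <- is.finite(combined) && combined < cutoffs[["combined"]]
  status <- if (score_pos || has_subtype) "positive" else "negative"
  discordant <- has_subtype && is.finite(combined) &&
    combined >= cutoffs[["combined"]]
  if (score_pos && !fm && !fi && !has_subtype) {
    margins <- c(marker = dct_marker - cutoffs[["marker"]],
                 imbalance = dct_imbalance - cutoffs[["imbalance"]])
    margins[!is.finite(margins)] <- Inf
    if (names(which.min(margins)) == "marker") fm <- TRUE else fi <- TRUE
  }
  data.frame(dct_marker = dct_marker, dct_imbalance = dct_imbalance,
             combined = combined, status = status, variant_id = variant,
             flag_marker = fm, flag_imbalance = fi, flag_subtype = has_subtype,
             discordant = discordant,
             ambiguous_subtype = isTRUE(subtype$ambiguous),
             qc = NA_character_, stringsAsFactors = FALSE)
}

#' Call ALK status on a Ct table
#'
#' @param object a fitted [alk_caller()].
#' @param ct a [ct_table()] to call; defaults to the training table's
#'   metrics (resubstitution).
#' @param panel optional `alk_panel` enabling subtype evidence.
#' @param ct_detect,tm_tol subtype detection thresholds (cycles, degrees C).
#' @param ... unused.
#' @return an `alk_calls` data frame, one row per sample, carrying the
#'   cutoffs used as an attribute.
#' @export
predict.alk_caller <- function(object, ct = NULL, panel = NULL,
                               ct_detect = 35, tm_tol = 0.5, ...) {
  sc <- if (is.null(ct)) object$scores else alk_scores(ct, object$max_ct)
  calls <- lapply(seq_len(nrow(sc)), function(i) {
    subtype <- NULL
    if (!is.null(panel) && !is.null(ct)) {
      subtype <- call_subtype(ct[ct$sample_id == sc$sample_id[i], , drop = FALSE],
                              panel, ct_detect, tm_tol)
    } else if (!is.null(panel) && is.null(ct)) {
      stop_validation("subtype calling needs the ct table; pass `ct`")
    }
    row <- integrate_call(sc$dct_marker[i], sc$dct_imbalance[i], sc$combined[i],
                          object$cutoffs, subtype, sc$qc_fail[i])
    cbind(data.frame(sample_id = sc$sample_id[i], stringsAsFactors = FALSE), row)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  structure(out, class = c("alk_calls", "data.frame"),
            cutoffs = object$cutoffs)
}

#' @export
print.alk_calls <- function(x, ...) {
  cat(sprintf("ALK calls: %d samples — %d positive, %d negative, %d indeterminate\n",
              nrow(x), sum(x$status == "positive"),
              sum(x$status == "negative"), sum(x$status == "indeterminate")))
  if (any(x$discordant))
    cat(sprintf("discordant (subtype+ / score-): %s\n",
                paste(x$sample_id[x$discordant], collapse = ", ")))
  NextMethod()
}
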