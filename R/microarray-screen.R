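# Marker-discovery computations: quantile normalization, median-polish
# probe-set summarization, SAM two-class permutation statistics, fold change,
# and one-mismatch probe-to-transcript matching.

#' Quantile-normalize an intensity matrix
#'
#' Forces every column (array) onto the common distribution given by the
#' across-column mean of sorted values; ties within a column receive the mean
#' of the reference values at their tied ranks.  Idempotent, and a no-op on a
#' single column.
#'
#' @param values numeric matrix, probes x samples, finite.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(values) {
  if (!is.matrix(values) || length(values) == 0L)
    stop_validation("quantile_normalize expects a nonempty numeric matrix")
  if (any(!is.finite(values)))
    stop_validation("quantile_normalize requires finite values")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Summarize probes into probe-set expression by Tukey median polish
#'
#' Each probe set's probes x samples sub-matrix is decomposed into overall +
#' probe (row) + sample (column) effects by alternating median sweeps; the
#' reported expression is overall + sample effect, the RMA summarization.
#' Probe sets with a single probe pass through unchanged.
#'
#' @param pm a [probe_matrix()].
#' @param tol convergence tolerance on the residual L1 norm.
#' @param maxiter sweep limit.
#' @return an `expr_matrix`: list with `values` (probe sets x samples) and
#'   `labels`.
#' @export
median_polish_summarize <- function(pm, tol = 1e-9, maxiter = 100L) {
  stopifnot(inherits(pm, "probe_matrix"))
  sets <- split(rownames(pm$values), pm$probeset[rownames(pm$values)])
  if (any(lengths(sets) == 0L))
    stop_validation("every probe set must contain at least one probe")
  ids <- names(sets)
  values <- matrix(NA_real_, nrow = length(ids), ncol = ncol(pm$values),
                   dimnames = list(ids, colnames(pm$values)))
  for (i in seq_along(ids)) {
    sub <- pm$values[sets[[i]], , drop = FALSE]
    if (nrow(sub) == 1L) {
      values[i, ] <- sub[1L, ]
    } else {
      ## past maxiter the last iterate is used; the sample effects settle
      ## long before the strict L1 stopping rule fires
      mp <- suppressWarnings(stats::medpolish(sub, eps = tol,
                                              maxiter = maxiter,
                                              trace.iter = FALSE))
      values[i, ] <- mp$overall + mp$col
    }
  }
  expr_matrix(values, pm$labels)
}

#' Construct a probe-set expression matrix object
#'
#' @param values numeric matrix of log2 expression, probe sets x samples.
#' @param labels named character map from sample id to subgroup tag.
#' @export
expr_matrix <- function(values, labels) {
  if (!is.matrix(values) || any(!is.finite(values)))
    stop_validation("expression values must be a finite numeric matrix")
  if (!setequal(colnames(values), names(labels)))
    stop_validation("every sample must carry a group label")
  structure(list(values = values, labels = labels[colnames(values)]),
            class = "expr_matrix")
}

## Two-class SAM numerator and denominator terms: r = mean difference,
## s = pooled-SE term sqrt((1/n1 + 1/n2) * pooled variance).
sam_rs <- function(x, pos) {
  n1 <- sum(pos); n2 <- sum(!pos)
  m1 <- rowMeans(x[, pos, drop = FALSE])
  m2 <- rowMeans(x[, !pos, drop = FALSE])
  ss <- rowSums((x[, pos, drop = FALSE] - m1)^2) +
    rowSums((x[, !pos, drop = FALSE] - m2)^2)
  list(r = m1 - m2, s = sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2)))
}

## s0 by the percentile rule: over candidate percentiles of s, pick the s0
## minimizing the coefficient of variation of the median |d| across
## equal-count windows of s.
sam_choose_s0 <- function(r, s, percentiles = seq(0, 1, by = 0.05)) {
  cand <- unique(stats::quantile(s, percentiles, names = FALSE))
  nw <- max(2L, min(100L, floor(length(s) / 5)))
  br <- unique(stats::quantile(s, seq(0, 1, length.out = nw + 1L), names = FALSE))
  if (length(br) < 3L) return(cand[1L])
  grp <- cut(s, br, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- ifelse(r == 0, 0, r / (s + s0))
    med <- tapply(abs(d), grp, stats::median)
    med <- med[is.finite(med)]
    m <- mean(med)
    if (length(med) < 2L || m == 0) Inf else stats::sd(med) / m
  }, numeric(1))
  cand[which.min(cv)]
}

## Class-label permutations as a logical n x B membership matrix for the
## positive class.  Exhaustive when few enough distinct splits exist,
## otherwise sampled without replacement.
sam_permutations <- function(n, n1, n_perm, seed) {
  total <- choose(n, n1)
  if (total <= n_perm) {
    idx <- utils::combn(n, n1)
  } else {
    idx <- with_seed(seed, {
      seen <- character(0)
      cols <- list()
      while (length(cols) < n_perm) {
        cand <- sort(sample.int(n, n1))
        key <- paste(cand, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          cols[[length(cols) + 1L]] <- cand
        }
      }
      matrix(unlist(cols), nrow = n1)
    })
  }
  P <- matrix(FALSE, nrow = n, ncol = ncol(idx))
  P[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n1))] <- TRUE
  P
}

#' Two-class SAM with permutation-based FDR
#'
#' Computes the SAM relative difference `d = (mean_pos - mean_neg) / (s + s0)`
#' per probe set, with `s` the two-sample pooled-SE term and the fudge factor
#' `s0` chosen by the percentile rule (minimize the coefficient of variation
#' of median |d| across windows of s).  q-values are the median number of
#' permuted |d| values at or above each observed |d|, divided by the number of
#' probe sets called at that threshold, made monotone in rank.  All distinct
#' class-label splits are enumerated when there are no more than `n_perm` of
#' them; otherwise `n_perm` splits are sampled without replacement.
#'
#' @param expr an [expr_matrix()].
#' @param positive_label subgroup tag defining the positive class.
#' @param n_perm number of label permutations (the screening default is
#'   1000).
#' @param seed integer seed for permutation sampling.
#' @param s0 optional fixed fudge factor overriding the percentile rule.
#' @return an object of class `sam_fit`; `$results` holds one row per probe
#'   set (`probeset_id`, `d_stat`, `s`, `fold_change_linear`, `q_value`,
#'   `rank`), ordered by rank.
#' @export
sam <- function(expr, positive_label, n_perm = 1000L, seed = 1L, s0 = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  pos <- expr$labels == positive_label
  if (!any(pos) || all(pos))
    stop_validation("both classes must be nonempty")
  if (!is_count(n_perm) || n_perm < 1)
    stop_validation("n_perm must be a count >= 1")
  x <- expr$values
  obs <- sam_rs(x, pos)
  if (is.null(s0)) s0 <- sam_choose_s0(obs$r, obs$s)
  d <- ifelse(obs$r == 0, 0, obs$r / (obs$s + s0))

  n <- ncol(x); n1 <- sum(pos); n2 <- n - n1
  P <- sam_permutations(n, n1, n_perm, seed)
  B <- ncol(P)
  Pn <- matrix(as.numeric(P), nrow = n)
  m1 <- (x %*% Pn) / n1
  m2 <- (x %*% (1 - Pn)) / n2
  sq <- x^2 %*% Pn
  sqn <- rowSums(x^2) - sq
  ss <- (sq - n1 * m1^2) + (sqn - n2 * m2^2)
  sperm <- sqrt(pmax(0, (1 / n1 + 1 / n2) * ss / (n - 2)))
  rperm <- m1 - m2
  dperm <- ifelse(rperm == 0, 0, rperm / (sperm + s0))

  absd <- abs(d)
  absdp <- abs(dperm)
  ## denom: number of probe sets at or above each observed |d| (ties count).
  denom <- vapply(absd, function(t) sum(absd >= t), numeric(1))
  cnt <- matrix(0, nrow = length(absd), ncol = B)
  for (b in seq_len(B)) {
    v <- sort(absdp[, b])
    lt <- findInterval(absd, v)           # number of v <= t
    eq <- lt - findInterval(absd, v, left.open = TRUE)  # number of v == t
    cnt[, b] <- length(v) - lt + eq       # number of v >= t
  }
  med_cnt <- apply(cnt, 1L, stats::median)
  q_raw <- pmin(1, med_cnt / denom)
  ord <- order(-absd, rownames(x))
  q_sorted <- rev(cummin(rev(q_raw[ord])))
  q <- numeric(length(q_raw)); q[ord] <- q_sorted

  fc <- fold_change(expr, positive_label)
  res <- data.frame(probeset_id = rownames(x), d_stat = d, s = obs$s,
                    fold_change_linear = fc, q_value = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[ord, ]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  structure(list(results = res, s0 = s0, n_perm = B,
                 exhaustive = choose(n, n1) <= n_perm,
                 d_perm = dperm, positive_label = positive_label,
                 call = match.call()),
            class = "sam_fit")
}

#' @export
print.sam_fit <- function(x, ...) {
  cat(sprintf("SAM two-class fit: %d probe sets, %d permutations%s, s0 = %.4g\n",
              nrow(x$results), x$n_perm,
              if (x$exhaustive) " (exhaustive)" else "", x$s0))
  cat(sprintf("probe sets with q < 0.05: %d\n", sum(x$results$q_value < 0.05)))
  print(utils::head(x$results, 5L), digits = 4)
  invisible(x)
}

#' @export
summary.sam_fit <- function(object, fdr = 0.05, ...) {
  hits <- object$results[object$results$q_value < fdr, ]
  cat(sprintf("%d / %d probe sets at q < %.3g\n", nrow(hits),
              nrow(object$results), fdr))
  print(hits, digits = 4)
  invisible(hits)
}

#' @export
as.data.frame.sam_fit <- function(x, ...) x$results

#' SAM quantile-quantile plot
#'
#' Observed d statistics against the mean of the order statistics of the
#' permuted d values, the conventional SAM diagnostic.
#'
#' @param x a `sam_fit`.
#' @param ... passed to [plot()].
#' @export
plot.sam_fit <- function(x, ...) {
  dbar <- rowMeans(apply(x$d_perm, 2L, sort))
  dobs <- sort(x$results$d_stat)
  plot(dbar, dobs, xlab = "expected d (permutation mean)",
       ylab = "observed d", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Linear fold change between two classes
#'
#' `2 ^ (mean log2 expression in the positive class - mean in the rest)`:
#' computed on the log2 scale, then exponentiated.
#'
#' @param expr an [expr_matrix()].
#' @param positive_label subgroup tag defining the positive class.
#' @return named vector of linear ratios, one per probe set.
#' @export
fold_change <- function(expr, positive_label) {
  stopifnot(inherits(expr, "expr_matrix"))
  pos <- expr$labels == positive_label
  if (!any(pos) || all(pos))
    stop_validation("both classes must be nonempty")
  2^(rowMeans(expr$values[, pos, drop = FALSE]) -
       rowMeans(expr$values[, !pos, drop = FALSE]))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop_validation("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_validation("correlation undefined: zero variance input")
  stats::cor(x, y, method = "pearson")
}

PROBE_ALPHABET <- c("A", "C", "G", "T", "N")

## N never matches anything, including another N.
hamming_n <- function(a, b) sum(a != b | a == "N" | b == "N")

#' Match short probes to transcripts with bounded mismatches
#'
#' Every ungapped placement of each probe (and, by default, of its reverse
#' complement) on each transcript with Hamming distance at most
#' `max_mismatch` is reported.  `N` counts as a mismatch against any base.
#' Coordinates are 0-based, half-open; hits are sorted by (transcript, start,
#' strand).
#'
#' @param probes named character vector of probe sequences over A/C/G/T/N.
#' @param transcripts a [Biostrings::DNAStringSet] (or named character
#'   vector) of transcript sequences.
#' @param max_mismatch maximum Hamming distance (the screening convention is
#'   1).
#' @param search_reverse_complement also search the reverse-complement
#'   orientation (strand "-").
#' @return data frame with columns `transcript_id`, `start`, `end`,
#'   `probe_id`, `mismatches`, `strand`.
#' @export
match_probes <- function(probes, transcripts, max_mismatch = 1L,
                         search_reverse_complement = TRUE) {
  if (is.character(transcripts))
    transcripts <- Biostrings::DNAStringSet(transcripts)
  if (is.null(names(probes))) names(probes) <- sprintf("probe_%d", seq_along(probes))
  probes <- toupper(probes)
  bad <- !vapply(strsplit(probes, ""), function(ch)
    all(ch %in% PROBE_ALPHABET) && length(ch) >= 1L, logical(1))
  if (any(bad))
    stop_validation("invalid probe sequence(s): %s",
                    paste(names(probes)[bad], collapse = ", "))
  hits <- list()
  for (p in names(probes)) {
    pat <- Biostrings::DNAString(probes[[p]])
    orients <- list(`+` = pat)
    if (search_reverse_complement)
      orients$`-` <- Biostrings::reverseComplement(pat)
    for (strand in names(orients)) {
      pchars <- strsplit(as.character(orients[[strand]]), "")[[1]]
      for (tx in names(transcripts)) {
        subj <- transcripts[[tx]]
        if (length(subj) < length(pat)) next
        m <- Biostrings::matchPattern(orients[[strand]], subj,
                                      max.mismatch = max_mismatch,
                                      fixed = TRUE)
        if (length(m) == 0L) next
        starts <- Biostrings::start(m)
        ## recount with the N-matches-nothing rule (matchPattern with
        ## fixed = TRUE would let N pair with N)
        for (s in starts) {
          wchars <- strsplit(as.character(
            Biostrings::subseq(subj, s, s + length(pat) - 1L)), "")[[1]]
          mm <- hamming_n(pchars, wchars)
          if (mm <= max_mismatch)
            hits[[length(hits) + 1L]] <- data.frame(
              transcript_id = tx, start = s - 1L, end = s - 1L + length(pat),
              probe_id = p, mismatches = mm, strand = strand,
              stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), probe_id = character(0),
               mismatches = integer(0), strand = character(0))
  out <- out[order(out$transcript_id, out$start, out$strand, out$probe_id), ]
  rownames(out) <- NULL
  out
}
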