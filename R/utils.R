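# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Validation failures are classed so callers (and tests) can distinguish
## bad inputs from programming errors.
stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("alkscreen_validation_error", "validationError")))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards.  All package randomness flows through this.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic per-operation sub-stream: one master seed per run, a fixed
## small offset per pipeline stage.  Kept strictly below 2^31 - 1.
sub_seed <- function(seed, op) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(op)) %% 2147483647
}

#' Empirical AUC by the Mann-Whitney statistic
#'
#' Probability that a randomly chosen positive-class value exceeds a randomly
#' chosen negative-class value, with ties counted one half.  Used throughout
#' to measure how well a score separates true ALK status; pass the negated
#' score when, as for delta-Ct, low values indicate positives.
#'
#' @param pos,neg numeric score vectors for the two classes.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop_validation("both classes must be nonempty to compute an AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
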