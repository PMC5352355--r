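# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's code paths: plain loops and enumeration only.

## Tukey median polish by direct alternating sweeps with the standard
## recentering convention; returns the decomposition.
brute_medpolish <- function(x, tol = 1e-12, maxiter = 500L) {
  r <- numeric(nrow(x)); cl <- numeric(ncol(x)); overall <- 0
  z <- x
  oldsum <- 0
  for (it in seq_len(maxiter)) {
    rd <- apply(z, 1, median)
    z <- z - rd
    r <- r + rd
    d <- median(cl); cl <- cl - d; overall <- overall + d
    cd <- apply(z, 2, median)
    z <- sweep(z, 2, cd)
    cl <- cl + cd
    d <- median(r); r <- r - d; overall <- overall + d
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < tol * newsum) break
    oldsum <- newsum
  }
  list(overall = overall, row = r, col = cl, residuals = z)
}

## Exhaustive-permutation SAM q-values for a fixed s0: enumerates every
## distinct positive-class assignment, computes d by its own arithmetic,
## and applies the median-count FDR with monotone enforcement.
sam_oracle <- function(x, pos, s0) {
  n <- ncol(x); n1 <- sum(pos)
  dstat <- function(assign) {
    p <- x[, assign, drop = FALSE]; q <- x[, !assign, drop = FALSE]
    m1 <- apply(p, 1, mean); m2 <- apply(q, 1, mean)
    ss <- apply((p - m1)^2, 1, sum) + apply((q - m2)^2, 1, sum)
    s <- sqrt((1 / ncol(p) + 1 / ncol(q)) * ss / (n - 2))
    ifelse(m1 - m2 == 0, 0, (m1 - m2) / (s + s0))
  }
  d <- dstat(pos)
  combos <- combn(n, n1)
  dperm <- apply(combos, 2, function(ix) dstat(seq_len(n) %in% ix))
  absd <- abs(d)
  q_raw <- sapply(seq_along(absd), function(i) {
    cnts <- apply(abs(dperm), 2, function(col) sum(col >= absd[i]))
    min(1, median(cnts) / sum(absd >= absd[i]))
  })
  ord <- order(-absd, rownames(x))
  q <- numeric(length(q_raw))
  q[ord] <- rev(cummin(rev(q_raw[ord])))
  list(d = d, q = q)
}

## Position-by-position Hamming scan of one probe against one transcript,
## both strands; N matches nothing.
brute_probe_scan <- function(probe, tx, max_mm, both = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  scan1 <- function(pat, strand) {
    pch <- strsplit(pat, "")[[1]]
    tch <- strsplit(tx, "")[[1]]
    L <- length(pch); n <- length(tch)
    hits <- NULL
    if (n >= L) for (s in 0:(n - L)) {
      w <- tch[(s + 1):(s + L)]
      mm <- sum(pch != w | pch == "N" | w == "N")
      if (mm <= max_mm)
        hits <- rbind(hits, data.frame(start = s, end = s + L,
                                       mismatches = mm, strand = strand,
                                       stringsAsFactors = FALSE))
    }
    hits
  }
  out <- scan1(probe, "+")
  if (both) out <- rbind(out, scan1(rc(probe), "-"))
  out
}

## FISH positive-call probability by full outcome enumeration (n cells,
## each independently positive with probability f): feasible for n <= 12.
fish_enum_prob <- function(f, n, threshold) {
  grid <- as.matrix(expand.grid(rep(list(0:1), n)))
  k <- rowSums(grid)
  p <- apply(grid, 1, function(g) prod(ifelse(g == 1, f, 1 - f)))
  sum(p[k > threshold * n])
}

## Small labelled expression fixture built in code.
tiny_expr <- function(values, labels) {
  expr_matrix(values, labels)
}
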