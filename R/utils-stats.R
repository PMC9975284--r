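# Internal statistical helpers shared across modules.

# Deterministic child seed so sub-generators are reproducible when run
# independently of the parent stream. Kept below 2^31 - 1.
childSeed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Row-wise mean/variance with NA handling (pairwise-complete by row).
rowMeansNA <- function(x) rowMeans(x, na.rm = TRUE)

rowVarsNA <- function(x) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  v <- ss / (n - 1)
  v[n < 2] <- NA_real_
  v
}

# Vectorized Welch two-sample t over matrix rows: group vs rest.
# Returns a data.frame with one row per matrix row. Rows where either group
# has fewer than minN observations get NA statistics and skipped = TRUE.
rowWelchT <- function(x, inGroup, minN = 3L) {
  stopifnot(is.logical(inGroup), length(inGroup) == ncol(x))
  x1 <- x[, inGroup, drop = FALSE]
  x2 <- x[, !inGroup, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  v1 <- rowVarsNA(x1); v2 <- rowVarsNA(x2)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  skipped <- n1 < minN | n2 < minN
  # zero pooled spread: identical constant groups -> t = 0, p = 1;
  # separated constants -> infinite t, p ~ 0
  zero <- !skipped & !is.na(se2) & se2 == 0
  if (any(zero)) {
    d <- m1[zero] - m2[zero]
    t[zero] <- ifelse(d == 0, 0, sign(d) * Inf)
    p[zero] <- ifelse(d == 0, 1, 0)
  }
  t[skipped] <- NA_real_; p[skipped] <- NA_real_
  data.frame(t = t, p = p, meanIn = m1, meanOut = m2,
             nIn = n1, nOut = n2, df = df, skipped = skipped,
             row.names = rownames(x))
}

# Vectorized one-sample t of matrix rows against 0 (paired deltas).
rowOneSampleT <- function(x, minN = 3L) {
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  s <- sqrt(rowVarsNA(x))
  t <- m / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), n - 1)
  skipped <- n < minN
  zero <- !skipped & !is.na(s) & s == 0
  if (any(zero)) {
    t[zero] <- ifelse(m[zero] == 0, 0, sign(m[zero]) * Inf)
    p[zero] <- ifelse(m[zero] == 0, 1, 0)
  }
  t[skipped] <- NA_real_; p[skipped] <- NA_real_
  data.frame(t = t, p = p, mean = m, n = n, skipped = skipped,
             row.names = rownames(x))
}

#' One-sided 2x2 enrichment test with Fisher/chi-square switching
#'
#' Tests enrichment of a feature within a group using the 2x2 table
#' \code{(a, b; c, d)} where \code{a} counts feature-positive members of the
#' group, \code{b} feature-positive non-members, \code{c} feature-negative
#' members and \code{d} feature-negative non-members. Vectorized over the
#' four count vectors.
#'
#' With \code{method = "auto"}, Fisher's exact test (hypergeometric upper
#' tail) is used when any expected cell is below 5 or the table total is
#' below 200; otherwise a one-sided chi-square p is returned as half the
#' two-sided Pearson p in the enrichment direction (1 minus half otherwise).
#'
#' @param a,b,c,d Integer vectors of 2x2 cell counts (recycled to a common
#'   length).
#' @param method \code{"auto"}, \code{"fisher"} or \code{"chisq"}.
#' @return A data.frame with columns \code{a,b,c,d}, \code{odds} (sample
#'   odds ratio), \code{p} (one-sided enrichment p-value) and \code{method}.
#' @examples
#' enrichmentTest(8, 2, 12, 78)
#' @export
enrichmentTest <- function(a, b, c, d, method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE))
    stop("negative cell counts")
  tot <- a + b + c + d
  e11 <- (a + b) * (a + c) / tot
  e12 <- (a + b) * (b + d) / tot
  e21 <- (c + d) * (a + c) / tot
  e22 <- (c + d) * (b + d) / tot
  useFisher <- switch(method,
    fisher = rep(TRUE, n),
    chisq  = rep(FALSE, n),
    auto   = tot < 200 | pmin(e11, e12, e21, e22) < 5)
  useFisher[is.na(useFisher)] <- TRUE
  p <- numeric(n)
  if (any(useFisher)) {
    i <- which(useFisher)
    # P(X >= a) for X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
    p[i] <- stats::phyper(a[i] - 1, a[i] + b[i], c[i] + d[i], a[i] + c[i],
                          lower.tail = FALSE)
  }
  if (any(!useFisher)) {
    i <- which(!useFisher)
    stat <- (a[i] - e11[i])^2 / e11[i] + (b[i] - e12[i])^2 / e12[i] +
      (c[i] - e21[i])^2 / e21[i] + (d[i] - e22[i])^2 / e22[i]
    half <- stats::pchisq(stat, df = 1, lower.tail = FALSE) / 2
    p[i] <- ifelse(a[i] >= e11[i], half, 1 - half)
  }
  p <- pmin(pmax(p, 0), 1)
  data.frame(a = a, b = b, c = c, d = d,
             odds = (a * d) / (b * c),
             p = p,
             method = ifelse(useFisher, "fisher", "chisq"))
}

#' Storey-Tibshirani q-values
#'
#' Estimates the null proportion pi0 from the p-value histogram over a
#' lambda grid with a cubic smoothing spline, then converts p-values to
#' q-values with the usual monotone step-down.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param lambda Tuning grid for the pi0 estimate.
#' @return Numeric vector of q-values, same length/order as \code{p}.
#' @export
estimateQValues <- function(p, lambda = seq(0.05, 0.9, by = 0.05)) {
  ok <- !is.na(p)
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0) return(q)
  if (m < 30) {
    pi0 <- 1
  } else {
    pi0l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
    fit <- try(stats::smooth.spline(lambda, pi0l, df = 3), silent = TRUE)
    pi0 <- if (inherits(fit, "try-error")) min(pi0l) else
      stats::predict(fit, x = max(lambda))$y
    pi0 <- min(max(pi0, 1e-8), 1)
  }
  o <- order(pv, decreasing = TRUE)
  qv <- pi0 * pv[o] * m / rank(pv, ties.method = "max")[o]
  qv <- pmin(cummin(qv), 1)
  q[ok][o] <- qv
  q
}
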