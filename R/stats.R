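#' Wilcoxon signed-rank test with tie-aware exact p-values
#'
#' Paired differences of exactly zero are dropped (standard signed-rank
#' convention; this changes the effective n and is therefore reported).
#' Absolute differences are ranked with average ranks for ties; the statistic
#' is `W = min(W+, W-)`. For `n <= exact_max_n` the two-sided p-value is
#' exact, computed from the full null distribution of `W+` over all `2^n`
#' equally likely sign patterns (evaluated by generating-function convolution
#' over the doubled ranks, which are integers even under average-rank ties).
#' Above that, a normal approximation with continuity correction and the
#' usual tie correction of the variance is used. Two-sided p-values
#' throughout.
#'
#' @param a,b equal-length paired measurement vectors; or give `a` alone as
#'   the vector of differences.
#' @param exact_max_n largest n for which the exact distribution is used;
#'   default 25.
#' @return list with `W`, `W_plus`, `W_minus`, `n` (after dropping zeros),
#'   `p` (two-sided), `method` (`"exact"`/`"normal_approx"`), and
#'   `degenerate` flag (all differences zero; p = 1).
#' @export
wilcoxon_signed_rank <- function(a, b = NULL, exact_max_n = 25L) {
  d <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  stopifnot(all(is.finite(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(W = 0, W_plus = 0, W_minus = 0, n = 0L, p = 1,
                method = "degenerate", degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_max_n) {
    # distribution of 2*W+ over 0..sum(2r): f starts as point mass at 0 and
    # each rank contributes a factor (1 + x^(2 r_i)) / 2
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- c(1, numeric(total))
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    wp2 <- as.integer(round(2 * w_plus))
    p_le <- sum(f[1:(wp2 + 1)])
    p_ge <- sum(f[(wp2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)    # continuity correction toward the mean
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  list(W = w, W_plus = w_plus, W_minus = w_minus, n = n, p = p,
       method = method, degenerate = FALSE)
}

#' z-score of a measurement against a norm row
#'
#' `(measurement - mean) / SD` against the population mean and SD of the
#' relevant tooth type.
#'
#' @param measurement mm.
#' @param norm_row one-row data.frame with `mean_mm` and `sd_mm` (see
#'   [norm_lookup()]), or a numeric `c(mean, sd)`.
#' @return numeric z-score.
#' @export
zscore <- function(measurement, norm_row) {
  if (is.data.frame(norm_row)) {
    m <- norm_row$mean_mm[1]; s <- norm_row$sd_mm[1]
  } else {
    m <- norm_row[1]; s <- norm_row[2]
  }
  if (is.null(m) || is.na(m) || is.null(s) || is.na(s)) {
    stop("missing norm row", call. = FALSE)
  }
  if (s <= 0) stop("norm SD must be > 0", call. = FALSE)
  (measurement - m) / s
}

#' Dahlberg's double-determination error
#'
#' `sqrt(sum((a - b)^2) / (2 n))` over duplicate measurement sessions: the
#' standard random-error estimate for repeated landmark measurements. When
#' each session carries independent noise of SD sigma, the estimate converges
#' to sigma.
#'
#' @param a,b equal-length duplicate measurement vectors (mm).
#' @return mm.
#' @export
dahlberg <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 1, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2) / (2 * length(a)))
}

#' Intraclass correlation ICC(1,1) of duplicate sessions
#'
#' One-way random-effects intraclass correlation from the two-session ANOVA
#' decomposition: `(MSB - MSW) / (MSB + (k-1) MSW)` with k = 2 raters
#' (sessions). Undefined (flagged, `NA`) when there is no between-subject
#' variance.
#'
#' @param a,b equal-length duplicate measurement vectors.
#' @return list with `icc` and `undefined` flag.
#' @export
icc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  k <- 2
  m <- cbind(a, b)
  subj_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((subj_means - grand)^2) / (n - 1)
  msw <- sum((m - subj_means)^2) / (n * (k - 1))
  denom <- msb + (k - 1) * msw
  if (denom < .Machine$double.eps) {
    return(list(icc = NA_real_, undefined = TRUE))
  }
  list(icc = (msb - msw) / denom, undefined = FALSE)
}

#' Paired t test on duplicate sessions
#'
#' Thin wrapper over [stats::t.test()] for systematic-error checks between
#' measurement sessions; degenerate (zero-variance differences) input is
#' flagged instead of erroring.
#'
#' @param a,b equal-length duplicate measurement vectors.
#' @return list with `t`, `p`, `degenerate` flag.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < .Machine$double.eps) {
    return(list(t = NA_real_, p = if (all(d == 0)) 1 else NA_real_,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
}
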