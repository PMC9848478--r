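#' Effect-size level bins
#'
#' Maps an effect-size magnitude to the reporting levels used in the
#' figures: no practical difference (`n`) below 0.2, `*` in [0.2, 0.3),
#' `**` in [0.3, 0.5), `***` at 0.5 and above.
#'
#' @param r effect-size magnitude(s).
#' @return Character vector of levels.
#' @export
effect_level <- function(r) {
  ifelse(r < 0.2, "n", ifelse(r < 0.3, "*", ifelse(r < 0.5, "**", "***")))
}

new_effect_size <- function(statistic, value, n, z = NA_real_) {
  structure(list(statistic = statistic, value = value, n = as.integer(n),
                 level = effect_level(abs(value)), z = z),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %d, level %s)\n",
              x$statistic, x$value, x$n, x$level))
  invisible(x)
}

#' Wilcoxon effect size r
#'
#' Rank-based effect size `r = |Z| / sqrt(N)` where Z is the tie- and
#' continuity-corrected normal approximation of the rank statistic
#' (rank-sum for unpaired, signed-rank for paired) and N is the total
#' number of observations. The sign of Z is discarded; being rank-based,
#' r is invariant under strictly monotone transforms of the data.
#'
#' @param x,y numeric samples; equal length required when `paired`.
#' @param paired use the signed-rank statistic on `x - y`.
#' @return An `effect_size` object (`statistic = "wilcoxon_r"`).
#' @export
wilcoxon_effect_size <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    N <- length(x) + length(y)
    d <- x - y
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      warning("all paired differences are zero; r = 0")
      return(new_effect_size("wilcoxon_r", 0, N, 0))
    }
    rk <- rank(abs(d))
    V <- sum(rk[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0) {
      warning("degenerate tie structure; r = 0")
      return(new_effect_size("wilcoxon_r", 0, N, 0))
    }
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  } else {
    if (!length(x) || !length(y)) stop("both samples must be non-empty")
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    rk <- rank(c(x, y))
    W <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
    mu <- n1 * n2 / 2
    ties <- table(rk)
    sig2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      warning("all observations tied; r = 0")
      return(new_effect_size("wilcoxon_r", 0, N, 0))
    }
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  }
  new_effect_size("wilcoxon_r", abs(z) / sqrt(N), N, z)
}

#' Chi-square goodness-of-fit effect size (Cohen's w)
#'
#' `w = sqrt(chisq / N)` with `chisq = sum((O - E)^2 / E)` and
#' `N = sum(O)`. Observed and expected totals must agree (within
#' rounding); expected cells must be positive. w is invariant under
#' multiplying all counts by a constant.
#'
#' @param observed observed counts.
#' @param expected expected counts (same total).
#' @return An `effect_size` object (`statistic = "cohen_w"`) with the
#'   chi-square statistic in `$z`.
#' @examples
#' chisq_gof_effect_size(c(30, 10), c(20, 20))  # w = 0.5
#' @export
chisq_gof_effect_size <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have equal length")
  if (any(expected <= 0)) stop("expected cells must be > 0")
  if (abs(sum(observed) - sum(expected)) > max(1, 1e-6 * sum(observed)))
    stop("observed and expected totals disagree")
  chisq <- sum((observed - expected)^2 / expected)
  N <- sum(observed)
  new_effect_size("cohen_w", sqrt(chisq / N), N, chisq)
}

#' Chi-square goodness-of-fit test
#'
#' Classical test of observed counts against expected proportions, with
#' `k - 1` degrees of freedom.
#'
#' @param observed observed counts (length >= 2).
#' @param expected_proportions probabilities summing to 1.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_count_test <- function(observed,
                             expected_proportions = rep(1 / length(observed),
                                                        length(observed))) {
  k <- length(observed)
  if (k < 2) stop("need at least 2 categories (0 df otherwise)")
  if (abs(sum(expected_proportions) - 1) > 1e-8)
    stop("expected proportions must sum to 1")
  E <- sum(observed) * expected_proportions
  if (any(E < 1)) warning("expected count < 1 in some cell; test unreliable")
  stat <- sum((observed - E)^2 / E)
  list(statistic = stat, df = k - 1L,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE), expected = E)
}

#' Pearson correlation as an effect size
#'
#' @param x,y numeric vectors, length >= 3, neither constant.
#' @return An `effect_size` object (`statistic = "pearson_r"`).
#' @export
pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for constant input")
  new_effect_size("pearson_r", cor(x, y), length(x))
}
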