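#' Exact score distribution of a discretized PWM
#'
#' Computes, by position-by-position convolution, the probability that the
#' i.i.d. background generates a word with each attainable integer score.
#' Starting from unit mass at score 0, each position i sends mass at score s
#' to `s + iweights[i, letter]` with factor `p(letter)`. The result is the
#' full distribution Q(M, s) over `[min_score, max_score]`, from which
#' P-values are tail sums.
#'
#' The mass vector is dense, indexed by `score - offset`; with m positions
#' the cost is O((max_score - min_score) * m).
#'
#' @param x A `discrete_pwm` (see [discretize()]).
#' @param bg A [background].
#' @return An object of class `score_distribution`: `offset` (= `min_score`)
#'   and `mass`, the probability of each integer score from `offset` upward.
#' @examples
#' m <- discretize(pwm(matrix(c(1, 0, 0, 0), 1, 4)), d = 1)
#' score_distribution(m, background())  # mass 0.75 at 0, 0.25 at 1
#' @export
score_distribution <- function(x, bg = background_uniform()) {
  stopifnot(inherits(x, "discrete_pwm"), inherits(bg, "pwm_background"))
  iw <- x$iweights
  m <- nrow(iw)
  lo_cum <- cumsum(apply(iw, 1, min))
  hi_cum <- cumsum(apply(iw, 1, max))
  mass <- 1           # mass over [lo, hi] after i positions; starts at score 0
  lo <- 0
  p <- as.numeric(bg)
  for (i in seq_len(m)) {
    new_lo <- lo_cum[i]
    new_mass <- numeric(hi_cum[i] - new_lo + 1)
    for (a in 1:4) {
      off <- lo + iw[i, a] - new_lo      # index shift for this letter
      idx <- seq_along(mass) + off
      new_mass[idx] <- new_mass[idx] + mass * p[a]
    }
    mass <- new_mass
    lo <- new_lo
  }
  structure(list(offset = lo, mass = mass), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat("Score distribution over [", x$offset, ", ",
      x$offset + length(x$mass) - 1, "], total mass ",
      format(sum(x$mass)), "\n", sep = "")
  invisible(x)
}

tail_probability <- function(dist, t) {
  hi <- dist$offset + length(dist$mass) - 1
  if (t <= dist$offset) return(sum(dist$mass))
  if (t > hi) return(0)
  sum(dist$mass[(t - dist$offset + 1):length(dist$mass)])
}

#' P-value of a score threshold
#'
#' The probability that the background generates a word scoring at least `t`
#' (threshold comparison is inclusive). Equals 1 for `t <= min_score` and 0
#' for `t > max_score`.
#'
#' @param x A `discrete_pwm`, or a precomputed `score_distribution`.
#' @param t Integer threshold on the discretized score scale.
#' @param bg A [background] (ignored when `x` is already a distribution).
#' @return A probability.
#' @export
pvalue_from_threshold <- function(x, t, bg = background_uniform()) {
  dist <- if (inherits(x, "score_distribution")) x else score_distribution(x, bg)
  stopifnot(is.numeric(t), length(t) == 1)
  tail_probability(dist, ceiling(t))
}

#' Threshold for a requested P-value
#'
#' Finds the integer threshold whose P-value brackets the requested one.
#' Because scores are discrete, the requested P-value is usually not exactly
#' attainable; both bracketing conventions are exposed:
#' `strong` (default) returns the smallest threshold with actual P-value
#' <= requested — the conservative choice, never admitting more words than
#' asked for; `weak` returns the largest threshold with actual P-value >=
#' requested.
#'
#' @param x A `discrete_pwm`, or a precomputed `score_distribution`.
#' @param p Requested P-value in (0, 1].
#' @param bg A [background] (ignored when `x` is already a distribution).
#' @param mode `"strong"` or `"weak"`.
#' @return An object of class `threshold_result` with fields `threshold`
#'   (integer score), `actual_pvalue`, `requested_pvalue` and `mode`.
#' @examples
#' m <- discretize(pwm(matrix(c(2, 1, 0, -1), 1, 4)), d = 1)
#' threshold_from_pvalue(m, 0.3, mode = "strong")  # t = 2, actual 0.25
#' threshold_from_pvalue(m, 0.3, mode = "weak")    # t = 1, actual 0.5
#' @export
threshold_from_pvalue <- function(x, p, bg = background_uniform(),
                                  mode = c("strong", "weak")) {
  mode <- match.arg(mode)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p <= 0 || p > 1)
    stop("requested P-value must lie in (0, 1]")
  dist <- if (inherits(x, "score_distribution")) x else score_distribution(x, bg)
  hi <- dist$offset + length(dist$mass) - 1
  # P(t) over integer thresholds min_score .. max_score + 1 (rev cumsum tail)
  pv <- rev(cumsum(rev(dist$mass)))
  ts <- dist$offset:(hi + 1L)
  pv <- c(pv, 0)
  if (mode == "strong") {
    k <- which(pv <= p + 1e-15)[1]   # pv non-increasing; first qualifying t
  } else {
    k <- max(which(pv >= p - 1e-15))
  }
  structure(list(threshold = ts[k], actual_pvalue = pv[k],
                 requested_pvalue = p, mode = mode),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(x$mode, " threshold ", x$threshold, ": actual P-value ",
      format(x$actual_pvalue), " (requested ", format(x$requested_pvalue),
      ")\n", sep = "")
  invisible(x)
}
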