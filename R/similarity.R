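#' Align two discretized PWMs at a given shift and orientation
#'
#' Places column 1 of the first matrix against column `1 + shift` of the
#' second (`shift` ranges over `(1 - m1) .. (m2 - 1)`, so the overlap is at
#' least one column) and pads every hanging position of either matrix with
#' zero columns. With `orientation = "revcomp"` the second matrix is
#' reverse-complemented before placement. Zero-column padding leaves each
#' matrix's score distribution and P-values unchanged, so the aligned pair
#' defines scores for one shared dictionary of words without perturbing
#' either model.
#'
#' @param m1,m2 `discrete_pwm` objects at the same discretization level.
#' @param shift Integer displacement of matrix 1 relative to matrix 2.
#' @param orientation `"direct"` or `"revcomp"`.
#' @return An object of class `aligned_pair`: padded `first` and `second`
#'   (equal-width `discrete_pwm`s), the `shift`, `orientation` and `width`.
#' @export
align_pwms <- function(m1, m2, shift = 0,
                       orientation = c("direct", "revcomp")) {
  stopifnot(inherits(m1, "discrete_pwm"), inherits(m2, "discrete_pwm"))
  orientation <- match.arg(orientation)
  w1 <- nrow(m1$iweights); w2 <- nrow(m2$iweights)
  if (shift < 1 - w1 || shift > w2 - 1)
    stop("shift ", shift, " outside [", 1 - w1, ", ", w2 - 1, "]")
  if (orientation == "revcomp") m2 <- reverse_complement(m2)
  pads <- alignment_padding(w1, w2, shift)
  structure(list(first = pad_discrete(m1, pads$l1, pads$r1),
                 second = pad_discrete(m2, pads$l2, pads$r2),
                 shift = as.integer(shift), orientation = orientation,
                 width = pads$w),
            class = "aligned_pair")
}

# zero-padding counts placing column 1 of matrix 1 at column 1+shift of
# matrix 2; positive shift pads matrix 1 on the left
alignment_padding <- function(w1, w2, shift) {
  start1 <- 1 + shift
  lo <- min(start1, 1)
  w <- max(start1 + w1 - 1, w2) - lo + 1
  l1 <- start1 - lo
  l2 <- 1 - lo
  list(w = w, l1 = l1, r1 = w - l1 - w1, l2 = l2, r2 = w - l2 - w2)
}

pad_discrete <- function(x, left, right) {
  if (left == 0 && right == 0) return(x)
  iw <- rbind(matrix(0, left, 4), x$iweights, matrix(0, right, 4))
  dimnames(iw) <- list(NULL, DNA)
  structure(list(source = extend_zero_columns(x$source, left, right),
                 d = x$d, iweights = iw,
                 min_score = x$min_score, max_score = x$max_score),
            class = "discrete_pwm")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("Aligned pair: width ", x$width, ", shift ", x$shift, ", ",
      x$orientation, " orientation\n", sep = "")
  invisible(x)
}

# Sparse joint DP over prefix score pairs. iw1, iw2: equal-width integer
# weight matrices; returns list(s1, s2, weight). With pruning, prefixes that
# cannot reach t1 on matrix 1 or t2 on matrix 2 even with the best remaining
# suffix are dropped — the cells that survive to the end are exactly those
# counted by the intersection sum, so pruning never changes it.
joint_dp <- function(iw1, iw2, p, t1 = -Inf, t2 = -Inf, prune = FALSE) {
  w <- nrow(iw1)
  stopifnot(nrow(iw2) == w)
  suf1 <- rev(c(0, cumsum(rev(apply(iw1, 1, max)))))[-1]  # rows i+1 .. w
  suf2 <- rev(c(0, cumsum(rev(apply(iw2, 1, max)))))[-1]
  lo2_cum <- cumsum(apply(iw2, 1, min))
  hi2_cum <- cumsum(apply(iw2, 1, max))
  s1 <- 0; s2 <- 0; wt <- 1
  for (i in seq_len(w)) {
    n <- length(wt)
    s1 <- rep(s1, 4) + rep(iw1[i, ], each = n)
    s2 <- rep(s2, 4) + rep(iw2[i, ], each = n)
    wt <- rep(wt, 4) * rep(p, each = n)
    if (prune) {
      keep <- (s1 + suf1[i] >= t1) & (s2 + suf2[i] >= t2)
      s1 <- s1[keep]; s2 <- s2[keep]; wt <- wt[keep]
      if (length(wt) == 0) return(list(s1 = numeric(0), s2 = numeric(0),
                                       weight = numeric(0)))
    }
    # collapse duplicate (s1, s2) cells
    K <- hi2_cum[i] - lo2_cum[i] + 1
    key <- (s2 - lo2_cum[i]) + K * s1     # s1 offset irrelevant for grouping
    o <- order(key)
    key <- key[o]; s1 <- s1[o]; s2 <- s2[o]; wt <- wt[o]
    first <- c(TRUE, diff(key) > 0)
    grp <- cumsum(first)
    wt <- as.vector(rowsum(wt, grp))
    s1 <- s1[first]; s2 <- s2[first]
  }
  list(s1 = s1, s2 = s2, weight = wt)
}

#' Joint score-pair distribution of two aligned PWMs
#'
#' Runs the two-dimensional dynamic program over word prefixes: a sparse
#' table keyed by the pair of prefix scores `(S1, S2)` holds the probability
#' that the background generates a prefix with those scores; each position
#' update sends cell `(S1, S2)` to `(S1 + w1(i, a), S2 + w2(i, a))` with
#' factor `p(a)` for each letter `a`. After the last position the table is
#' the joint distribution of the two word scores, and the intersection
#' probability is the sum over cells passing both thresholds.
#'
#' With `prune = TRUE`, cells whose score plus the best attainable suffix
#' score falls short of the threshold on either matrix are discarded early;
#' this loses parts of the table but provably not the intersection mass.
#'
#' @param pair An `aligned_pair` from [align_pwms()].
#' @param bg A [background].
#' @param t1,t2 Integer thresholds (required when `prune = TRUE`).
#' @param prune Drop cells that cannot reach both thresholds.
#' @return An object of class `joint_score_table` with parallel vectors
#'   `s1`, `s2`, `weight`.
#' @export
joint_score_table <- function(pair, bg = background_uniform(),
                              t1 = -Inf, t2 = -Inf, prune = FALSE) {
  stopifnot(inherits(pair, "aligned_pair"), inherits(bg, "pwm_background"))
  tab <- joint_dp(pair$first$iweights, pair$second$iweights,
                  as.numeric(bg), t1, t2, prune)
  structure(c(tab, list(pruned = prune, t1 = t1, t2 = t2)),
            class = "joint_score_table")
}

#' @export
print.joint_score_table <- function(x, ...) {
  cat("Joint score table: ", length(x$weight), " cells, total weight ",
      format(sum(x$weight)), if (x$pruned) " (pruned)", "\n", sep = "")
  invisible(x)
}

#' Probability that a background word passes both thresholds
#'
#' Sums the joint table over all score pairs with `s1 >= t1` and `s2 >= t2` —
#' the probability weight of the intersection of the two recognized word
#' sets. The table must be unpruned, or pruned against the same thresholds.
#'
#' @param table A `joint_score_table`.
#' @param t1,t2 Integer thresholds.
#' @return A probability.
#' @export
intersection_probability <- function(table, t1, t2) {
  stopifnot(inherits(table, "joint_score_table"))
  sum(table$weight[table$s1 >= t1 & table$s2 >= t2])
}

#' Jaccard similarity of two aligned TFBS models
#'
#' For one fixed alignment, the similarity is the conditional probability
#' that a random background word passes both thresholds given that it passes
#' at least one: `J1 = P(both) / (P1 + P2 - P(both))`. Under a uniform
#' background this is literally the Jaccard index of the two recognized word
#' sets. `P1` and `P2` come from the one-dimensional score distribution of
#' each aligned matrix (padding does not change them). Returns 0 when the
#' union has no mass.
#'
#' @param pair An `aligned_pair`.
#' @param t1,t2 Integer thresholds on the two matrices' discretized scales.
#' @param bg A [background].
#' @return A list with `jaccard` (J1) and the components `p_intersection`,
#'   `p_union`, `p1`, `p2`.
#' @export
jaccard_aligned <- function(pair, t1, t2, bg = background_uniform()) {
  stopifnot(inherits(pair, "aligned_pair"))
  p1 <- pvalue_from_threshold(pair$first, t1, bg)
  p2 <- pvalue_from_threshold(pair$second, t2, bg)
  pint <- intersection_probability(
    joint_score_table(pair, bg, t1, t2, prune = TRUE), t1, t2)
  punion <- p1 + p2 - pint
  list(jaccard = if (punion > 0) pint / punion else 0,
       p_intersection = pint, p_union = punion, p1 = p1, p2 = p2)
}

# shifts ordered by the alignment tie-break: smaller |shift| first, negative
# before positive on equal magnitude
ordered_shifts <- function(w1, w2) {
  s <- (1 - w1):(w2 - 1)
  s[order(abs(s), s)]
}

#' Best-alignment Jaccard similarity of two TFBS models
#'
#' The headline similarity J2: the maximum single-alignment Jaccard index J1
#' over all relative shifts of the two matrices (every overlap of at least
#' one column) and, optionally, over the reverse-complement orientation of
#' the second model — `2 * (m1 + m2 - 1)` alignments in all. The reported
#' distance `D2 = 1 - J2` is a proper metric on TFBS models compared at
#' fixed P-value levels.
#'
#' Each model's threshold is obtained either from a shared (or per-model)
#' P-value — derived in strong mode on the discretized matrix, the default
#' pathway, which keeps the two recognized word sets comparable in size — or
#' from real score thresholds mapped to the integer scale by
#' [discretize_threshold()].
#'
#' The orientation search requires a strand-symmetric background: only then
#' is the reverse-complemented model's P-value the same as the original's,
#' which the maximization relies on. Ties between alignments are broken
#' deterministically: direct orientation over reverse-complement, then
#' smaller absolute shift, then the negative shift.
#'
#' @param x,y [pwm] objects (or `discrete_pwm`s already at level `d`).
#' @param bg A [background]; must be strand-symmetric unless
#'   `both_strands = FALSE`.
#' @param d Discretization level used for the comparison (both matrices).
#' @param pvalue Requested P-value, recycled to both models (default 0.0005).
#' @param thresholds Optional length-2 real thresholds; overrides `pvalue`.
#' @param ithresholds Optional length-2 integer thresholds already on the
#'   discretized scale; overrides both `pvalue` and `thresholds`.
#' @param both_strands Search the reverse-complement orientation as well.
#' @param prune Use suffix-bound pruning in the joint DP.
#' @param keep_alignments Keep the per-alignment J1 table as a data frame
#'   (diagnostic).
#' @return An object of class `pwm_similarity`: `jaccard` (J2), `distance`
#'   (D2), `shift`, `orientation`, `p_intersection`, `p_union`, `p1`, `p2`,
#'   the integer `thresholds`, `d`, and the model `names`.
#' @examples
#' m <- random_pwm(8, seed = 1)
#' jaccard_best(m, m, pvalue = 0.001)        # J2 = 1 at shift 0
#' jaccard_best(m, reverse_complement(m), pvalue = 0.001)
#' @export
jaccard_best <- function(x, y, bg = background_uniform(), d = 10,
                         pvalue = 0.0005, thresholds = NULL,
                         ithresholds = NULL, both_strands = TRUE,
                         prune = TRUE, keep_alignments = FALSE) {
  stopifnot(inherits(bg, "pwm_background"))
  if (both_strands && !is_symmetric_background(bg))
    stop("orientation search needs a strand-symmetric background ",
         "(p(A) = p(T), p(C) = p(G)); use both_strands = FALSE")
  d1 <- if (inherits(x, "discrete_pwm")) x else discretize(x, d)
  d2 <- if (inherits(y, "discrete_pwm")) y else discretize(y, d)
  if (!isTRUE(all.equal(d1$d, d2$d)))
    stop("both models must be discretized at the same level")
  d <- d1$d

  if (!is.null(ithresholds)) {
    stopifnot(is.numeric(ithresholds), length(ithresholds) == 2)
    t1 <- ithresholds[1]; t2 <- ithresholds[2]
    p1 <- pvalue_from_threshold(d1, t1, bg)
    p2 <- pvalue_from_threshold(d2, t2, bg)
  } else if (!is.null(thresholds)) {
    stopifnot(is.numeric(thresholds), length(thresholds) == 2)
    t1 <- discretize_threshold(thresholds[1], d)
    t2 <- discretize_threshold(thresholds[2], d)
    p1 <- pvalue_from_threshold(d1, t1, bg)
    p2 <- pvalue_from_threshold(d2, t2, bg)
  } else {
    pvalue <- rep_len(pvalue, 2)
    tr1 <- threshold_from_pvalue(d1, pvalue[1], bg, mode = "strong")
    tr2 <- threshold_from_pvalue(d2, pvalue[2], bg, mode = "strong")
    t1 <- tr1$threshold; p1 <- tr1$actual_pvalue
    t2 <- tr2$threshold; p2 <- tr2$actual_pvalue
  }

  p <- as.numeric(bg)
  w1 <- nrow(d1$iweights); w2 <- nrow(d2$iweights)
  orientations <- if (both_strands) c("direct", "revcomp") else "direct"
  shifts <- ordered_shifts(w1, w2)

  best <- list(jaccard = -1)
  diag_rows <- if (keep_alignments) vector("list", 2 * length(shifts)) else NULL
  k <- 0
  for (ori in orientations) {
    iw2o <- if (ori == "revcomp") revcomp_matrix(d2$iweights) else d2$iweights
    for (s in shifts) {
      pads <- alignment_padding(w1, w2, s)
      iw1p <- rbind(matrix(0, pads$l1, 4), d1$iweights, matrix(0, pads$r1, 4))
      iw2p <- rbind(matrix(0, pads$l2, 4), iw2o, matrix(0, pads$r2, 4))
      tab <- joint_dp(iw1p, iw2p, p, t1, t2, prune = prune)
      pint <- sum(tab$weight[tab$s1 >= t1 & tab$s2 >= t2])
      punion <- p1 + p2 - pint
      j1 <- if (punion > 0) pint / punion else 0
      if (keep_alignments) {
        k <- k + 1
        diag_rows[[k]] <- data.frame(shift = s, orientation = ori,
                                     jaccard = j1, p_intersection = pint)
      }
      if (j1 > best$jaccard + 1e-12) {
        best <- list(jaccard = j1, shift = s, orientation = ori,
                     p_intersection = pint, p_union = punion)
      }
    }
  }

  res <- list(jaccard = best$jaccard, distance = 1 - best$jaccard,
              shift = best$shift, orientation = best$orientation,
              p_intersection = best$p_intersection, p_union = best$p_union,
              p1 = p1, p2 = p2, thresholds = c(t1, t2), d = d,
              names = c(d1$source$name, d2$source$name))
  if (keep_alignments)
    res$alignments <- do.call(rbind, diag_rows[seq_len(k)])
  structure(res, class = "pwm_similarity")
}

#' @export
print.pwm_similarity <- function(x, ...) {
  cat("TFBS model similarity: ", x$names[1], " vs ", x$names[2], "\n",
      "  J2 = ", format(x$jaccard, digits = 6),
      "  (D2 = ", format(x$distance, digits = 6), ")\n",
      "  best alignment: shift ", x$shift, ", ", x$orientation,
      " orientation\n",
      "  P(both) = ", format(x$p_intersection, digits = 6),
      ", P(either) = ", format(x$p_union, digits = 6),
      "; P1 = ", format(x$p1, digits = 6),
      ", P2 = ", format(x$p2, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Distance between two TFBS models
#'
#' `D2 = 1 - J2`; zero exactly for a model against itself, symmetric in its
#' arguments, and satisfying the triangle inequality, so it defines a proper
#' metric on models compared at fixed P-value levels.
#'
#' @inheritParams jaccard_best
#' @param ... Passed to [jaccard_best()].
#' @return The distance, a number in `[0, 1]`.
#' @export
tfbs_distance <- function(x, y, ...) jaccard_best(x, y, ...)$distance
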