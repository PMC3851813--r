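# run code under a fixed RNG seed without disturbing the caller's RNG state;
# derived seeds can exceed the 32-bit range set.seed accepts, so reduce first
with_seed <- function(seed, code) {
  seed <- as.integer(round(seed) %% .Machine$integer.max)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded synthetic PWM generator
#'
#' Builds reproducible random PWMs for testing and benchmarking; the same
#' seed and parameters always give the cell-identical matrix. Three weight
#' models are available:
#'
#' * `"logodds"` (default): per-position letter frequencies are drawn from a
#'   sparse Dirichlet (concentration `alpha`, so most positions have a
#'   dominant letter, as real motifs do) and converted to log-odds against
#'   `bg`, giving realistic matrices mixing positive and negative weights.
#' * `"uniform"`: i.i.d. uniform real weights on `[-1, 1]`.
#' * `"counts"`: non-negative integer counts per column (multinomial draws
#'   of `depth` observations), emulating raw count matrices.
#'
#' @param m Motif width (positions), at least 1.
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param model Weight model, see above.
#' @param bg [background] used for the log-odds conversion.
#' @param alpha Dirichlet concentration of the `"logodds"` model.
#' @param depth Observation count per column of the `"counts"` model.
#' @param name Motif name; defaults to one derived from the seed.
#' @return A [pwm].
#' @examples
#' random_pwm(6, seed = 42)
#' @export
random_pwm <- function(m, seed = 1,
                       model = c("logodds", "uniform", "counts"),
                       bg = background_uniform(), alpha = 0.5,
                       depth = 100, name = NULL) {
  model <- match.arg(model)
  if (!is.numeric(m) || length(m) != 1 || m < 1)
    stop("width m must be a positive integer")
  m <- as.integer(m)
  if (is.null(name)) name <- sprintf("random_%s_m%d_s%d", model, m, seed)
  mat <- with_seed(seed, {
    switch(model,
      logodds = {
        g <- matrix(stats::rgamma(4 * m, shape = alpha), m, 4)
        f <- (g + 1e-3) / rowSums(g + 1e-3)
        log(f / rep(as.numeric(bg), each = m))
      },
      uniform = matrix(stats::runif(4 * m, -1, 1), m, 4),
      counts = t(stats::rmultinom(m, size = depth, prob = rep(0.25, 4)))
    )
  })
  pwm(mat, name = name)
}

#' Perturb a PWM with seeded Gaussian noise
#'
#' Adds independent normal noise to every cell, producing a "same-TF-like"
#' relative of the input — the kind of variation seen between motifs built
#' for the same factor from different experiments. With `noise_sd = 0` the
#' matrix is returned unchanged.
#'
#' @param x A [pwm].
#' @param noise_sd Standard deviation of the per-cell noise (score units).
#' @param seed Integer seed.
#' @return A [pwm].
#' @export
perturb_pwm <- function(x, noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(x, "pwm"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (noise_sd == 0) return(pwm(x$weights, name = paste0(x$name, "_perturbed")))
  mat <- x$weights +
    with_seed(seed, matrix(stats::rnorm(4 * x$width, 0, noise_sd), x$width, 4))
  pwm(mat, name = paste0(x$name, "_perturbed"))
}

#' Write a directory of synthetic PWM fixture files
#'
#' Generates `n` seeded random PWMs (widths drawn from `widths`) and writes
#' each to `<dir>/<name>.pwm` in the flat-file format of [write_pwm()].
#'
#' @param dir Output directory (created if missing).
#' @param n Number of matrices.
#' @param seed Master seed; entry i uses `seed * 1000 + i`.
#' @param widths Candidate motif widths, sampled per entry.
#' @param model Weight model for [random_pwm()].
#' @return Invisibly, the vector of file paths.
#' @export
write_fixture_collection <- function(dir, n = 10, seed = 1, widths = 6:12,
                                     model = "logodds") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ws <- with_seed(seed, sample(widths, n, replace = TRUE))
  paths <- character(n)
  for (i in seq_len(n)) {
    p <- random_pwm(ws[i], seed = seed * 1000 + i, model = model,
                    name = sprintf("fix%03d", i))
    paths[i] <- file.path(dir, sprintf("fix%03d.pwm", i))
    write_pwm(p, paths[i])
  }
  invisible(paths)
}

#' Brute-force Jaccard similarity by word enumeration
#'
#' Independent oracle for the dynamic programs: enumerates every word of the
#' aligned width, scores it under both matrices, and accumulates the
#' intersection and union probabilities literally from the set definitions.
#' With `shift` given, evaluates that single alignment (J1); with
#' `shift = NULL`, maximizes over every shift and both orientations (J2).
#' Enumeration is exponential, so the aligned width is capped.
#'
#' @param m1,m2 `discrete_pwm` objects.
#' @param t1,t2 Integer thresholds.
#' @param bg A [background].
#' @param shift Single alignment shift, or `NULL` to maximize over all.
#' @param orientation Orientation for the single-alignment form.
#' @param max_width Refuse enumeration beyond this aligned width.
#' @return A list with `jaccard` and components `p_intersection`, `p_union`,
#'   `p1`, `p2` (single alignment), or `jaccard` plus the best `shift` and
#'   `orientation` (maximized form).
#' @export
brute_force_jaccard <- function(m1, m2, t1, t2, bg = background_uniform(),
                                shift = NULL,
                                orientation = c("direct", "revcomp"),
                                max_width = 10) {
  stopifnot(inherits(m1, "discrete_pwm"), inherits(m2, "discrete_pwm"))
  orientation <- match.arg(orientation)
  w1 <- nrow(m1$iweights); w2 <- nrow(m2$iweights)
  if (!is.null(shift)) {
    pads <- alignment_padding(w1, w2, shift)
    if (pads$w > max_width)
      stop("aligned width ", pads$w, " exceeds the enumeration cap ",
           max_width)
    iw2 <- if (orientation == "revcomp") revcomp_matrix(m2$iweights)
           else m2$iweights
    iw1p <- rbind(matrix(0, pads$l1, 4), m1$iweights, matrix(0, pads$r1, 4))
    iw2p <- rbind(matrix(0, pads$l2, 4), iw2, matrix(0, pads$r2, 4))
    return(enumerate_pair(iw1p, iw2p, t1, t2, as.numeric(bg)))
  }
  if (max(w1, w2) + min(w1, w2) - 1 > max_width)
    stop("worst-case aligned width exceeds the enumeration cap ", max_width)
  best <- NULL
  for (ori in c("direct", "revcomp")) {
    for (s in ordered_shifts(w1, w2)) {
      r <- brute_force_jaccard(m1, m2, t1, t2, bg, shift = s,
                               orientation = ori, max_width = max_width)
      if (is.null(best) || r$jaccard > best$jaccard + 1e-12) {
        best <- r; best$shift <- s; best$orientation <- ori
      }
    }
  }
  best
}

# score every word of length w under both matrices and apply the set
# definitions directly
enumerate_pair <- function(iw1, iw2, t1, t2, p) {
  s1 <- 0; s2 <- 0; pr <- 1
  for (i in seq_len(nrow(iw1))) {
    n <- length(pr)
    s1 <- rep(s1, 4) + rep(iw1[i, ], each = n)
    s2 <- rep(s2, 4) + rep(iw2[i, ], each = n)
    pr <- rep(pr, 4) * rep(p, each = n)
  }
  in1 <- s1 >= t1; in2 <- s2 >= t2
  pint <- sum(pr[in1 & in2])
  punion <- sum(pr[in1 | in2])
  list(jaccard = if (punion > 0) pint / punion else 0,
       p_intersection = pint, p_union = punion,
       p1 = sum(pr[in1]), p2 = sum(pr[in2]))
}
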