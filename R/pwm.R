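DNA <- c("A", "C", "G", "T")

#' Background letter probabilities
#'
#' An i.i.d. (Bernoulli) background model over the DNA alphabet. Words are
#' generated letter by letter with fixed probabilities, so the probability of
#' a word is the product of its letter probabilities. A background is
#' *strand-symmetric* when `p(A) = p(T)` and `p(C) = p(G)`; symmetry is
#' required for the reverse-complement orientation search, because only then
#' does reverse-complementing a PWM leave its score distribution (and hence
#' its P-values) unchanged.
#'
#' @param a,c,g,t Letter probabilities; must be non-negative and sum to 1.
#' @return An object of class `pwm_background`: a named numeric vector of the
#'   four letter probabilities.
#' @examples
#' background(0.3, 0.2, 0.2, 0.3)
#' @export
background <- function(a = 0.25, c = 0.25, g = 0.25, t = 0.25) {
  p <- c(A = a, C = c, G = g, T = t)
  if (any(!is.finite(p)) || any(p < 0))
    stop("background probabilities must be finite and non-negative")
  if (abs(sum(p) - 1) > 1e-12)
    stop("background probabilities must sum to 1 (got ", sum(p), ")")
  structure(p, class = "pwm_background")
}

#' @rdname background
#' @export
background_uniform <- function() background()

#' @rdname background
#' @param gc GC content in `[0, 1]`; builds the strand-symmetric background
#'   with `p(C) = p(G) = gc/2` and `p(A) = p(T) = (1 - gc)/2`.
#' @export
background_gc <- function(gc) {
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  background((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
}

#' @rdname background
#' @param bg A `pwm_background`.
#' @export
is_symmetric_background <- function(bg) {
  stopifnot(inherits(bg, "pwm_background"))
  abs(bg[["A"]] - bg[["T"]]) <= 1e-12 && abs(bg[["C"]] - bg[["G"]]) <= 1e-12
}

#' @export
print.pwm_background <- function(x, ...) {
  cat("i.i.d. background: A=", format(x[["A"]]), " C=", format(x[["C"]]),
      " G=", format(x[["G"]]), " T=", format(x[["T"]]),
      if (is_symmetric_background(x)) " (strand-symmetric)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Position weight matrix
#'
#' A PWM assigns an additive per-position, per-letter score to DNA words of a
#' fixed length m: the score of a word is the sum, over positions, of the
#' weight of the letter at that position. Weights are taken as-is — raw
#' counts, frequencies, or log-odds all work, since the similarity measure
#' compares the recognized word sets, not the matrix cells.
#'
#' Internally the matrix is stored position-major: m rows by 4 columns in
#' A, C, G, T order.
#'
#' @param weights Numeric matrix with 4 columns (positions in rows), or a
#'   4-row matrix which is transposed on input when it cannot be row-form.
#' @param name Text label for the motif.
#' @return An object of class `pwm` with elements `name`, `width` and
#'   `weights` (an m x 4 matrix with columns A, C, G, T).
#' @examples
#' pwm(rbind(c(2, 0, 0, 0), c(0, 2, 1, 0)), name = "toy")
#' @export
pwm <- function(weights, name = "pwm") {
  weights <- as.matrix(weights)
  if (ncol(weights) != 4 && nrow(weights) == 4) weights <- t(weights)
  if (ncol(weights) != 4)
    stop("a PWM needs 4 letter columns (A, C, G, T); got ", ncol(weights))
  if (nrow(weights) < 1) stop("a PWM needs at least one position")
  if (!is.numeric(weights) || any(!is.finite(weights)))
    stop("PWM weights must all be finite numbers")
  storage.mode(weights) <- "double"
  dimnames(weights) <- list(NULL, DNA)
  structure(list(name = as.character(name)[1],
                 width = nrow(weights),
                 weights = weights),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM '", x$name, "': ", x$width, " position",
      if (x$width > 1) "s", "\n", sep = "")
  mat <- x$weights
  rownames(mat) <- seq_len(nrow(mat))
  print(round(mat, 4))
  invisible(x)
}

#' Read a PWM from a plain-text flat file
#'
#' Accepts the two common plain-matrix dialects: `rows` (one line per motif
#' position holding the four A C G T weights) and `columns` (four lines, one
#' per letter in A, C, G, T order, each holding one weight per position). An
#' optional header line — either `>`-prefixed or simply non-numeric — supplies
#' the motif name; otherwise the file name (minus extension) is used. In the
#' 4-line dialect a leading letter token per line (`A`, `C`, `G`, `T`, as in
#' some legacy collections) and stray brackets are tolerated.
#'
#' With `dialect = "auto"` the block shape decides: a 4 x m block with m != 4
#' is letter-rows (`columns` dialect), an m x 4 block is position-rows, and an
#' ambiguous 4 x 4 block is read as position-rows.
#'
#' @param file Path to the file (or a character vector of lines via `text`).
#' @param dialect One of `"auto"`, `"rows"`, `"columns"`.
#' @param text Optional character vector of lines, used instead of `file`.
#' @return A [pwm] object.
#' @seealso [write_pwm()]
#' @export
read_pwm <- function(file, dialect = c("auto", "rows", "columns"), text = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
    default_name <- tools::file_path_sans_ext(basename(file))
  } else {
    lines <- text
    default_name <- "pwm"
  }
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("empty PWM file")

  name <- default_name
  parse_line <- function(s) {
    toks <- strsplit(s, "[\\s\\[\\]|]+", perl = TRUE)[[1]]
    toks[nzchar(toks)]
  }
  first <- parse_line(lines[1])
  is_num <- function(tok) !is.na(suppressWarnings(as.numeric(tok)))
  # header: '>'-prefixed, or a line with any non-numeric token that is not a
  # letter-prefixed matrix row
  letter_row <- function(toks)
    length(toks) >= 2 && toks[1] %in% DNA && all(is_num(toks[-1]))
  if (startsWith(lines[1], ">")) {
    name <- sub("^>\\s*", "", lines[1])
    if (!nzchar(name)) name <- default_name
    lines <- lines[-1]; lineno <- lineno[-1]
  } else if (!all(is_num(first)) && !letter_row(first)) {
    name <- lines[1]
    lines <- lines[-1]; lineno <- lineno[-1]
  }
  if (length(lines) == 0) stop("PWM file has a header but no matrix block")

  rows <- lapply(lines, parse_line)
  prefixed <- vapply(rows, function(r) length(r) >= 2 && r[1] %in% DNA &&
                       all(is_num(r[-1])), logical(1))
  row_letters <- NULL
  if (all(prefixed) && length(rows) == 4) {
    row_letters <- vapply(rows, `[`, character(1), 1)
    rows <- lapply(rows, `[`, -1)
  }
  lens <- lengths(rows)
  if (length(unique(lens)) != 1)
    stop("non-rectangular matrix block: line ", lineno[which(lens != lens[1])[1]],
         " has ", lens[which(lens != lens[1])[1]], " values, expected ", lens[1])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad))
    stop("non-numeric value in matrix block at line ", lineno[bad[1]])
  block <- do.call(rbind, vals)

  if (!is.null(row_letters)) {
    if (!identical(row_letters, DNA))
      stop("letter-prefixed rows must appear in A, C, G, T order")
    if (dialect == "rows")
      stop("letter-prefixed block is the 4-row (columns) dialect")
    dialect <- "columns"
  }
  if (dialect == "auto") {
    dialect <- if (nrow(block) == 4 && ncol(block) != 4) "columns" else "rows"
  }
  if (dialect == "columns") {
    if (nrow(block) != 4)
      stop("columns dialect needs exactly 4 letter rows; got ", nrow(block))
    block <- t(block)
  } else if (ncol(block) != 4) {
    stop("rows dialect needs 4 values per line; got ", ncol(block))
  }
  pwm(block, name = name)
}

#' Write a PWM flat file
#'
#' Emits the position-rows dialect with a `>` name header, the form
#' [read_pwm()] reads back cell-exactly.
#'
#' @param x A [pwm].
#' @param file Output path or connection.
#' @export
write_pwm <- function(x, file) {
  stopifnot(inherits(x, "pwm"))
  lines <- c(paste0(">", x$name),
             apply(x$weights, 1, function(r)
               paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = "\t")))
  writeLines(lines, file)
  invisible(x)
}

#' Score a word under a PWM
#'
#' The score of a length-m word is the sum over positions of the weight of
#' the word's letter at that position.
#'
#' @param x A [pwm] (or `discrete_pwm`, scored on the integer scale).
#' @param word A character scalar over A, C, G, T of length `x$width`.
#' @return The additive score, a single number.
#' @examples
#' m <- pwm(rbind(c(1, 0, 0, 0), c(0, 2, 0, 0)))
#' score_word(m, "AC")  # 3
#' @export
score_word <- function(x, word) {
  w <- if (inherits(x, "discrete_pwm")) x$iweights else x$weights
  stopifnot(is.character(word), length(word) == 1)
  letters <- strsplit(toupper(word), "")[[1]]
  if (length(letters) != nrow(w))
    stop("word length ", length(letters), " != PWM width ", nrow(w))
  idx <- match(letters, DNA)
  if (anyNA(idx))
    stop("word contains letters outside A, C, G, T: ", word)
  sum(w[cbind(seq_along(idx), idx)])
}

#' Reverse complement of a PWM
#'
#' Produces the matrix recognizing the same binding sites on the opposite
#' strand: position order is reversed and the A/T and C/G weight columns are
#' swapped, so that for every word w, `score(M, w) == score(revcomp(M),
#' revcomp(w))`. Applying it twice returns the original matrix cell-exactly.
#'
#' @param x A [pwm] or `discrete_pwm`.
#' @return An object of the same class.
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

revcomp_matrix <- function(mat) {
  out <- mat[rev(seq_len(nrow(mat))), c(4, 3, 2, 1), drop = FALSE]
  dimnames(out) <- list(NULL, DNA)
  out
}

#' @export
reverse_complement.pwm <- function(x) {
  pwm(revcomp_matrix(x$weights), name = x$name)
}

#' @export
reverse_complement.discrete_pwm <- function(x) {
  out <- x
  out$source <- reverse_complement(x$source)
  out$iweights <- revcomp_matrix(x$iweights)
  out
}

#' Extend a PWM with zero columns
#'
#' Pads a PWM with all-zero positions on the left and/or right. Zero columns
#' contribute nothing to any word's score, so the score distribution and
#' every P-value are unchanged; this is the padding used to align matrices
#' of different widths.
#'
#' @param x A [pwm].
#' @param left,right Number of zero positions to add on each side.
#' @return A [pwm] of width `width + left + right`.
#' @export
extend_zero_columns <- function(x, left = 0, right = 0) {
  stopifnot(inherits(x, "pwm"))
  if (left < 0 || right < 0) stop("left and right must be non-negative")
  left <- as.integer(left); right <- as.integer(right)
  mat <- rbind(matrix(0, left, 4), x$weights, matrix(0, right, 4))
  pwm(mat, name = x$name)
}

#' Discretize a PWM
#'
#' Multiplies every weight by the discretization level `d` and rounds it up
#' (ceiling) to an integer. Ceiling (rather than round-to-nearest) makes the
#' derived integer threshold an upper bound for the requested P-value.
#' Discretization preserves word ranking up to ties and bounds the number of
#' distinct scores, which is what makes the exact dynamic programs tractable.
#'
#' @param x A [pwm].
#' @param d Positive discretization level. Larger values give finer score
#'   resolution at higher cost.
#' @return An object of class `discrete_pwm`: the source PWM, the level, the
#'   integer weight matrix, and the attainable integer score range
#'   `[min_score, max_score]` (sums of the column minima/maxima).
#' @export
discretize <- function(x, d) {
  stopifnot(inherits(x, "pwm"))
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0)
    stop("discretization level d must be a positive number")
  iw <- ceiling(d * x$weights)
  dimnames(iw) <- list(NULL, DNA)
  structure(list(source = x, d = d, iweights = iw,
                 min_score = sum(apply(iw, 1, min)),
                 max_score = sum(apply(iw, 1, max))),
            class = "discrete_pwm")
}

#' @export
print.discrete_pwm <- function(x, ...) {
  cat("Discretized PWM '", x$source$name, "' (d = ", format(x$d),
      "): scores in [", x$min_score, ", ", x$max_score, "]\n", sep = "")
  invisible(x)
}

#' Map a real-valued threshold to the discretized integer scale
#'
#' Uses the same ceiling convention as per-cell discretization, so a word
#' passing the integer threshold is guaranteed for words passing the real
#' threshold with margin; `ceil(d * t)`.
#'
#' @param t Real threshold.
#' @param d Discretization level.
#' @return Integer-valued threshold on the discretized score scale.
#' @export
discretize_threshold <- function(t, d) ceiling(d * t)
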