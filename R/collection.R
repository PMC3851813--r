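#' Build a PWM collection with precomputed thresholds
#'
#' Parses every PWM file in a directory and precomputes, for each entry, the
#' strong-mode integer threshold and its actual P-value at the collection's
#' shared P-value, at both the rough and the precise discretization level.
#' Caching the thresholds is what makes repeated scans cheap: a scan only
#' runs the joint DP, never the per-entry threshold search.
#'
#' One degenerate case is handled specially: at a coarse level the score
#' lumping can leave no attainable score with tail probability at or below
#' the requested P-value, so the strong threshold would recognize no word at
#' all (actual P-value 0) and every similarity against the entry — including
#' an identical matrix — would be 0. For such levels the weak threshold is
#' cached instead, keeping the recognized set non-empty.
#'
#' Files that fail to parse are recorded in `$errors` and skipped; an empty
#' directory (or one with no parseable file) is an error. Entries are kept
#' sorted by name so results never depend on directory listing order.
#'
#' @param dir Directory of PWM flat files (see [read_pwm()]).
#' @param pvalue Shared P-value for every model (default 0.0005).
#' @param d_rough,d_precise Discretization levels of the two scan passes.
#' @param bg A [background].
#' @return An object of class `pwm_collection`: `entries` (each with `name`,
#'   `pwm` and per-level cached `thresholds`), the shared parameters, and
#'   `errors` (named character vector of per-file failures).
#' @seealso [scan_collection()], [write_collection()]
#' @export
build_collection <- function(dir, pvalue = 0.0005, d_rough = 5,
                             d_precise = 10, bg = background_uniform()) {
  if (!dir.exists(dir)) stop("collection directory not found: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stop("no files in collection directory: ", dir)
  entries <- list()
  errors <- character(0)
  for (f in files) {
    entry <- tryCatch({
      p <- read_pwm(f)
      list(name = p$name, pwm = p,
           thresholds = cache_thresholds(p, pvalue, c(d_rough, d_precise), bg))
    }, error = function(e) e)
    if (inherits(entry, "error")) {
      errors[basename(f)] <- conditionMessage(entry)
    } else {
      entries[[entry$name]] <- entry
    }
  }
  if (length(entries) == 0)
    stop("no parseable PWM file in ", dir, " (", length(errors), " failed)")
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, pvalue = pvalue, d_rough = d_rough,
                 d_precise = d_precise, bg = bg, errors = errors),
            class = "pwm_collection")
}

# strong-mode threshold per level; when coarse discretization lumps so many
# words together that no attainable score has tail probability <= pvalue,
# the strong threshold admits no word at all (actual P-value 0) and a scan
# could not even recognize an identical matrix — fall back to the weak
# threshold, the only other bracketing choice, so the set stays non-empty
scan_threshold <- function(dp, pvalue, bg) {
  tr <- threshold_from_pvalue(dp, pvalue, bg, mode = "strong")
  if (tr$actual_pvalue == 0)
    tr <- threshold_from_pvalue(dp, pvalue, bg, mode = "weak")
  tr
}

cache_thresholds <- function(p, pvalue, levels, bg) {
  lapply(levels, function(d) {
    tr <- scan_threshold(discretize(p, d), pvalue, bg)
    list(d = d, threshold = tr$threshold, actual_pvalue = tr$actual_pvalue)
  })
}

#' @export
print.pwm_collection <- function(x, ...) {
  cat("PWM collection: ", length(x$entries), " entries at P-value ",
      format(x$pvalue), " (d = ", x$d_rough, " / ", x$d_precise, ")\n",
      sep = "")
  if (length(x$errors))
    cat("  ", length(x$errors), " file(s) failed to parse\n", sep = "")
  invisible(x)
}

#' Serialize / restore a collection cache
#'
#' The cache is one self-describing JSON text file holding the shared
#' parameters (P-value, discretization levels, background) and, per entry,
#' the name, the weight matrix and the cached thresholds — diffable and
#' human-readable.
#'
#' @param collection A `pwm_collection`.
#' @param file Path of the cache file.
#' @return `write_collection` returns the collection invisibly;
#'   `read_collection` returns the restored `pwm_collection`.
#' @export
write_collection <- function(collection, file) {
  stopifnot(inherits(collection, "pwm_collection"))
  obj <- list(
    format = "pwmjaccard-collection",
    version = 1L,
    pvalue = collection$pvalue,
    d_rough = collection$d_rough,
    d_precise = collection$d_precise,
    background = as.numeric(collection$bg),
    entries = lapply(unname(collection$entries), function(e) list(
      name = e$name,
      weights = e$pwm$weights,
      thresholds = lapply(e$thresholds, function(th)
        list(d = th$d, threshold = th$threshold,
             actual_pvalue = th$actual_pvalue))
    ))
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(collection)
}

#' @rdname write_collection
#' @export
read_collection <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "pwmjaccard-collection"))
    stop("not a collection cache file: ", file)
  bg <- do.call(background, as.list(obj$background))
  entries <- lapply(obj$entries, function(e) {
    list(name = e$name,
         pwm = pwm(matrix(unlist(e$weights), ncol = 4, byrow = FALSE,
                          dimnames = NULL), name = e$name),
         thresholds = lapply(e$thresholds, function(th)
           list(d = as.numeric(th$d), threshold = as.numeric(th$threshold),
                actual_pvalue = as.numeric(th$actual_pvalue))))
  })
  names(entries) <- vapply(entries, `[[`, character(1), "name")
  entries <- entries[order(names(entries))]
  structure(list(entries = entries, pvalue = obj$pvalue,
                 d_rough = obj$d_rough, d_precise = obj$d_precise,
                 bg = bg, errors = character(0)),
            class = "pwm_collection")
}

#' Two-pass similarity scan of a collection
#'
#' Finds collection entries similar to a query model. Pass one computes J2
#' against every entry at the cheap rough discretization; entries whose
#' rough J2 reaches `cutoff - margin` advance to pass two, which recomputes
#' J2 at the precise level. Hits with precise J2 >= `cutoff` are returned
#' ranked by similarity (descending), name (ascending) on ties.
#'
#' The rough pass is a heuristic filter: coarse discretization shifts J2
#' slightly, and `margin` is the allowance for that drift. With
#' `cutoff = 0, margin = 0` the scan degenerates to the exhaustive precise
#' computation against every entry.
#'
#' @param query A [pwm].
#' @param collection A `pwm_collection` (see [build_collection()]).
#' @param cutoff Minimum precise J2 for a reported hit, in `[0, 1]`.
#' @param margin Rough-pass allowance subtracted from `cutoff`.
#' @param pvalue Query P-value; defaults to the collection's shared P-value.
#' @return A data frame of class `pwm_scan_hits` with columns `name`,
#'   `jaccard`, `distance`, `shift`, `orientation`.
#' @export
scan_collection <- function(query, collection, cutoff = 0.05, margin = 0.05,
                            pvalue = NULL) {
  stopifnot(inherits(query, "pwm"), inherits(collection, "pwm_collection"))
  if (cutoff < 0 || cutoff > 1) stop("cutoff must be in [0, 1]")
  if (margin < 0) stop("margin must be non-negative")
  if (is.null(pvalue)) pvalue <- collection$pvalue
  bg <- collection$bg

  pass <- function(d, level_idx, names) {
    qd <- discretize(query, d)
    qt <- scan_threshold(qd, pvalue, bg)
    out <- lapply(names, function(nm) {
      e <- collection$entries[[nm]]
      lev <- e$thresholds[[level_idx]]
      ed <- discretize(e$pwm, d)
      jaccard_best(qd, ed, bg = bg,
                   ithresholds = c(qt$threshold, lev$threshold))
    })
    names(out) <- names
    out
  }

  all_names <- names(collection$entries)
  hits <- data.frame(name = character(0), jaccard = numeric(0),
                     distance = numeric(0), shift = integer(0),
                     orientation = character(0), stringsAsFactors = FALSE)
  if (length(all_names)) {
    rough <- pass(collection$d_rough, 1L, all_names)
    keep <- all_names[vapply(rough, `[[`, numeric(1), "jaccard") >=
                        cutoff - margin]
    if (length(keep)) {
      precise <- pass(collection$d_precise, 2L, keep)
      j2 <- vapply(precise, `[[`, numeric(1), "jaccard")
      sel <- keep[j2 >= cutoff]
      if (length(sel)) {
        hits <- data.frame(
          name = sel,
          jaccard = vapply(precise[sel], `[[`, numeric(1), "jaccard"),
          distance = vapply(precise[sel], `[[`, numeric(1), "distance"),
          shift = vapply(precise[sel], `[[`, numeric(1), "shift"),
          orientation = vapply(precise[sel], `[[`, character(1),
                               "orientation"),
          stringsAsFactors = FALSE, row.names = NULL)
        hits <- hits[order(-hits$jaccard, hits$name), , drop = FALSE]
        rownames(hits) <- NULL
      }
    }
  }
  class(hits) <- c("pwm_scan_hits", "data.frame")
  hits
}

#' All-vs-all similarity and distance matrices for a collection
#'
#' Computes J2 for every pair of collection entries at the shared P-value,
#' returning the symmetric similarity matrix (diagonal 1) and the matching
#' distance matrix `D2 = 1 - J2`.
#'
#' @param collection A `pwm_collection` with at least 2 entries.
#' @param d Discretization level; defaults to the collection's precise level.
#' @return A list with matrices `jaccard` and `distance`, both named by
#'   entry.
#' @export
pairwise_matrix <- function(collection, d = NULL) {
  stopifnot(inherits(collection, "pwm_collection"))
  n <- length(collection$entries)
  if (n < 2) stop("pairwise matrix needs at least 2 entries")
  if (is.null(d)) d <- collection$d_precise
  level_idx <- match(d, c(collection$d_rough, collection$d_precise))
  nms <- names(collection$entries)
  dp <- lapply(collection$entries, function(e) discretize(e$pwm, d))
  th <- vapply(collection$entries, function(e) {
    if (!is.na(level_idx)) e$thresholds[[level_idx]]$threshold
    else scan_threshold(discretize(e$pwm, d), collection$pvalue,
                        collection$bg)$threshold
  }, numeric(1))
  J <- diag(1, n)
  dimnames(J) <- list(nms, nms)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- jaccard_best(dp[[i]], dp[[j]], bg = collection$bg,
                        ithresholds = c(th[i], th[j]))
      J[i, j] <- J[j, i] <- r$jaccard
    }
  }
  list(jaccard = J, distance = 1 - J)
}

#' UPGMA tree of a motif distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering of the D2 matrix,
#' returned as an ultrametric rooted tree: every root-to-leaf path has the
#' same length, and two leaves merged at distance h sit at height h/2.
#'
#' @param dist_matrix Symmetric distance matrix with zero diagonal and leaf
#'   names as dimnames (e.g. `pairwise_matrix(...)$distance`).
#' @return An object of class `upgma_tree` with elements `phylo` (an
#'   [ape::phylo] tree), `hclust` (the merge structure) and `newick` (the
#'   serialized tree text).
#' @export
upgma_tree <- function(dist_matrix) {
  dist_matrix <- as.matrix(dist_matrix)
  if (nrow(dist_matrix) != ncol(dist_matrix) ||
      max(abs(dist_matrix - t(dist_matrix))) > 1e-9)
    stop("distance matrix must be symmetric")
  if (any(abs(diag(dist_matrix)) > 1e-12))
    stop("distance matrix must have a zero diagonal")
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "average")
  phy <- ape::as.phylo(hc)   # halves merge heights: UPGMA branch lengths
  structure(list(phylo = phy, hclust = hc,
                 newick = ape::write.tree(phy)),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat("UPGMA tree with ", length(x$hclust$labels), " leaves\n", sep = "")
  cat(x$newick, "\n")
  invisible(x)
}

#' Cut a UPGMA tree into motif clusters
#'
#' Traverses the tree from the root: a subtree becomes a cluster as soon as
#' the maximum pairwise distance among its leaves — measured on the true
#' distance matrix, not on cophenetic tree heights — does not exceed
#' `max_pairwise_distance`. The default 0.95 corresponds to requiring that
#' the two most dissimilar motifs in a cluster still share at least 5% of
#' their recognized words.
#'
#' @param dist_matrix The distance matrix the tree was built from.
#' @param tree A `upgma_tree` (rebuilt from `dist_matrix` when omitted).
#' @param max_pairwise_distance Cluster admission threshold.
#' @return A list of character vectors partitioning the leaf names; clusters
#'   and members are name-sorted, so the partition does not depend on input
#'   order.
#' @export
cut_clusters <- function(dist_matrix, tree = NULL,
                         max_pairwise_distance = 0.95) {
  dist_matrix <- as.matrix(dist_matrix)
  if (is.null(tree)) tree <- upgma_tree(dist_matrix)
  stopifnot(inherits(tree, "upgma_tree"))
  hc <- tree$hclust
  labels <- hc$labels
  n <- length(labels)
  if (n == 1) return(list(labels))

  leaves_of <- function(node) {
    # node: row of hc$merge (positive) or -leaf index
    if (node < 0) return(-node)
    c(leaves_of(hc$merge[node, 1]), leaves_of(hc$merge[node, 2]))
  }
  clusters <- list()
  descend <- function(node) {
    idx <- leaves_of(node)
    if (length(idx) == 1 ||
        max(dist_matrix[labels[idx], labels[idx]]) <= max_pairwise_distance) {
      clusters[[length(clusters) + 1]] <<- sort(labels[idx])
    } else {
      descend(hc$merge[node, 1])
      descend(hc$merge[node, 2])
    }
  }
  descend(n - 1L)
  clusters[order(vapply(clusters, `[`, character(1), 1))]
}
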