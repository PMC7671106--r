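#' Read a prey-item x functional-trait matrix
#'
#' Reads a delimited file whose first column holds prey-item names and whose
#' remaining columns are binary (0/1) functional traits, e.g. presence of a
#' chitinous exoskeleton, ability to swim, defensive spines.
#'
#' @param path Path to a CSV/TSV file. The delimiter is sniffed from the
#'   header line (comma or tab).
#' @return A validated integer matrix with prey items as row names and traits
#'   as column names.
#' @seealso [prey_cluster()], [dietmorph_example()]
#' @export
read_prey_traits <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  validate_prey_traits(m)
  storage.mode(m) <- "integer"
  m
}

#' Validate a binary prey-trait matrix
#'
#' @param m Numeric matrix, rows = prey items, columns = traits.
#' @return `m`, invisibly, if valid; otherwise an error of class
#'   `dietmorph_validation_error`.
#' @export
validate_prey_traits <- function(m) {
  if (!is.matrix(m)) stop_validation("prey traits must be a matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop_validation("prey-item names must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop_validation("trait names must be present and unique")
  if (anyNA(m)) stop_validation("prey-trait matrix contains missing values")
  bad <- which(!(m == 0 | m == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_validation(sprintf(
      "non-binary prey-trait entry at row '%s', column '%s'",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  invisible(m)
}

stop_validation <- function(msg) {
  stop(structure(class = c("dietmorph_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1L))))
}

#' Euclidean distances between prey items
#'
#' For binary traits the Euclidean distance between two items equals the
#' square root of the number of traits on which they differ, so distances are
#' bounded by `sqrt(ncol(m))`.
#'
#' @param m Binary prey-trait matrix (see [validate_prey_traits()]).
#' @return A [stats::dist] object over the prey items.
#' @export
prey_dist <- function(m) {
  validate_prey_traits(m)
  if (nrow(m) < 2L) stop_validation("need at least 2 prey items")
  stats::dist(m, method = "euclidean")
}

#' Ward clustering of prey items
#'
#' Agglomerative minimum-variance (Ward) clustering of a prey-trait matrix or
#' a precomputed distance matrix. Two common dialects of Ward's method exist,
#' differing in whether pairwise distances are squared before the
#' Lance-Williams update:
#' \describe{
#'   \item{`"sqrt"`}{distances used as-is; heights are on the distance scale
#'     (the `hclust` \code{ward.D2} convention). Default.}
#'   \item{`"squared"`}{distances squared before the recurrence (the classic
#'     \code{ward.D}-on-squared-distances convention); heights are on the
#'     squared-distance scale.}
#' }
#' Items are sorted by name before clustering so the result is invariant to
#' the input row order; merge ties are thereby broken by item name.
#'
#' @param x Binary prey-trait matrix, or a `dist` object.
#' @param dialect `"sqrt"` or `"squared"`.
#' @return An object of class `prey_clust`: a list with elements `hclust`
#'   (the merge tree), `dialect`, `dist` (the unsquared distances) and
#'   `traits` (the trait matrix, if one was supplied).
#' @export
prey_cluster <- function(x, dialect = c("sqrt", "squared")) {
  dialect <- match.arg(dialect)
  traits <- NULL
  if (inherits(x, "dist")) {
    d <- x
  } else {
    validate_prey_traits(x)
    traits <- x[order(rownames(x)), , drop = FALSE]
    d <- prey_dist(traits)
  }
  dm <- as.matrix(d)
  if (!isTRUE(all.equal(dm, t(dm)))) stop_validation("distance matrix is not symmetric")
  ord <- order(rownames(dm))
  d <- stats::as.dist(dm[ord, ord])
  hc <- if (dialect == "sqrt") {
    stats::hclust(d, method = "ward.D2")
  } else {
    stats::hclust(d^2, method = "ward.D")
  }
  structure(list(hclust = hc, dialect = dialect, dist = d, traits = traits),
            class = "prey_clust")
}

#' @export
print.prey_clust <- function(x, ...) {
  cat("Ward clustering of", length(x$hclust$labels), "prey items",
      sprintf("(%s-input dialect)\n", x$dialect))
  invisible(x)
}

#' Convert a prey dendrogram to an ape phylo object
#'
#' Useful for Newick export of the dendrogram with merge heights as branch
#' lengths: `ape::write.tree(as_phylo(pc))`.
#'
#' @param x A `prey_clust` object.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(x) {
  stopifnot(inherits(x, "prey_clust"))
  ape::as.phylo(x$hclust)
}

#' Within-groups sum of squares across candidate cluster counts
#'
#' For each k in `1:k_max`, cuts the dendrogram into k groups and sums the
#' squared Euclidean distances of each item to its group centroid in the
#' original trait space. The curve is non-increasing in k and reaches 0 at
#' k = number of items.
#'
#' @param m Binary prey-trait matrix.
#' @param pc A `prey_clust` object built from `m` (or a compatible item set).
#' @param k_max Largest cluster count to evaluate; defaults to
#'   `min(nrow(m) - 1, 15)`.
#' @return A data frame with columns `k` and `wgss`.
#' @export
wgss_curve <- function(m, pc, k_max = min(nrow(m) - 1L, 15L)) {
  validate_prey_traits(m)
  stopifnot(inherits(pc, "prey_clust"))
  n <- nrow(m)
  if (k_max < 1L || k_max > n) stop_validation("k_max out of range")
  m <- m[pc$hclust$labels, , drop = FALSE]
  w <- vapply(seq_len(k_max), function(k) {
    cl <- stats::cutree(pc$hclust, k = k)
    sum(vapply(split(seq_len(n), cl), function(idx) {
      r <- m[idx, , drop = FALSE]
      sum(sweep(r, 2L, colMeans(r))^2)
    }, numeric(1L)))
  }, numeric(1L))
  data.frame(k = seq_len(k_max), wgss = w)
}

#' Select the number of prey categories from a WGSS curve
#'
#' Implements a reproducible elbow rule: the k whose point on the
#' (k, WGSS) curve lies at maximum perpendicular distance from the chord
#' joining the first and last points. A degenerate (all-zero) curve returns
#' k = 1 with `degenerate = TRUE`; a non-monotone curve triggers a warning
#' but not an error.
#'
#' @param curve Data frame with columns `k` and `wgss`, covering k = 1 upward.
#' @return An object of class `k_selection`: list with `k`, `curve`,
#'   `degenerate`.
#' @export
select_k <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("k", "wgss") %in% names(curve)))
  k <- curve$k; w <- curve$wgss
  if (length(k) < 3L) stop_validation("curve must cover at least k = 1..3")
  if (any(diff(w) > 1e-8 * max(abs(w), 1)))
    warning("WGSS curve is not non-increasing in k")
  if (max(w) <= .Machine$double.eps) {
    return(structure(list(k = 1L, curve = curve, degenerate = TRUE),
                     class = "k_selection"))
  }
  x1 <- k[1L]; y1 <- w[1L]
  x2 <- k[length(k)]; y2 <- w[length(w)]
  num <- abs((y2 - y1) * k - (x2 - x1) * w + x2 * y1 - y2 * x1)
  dd <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  structure(list(k = k[which.max(dd)], curve = curve, degenerate = FALSE),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Selected", x$k, "prey categories",
      if (x$degenerate) "(degenerate curve)" else "", "\n")
  invisible(x)
}

#' Cut a prey dendrogram into named categories
#'
#' Cuts at `k` groups and relabels them canonically: groups are ordered by
#' their lexicographically smallest member, so the labelling is stable under
#' permutation of the input rows.
#'
#' @param pc A `prey_clust` object.
#' @param k Number of categories.
#' @param names Optional character vector of human-readable category names,
#'   length `k`, applied in canonical group order.
#' @return An object of class `category_set`: data frame with columns
#'   `item`, `category_id`, `category_name`, plus attribute `k`.
#' @export
cut_categories <- function(pc, k, names = NULL) {
  stopifnot(inherits(pc, "prey_clust"))
  n <- length(pc$hclust$labels)
  if (k < 1L || k > n) stop_validation("k out of range")
  cl <- stats::cutree(pc$hclust, k = k)
  smallest <- vapply(split(names(cl), cl), min, character(1L))
  canon <- rank(smallest)           # group with smallest member name -> id 1
  id <- unname(canon[as.character(cl)])
  nm <- if (is.null(names)) paste0("category_", seq_len(k)) else {
    stopifnot(length(names) == k)
    names
  }
  out <- data.frame(item = names(cl), category_id = id,
                    category_name = nm[id], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$item), ]
  rownames(out) <- NULL
  structure(out, k = k, class = c("category_set", "data.frame"))
}

#' Path to a packaged example data file
#'
#' @param file One of `"prey_traits.csv"` (29 prey items x 25 binary
#'   functional traits) or `"diet_category_importances.csv"` (54 sculpin
#'   species with habitat, published category labels and per-category diet
#'   importances). Called with no arguments, lists the available files.
#' @return A file path, or a vector of file names.
#' @export
dietmorph_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "dietmorph")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop_validation(paste("no packaged file", file))
  path
}
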