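#' Labelled set of nuclei centroids
#'
#' Constructs a `centroid_set`, the basic point-cloud container of the
#' package: one row per nucleus, with a unique integer label and a 2D or 3D
#' position in arbitrary (but consistent) length units. Downstream results
#' are invariant to uniform scaling, so the units themselves never matter;
#' anisotropic voxel sizes must be applied *before* construction (see
#' [extract_centroids()]).
#'
#' Near-duplicate points are rejected rather than merged: two nuclei closer
#' than `1e-9` times the bounding-box diagonal almost always indicate an
#' upstream segmentation fault, and silently merging them would hide it.
#'
#' @param coords numeric matrix (or data frame) with one row per nucleus and
#'   2 or 3 columns (x, y\[, z\]).
#' @param ids integer labels, one per row; defaults to `seq_len(nrow(coords))`.
#' @return An object of class `centroid_set`: a list with elements `ids`
#'   (integer vector), `coords` (numeric matrix), and `dim` (2 or 3).
#' @examples
#' cs <- centroid_set(rbind(c(0, 0), c(1, 0), c(0, 1)))
#' cs$dim
#' @export
centroid_set <- function(coords, ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (!ncol(coords) %in% c(2L, 3L)) {
    stop("coords must have 2 or 3 columns, got ", ncol(coords))
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("coords contain missing or non-finite values")
  }
  n <- nrow(coords)
  d <- ncol(coords)
  if (is.null(ids)) ids <- seq_len(n)
  ids <- as.integer(ids)
  if (length(ids) != n) stop("length(ids) must equal nrow(coords)")
  if (anyNA(ids)) stop("ids must be integers without NA")
  if (anyDuplicated(ids)) {
    stop("duplicate centroid ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  }
  if (n < 1L) stop("empty centroid set")
  dup <- find_near_duplicates(coords)
  if (!is.null(dup)) {
    stop(
      "centroids ", ids[dup[1]], " and ", ids[dup[2]],
      " coincide (closer than 1e-9 of the bounding-box diagonal); ",
      "duplicate nuclei usually indicate an upstream segmentation error"
    )
  }
  dimnames(coords) <- NULL
  structure(list(ids = ids, coords = coords, dim = d), class = "centroid_set")
}

# Returns indices of the first near-duplicate pair, or NULL. Tolerance is
# relative to the bounding-box diagonal so the check is scale invariant.
find_near_duplicates <- function(coords) {
  diag_len <- sqrt(sum((apply(coords, 2, max) - apply(coords, 2, min))^2))
  tol <- 1e-9 * max(diag_len, .Machine$double.xmin)
  n <- nrow(coords)
  if (n > 1L) {
    dd <- as.matrix(stats::dist(coords))
    dd[upper.tri(dd, diag = TRUE)] <- Inf
    if (any(dd <= tol)) {
      idx <- which(dd <= tol, arr.ind = TRUE)[1L, ]
      return(as.integer(idx))
    }
  }
  NULL
}

#' @export
print.centroid_set <- function(x, ...) {
  cat("Centroid set:", length(x$ids), "nuclei in", paste0(x$dim, "D"), "\n")
  rng <- apply(x$coords, 2, range)
  cat(
    "  extent:",
    paste(sprintf("[%.4g, %.4g]", rng[1, ], rng[2, ]), collapse = " x "),
    "\n"
  )
  invisible(x)
}

#' @export
format.centroid_set <- function(x, ...) {
  sprintf("<centroid_set: %d nuclei, %dD>", length(x$ids), x$dim)
}

# row index of each id, with validation
id_index <- function(cs, ids) {
  idx <- match(as.integer(ids), cs$ids)
  if (anyNA(idx)) {
    stop("unknown centroid id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}
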