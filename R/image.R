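#' Render a synthetic nuclear-marker image of a tissue
#'
#' Draws one isotropic Gaussian blob (peak intensity 1, standard deviation
#' `radius / 2`) per centroid on a pixel/voxel grid covering the tissue
#' box, and adds independent Gaussian read noise. The signal-to-noise
#' ratio is `1 / noise_sd`. Used to exercise the image-to-centroid path
#' ([extract_centroids()]) end to end without external data; it emulates a
#' well-separated nuclear stain (e.g. DAPI), not the full complexity of
#' real microscopy (no background gradients, PSF anisotropy, or intensity
#' variation between nuclei).
#'
#' @param tissue a [generate_tissue()] result.
#' @param voxel_size edge length of a pixel/voxel, in the tissue's length
#'   units (same for every axis).
#' @param radius nominal nucleus radius (length units); must be smaller
#'   than half the lattice spacing.
#' @param noise_sd standard deviation of the additive Gaussian noise,
#'   relative to the unit blob peak.
#' @param seed RNG seed for the noise.
#' @return Numeric array (2D matrix or 3D array) of intensities, with
#'   attributes `voxel_size` and `origin` (physical coordinate of the
#'   0-index voxel, i.e. the lower box corner).
#' @export
render_nuclei_image <- function(tissue, voxel_size = 0.125, radius = 0.3,
                                noise_sd = 0.02, seed = 1) {
  stopifnot(inherits(tissue, "synthetic_tissue"))
  p <- tissue$params
  mean_spacing <- if (p$lattice == "uniform") {
    prod(p$box[2, ] - p$box[1, ])^(1 / p$dim) / p$n^(1 / p$dim)
  } else {
    p$spacing
  }
  if (radius >= mean_spacing / 2) {
    stop("radius must be smaller than half the mean spacing (", mean_spacing / 2, ")")
  }
  P <- tissue$centroids$coords
  dmin <- stats::dist(P)
  if (any(dmin < 2 * radius)) {
    warning("some nuclei overlap (centroid distance < 2 * radius)")
  }
  box <- p$box
  d <- p$dim
  dims <- pmax(ceiling((box[2, ] - box[1, ]) / voxel_size) + 1L, 2L)
  img <- array(0, dim = dims)
  sigma <- radius / 2
  halfw <- ceiling(4 * sigma / voxel_size)
  axes <- lapply(dims, function(k) seq_len(k)) # 1-based voxel indices
  for (c_ in seq_len(nrow(P))) {
    # voxel v (0-based) samples physical position origin + v * voxel_size
    cv <- (P[c_, ] - box[1, ]) / voxel_size # 0-based fractional index
    lo <- pmax(floor(cv) - halfw + 1L, 1L) # 1-based window bounds
    hi <- pmin(floor(cv) + halfw + 1L, dims)
    win <- lapply(seq_len(d), function(k) lo[k]:hi[k])
    # squared distance (in voxels) from the blob center, per axis
    sq <- lapply(seq_len(d), function(k) (win[[k]] - 1 - cv[k])^2)
    d2 <- if (d == 2L) outer(sq[[1]], sq[[2]], "+") else {
      outer(outer(sq[[1]], sq[[2]], "+"), sq[[3]], "+")
    }
    blob <- exp(-d2 * voxel_size^2 / (2 * sigma^2))
    idx <- as.matrix(do.call(expand.grid, win))
    img[idx] <- img[idx] + as.vector(blob)
  }
  img <- img + with_local_seed(
    seed,
    array(stats::rnorm(prod(dims), 0, noise_sd), dim = dims)
  )
  attr(img, "voxel_size") <- voxel_size
  attr(img, "origin") <- box[1, ]
  img
}

#' Extract nuclei centroids from a single-channel image
#'
#' Segments nuclei by global automatic intensity thresholding (Otsu's
#' method on the full image histogram), labels connected foreground
#' components (8-connectivity in 2D, 26-connectivity in 3D), discards
#' components smaller than `min_size` pixels/voxels, and returns the
#' intensity-weighted center of mass of each remaining component.
#' Centroids are reported in physical units: 0-based voxel index times the
#' per-axis `spacing`. Anisotropic voxel sizes must be corrected here — the
#' downstream angle statistic is not invariant under anisotropic scaling.
#'
#' @param image 2D matrix or 3D array of intensities.
#' @param spacing per-axis physical size of a pixel/voxel (recycled to the
#'   image dimensionality; default isotropic 1).
#' @param min_size minimum component size in pixels/voxels.
#' @return A [centroid_set()] (ids in decreasing component size order are
#'   relabelled `1..k`), or a zero-row data frame with columns
#'   `id`, `x`, `y`(, `z`) if no component survives the size filter.
#' @export
extract_centroids <- function(image, spacing = 1, min_size = 5) {
  image <- as.array(image)
  d <- length(dim(image))
  if (!d %in% c(2L, 3L)) stop("image must be a 2D matrix or 3D array")
  spacing <- rep_len(as.numeric(spacing), d)
  if (any(spacing <= 0)) stop("spacing must be positive for every axis")
  rng <- range(image)
  if (rng[1] == rng[2]) stop("empty foreground: image is constant")
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  # global Otsu threshold from the pooled histogram (column layout only
  # reshapes; the histogram is unchanged)
  thr <- EBImage::otsu(EBImage::Image(matrix(as.vector(norm), ncol = 1)))
  mask <- norm > thr
  if (!any(mask)) stop("empty foreground after thresholding")
  labels <- label_components(mask)
  sizes <- tabulate(labels[labels > 0L])
  keep <- which(sizes >= min_size)
  cols <- c("x", "y", "z")[seq_len(d)]
  if (length(keep) == 0L) {
    empty <- as.data.frame(matrix(numeric(), 0, d + 1,
      dimnames = list(NULL, c("id", cols))
    ))
    return(empty)
  }
  vox <- which(labels > 0L & array(labels %in% keep, dim(labels)))
  lab <- labels[vox]
  w <- image[vox] - rng[1]
  pos <- arrayInd(vox, dim(image)) - 1L # 0-based indices
  coords <- matrix(NA_real_, length(keep), d)
  for (ci in seq_along(keep)) {
    sel <- lab == keep[ci]
    ww <- w[sel]
    coords[ci, ] <- colSums(pos[sel, , drop = FALSE] * ww) / sum(ww)
  }
  coords <- sweep(coords, 2, spacing, `*`)
  ord <- order(sizes[keep], decreasing = TRUE)
  centroid_set(coords[ord, , drop = FALSE], ids = seq_along(keep))
}

# Connected-component labelling of a logical mask with full connectivity
# (8 neighbors in 2D, 26 in 3D), breadth-first over the foreground.
label_components <- function(mask) {
  dims <- dim(mask)
  d <- length(dims)
  offs <- as.matrix(do.call(expand.grid, rep(list(-1:1), d)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  labels <- array(0L, dims)
  fg <- which(mask)
  cur <- 0L
  for (s in fg) {
    if (labels[s] != 0L) next
    cur <- cur + 1L
    labels[s] <- cur
    frontier <- s
    while (length(frontier)) {
      pos <- arrayInd(frontier, dims)
      nb <- integer(0)
      for (o in seq_len(nrow(offs))) {
        q <- pos + matrix(offs[o, ], nrow(pos), d, byrow = TRUE)
        ok <- rowSums(q >= 1L) == d & rowSums(q <= matrix(dims, nrow(q), d, byrow = TRUE)) == d
        if (!any(ok)) next
        qq <- q[ok, , drop = FALSE]
        lin <- qq[, 1]
        mult <- 1L
        for (k in 2:d) {
          mult <- mult * dims[k - 1]
          lin <- lin + (qq[, k] - 1L) * mult
        }
        nb <- c(nb, lin[mask[lin] & labels[lin] == 0L])
      }
      nb <- unique(nb)
      labels[nb] <- cur
      frontier <- nb
    }
  }
  labels
}

#' Read a single-channel TIFF image (2D or 3D stack)
#'
#' @param path path to a TIFF file; multi-frame files are read as a 3D
#'   array with the frame index as the third axis.
#' @return Numeric matrix or 3D array of intensities.
#' @export
read_nuclei_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  frames <- lapply(frames, function(f) {
    if (length(dim(f)) == 3L) f[, , 1] else f # collapse accidental channels
  })
  if (length(frames) == 1L) {
    return(frames[[1]])
  }
  array(unlist(frames), dim = c(dim(frames[[1]]), length(frames)))
}

#' Write an intensity array as a TIFF image (2D or 3D stack)
#'
#' Intensities are clipped to `[0, 1]` as required by the TIFF writer.
#'
#' @param image numeric matrix or 3D array.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_nuclei_tiff <- function(image, path) {
  img <- pmin(pmax(image, 0), 1)
  if (length(dim(img)) == 3L) {
    frames <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
    tiff::writeTIFF(frames, path)
  } else {
    tiff::writeTIFF(img, path)
  }
  invisible(path)
}
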