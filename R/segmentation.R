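#' Foreground mask of the nuclear-stain channel
#'
#' Builds a binary nuclear-foreground mask by Gaussian smoothing, contrast
#' limited adaptive histogram equalization (CLAHE), and Otsu thresholding of
#' the processed image. Images are plain numeric matrices indexed
#' `[row, col]`; intensities are normalized to their maximum before
#' processing, so the mask is invariant to linear rescaling of the input.
#'
#' CLAHE is applied on a grid of `clahe_tile`-pixel tiles; for images
#' smaller than two tiles in either direction the equalization step is a
#' no-op (there is no local contrast to equalize over).
#'
#' @param stain_image Numeric matrix of non-negative, finite intensities.
#' @param smoothing_sigma Gaussian smoothing bandwidth in pixels.
#' @param clahe_clip Contrast clip limit as a fraction of the histogram
#'   (scaled onto the equalizer's 256 bins).
#' @param clahe_tile Equalization tile size in pixels.
#' @return Logical matrix, `TRUE` on nuclear foreground.
#' @export
build_foreground_mask <- function(stain_image, smoothing_sigma = 2,
                                  clahe_clip = 0.01, clahe_tile = 64) {
  img <- as.matrix(stain_image)
  if (any(!is.finite(img))) {
    qm_stop("image contains non-finite values", "qmosaic_image_error")
  }
  if (any(img < 0)) {
    qm_stop("image contains negative intensities", "qmosaic_image_error")
  }
  rng <- range(img)
  if (rng[1] == rng[2]) {
    qm_stop("constant image: no foreground distinguishable",
            "qmosaic_degenerate_threshold_error")
  }
  x <- EBImage::Image(t(img) / rng[2])
  if (smoothing_sigma > 0) {
    x <- EBImage::gblur(x, sigma = smoothing_sigma)
  }
  nx <- floor(dim(x)[1] / clahe_tile)
  ny <- floor(dim(x)[2] / clahe_tile)
  if (nx >= 2 && ny >= 2) {
    x <- EBImage::clahe(x, nx = nx, ny = ny,
                        limit = max(1, clahe_clip * 256))
  }
  x[x < 0] <- 0
  x[x > 1] <- 1
  thr <- EBImage::otsu(x)
  mask <- t(EBImage::imageData(x) >= thr)
  storage.mode(mask) <- "logical"
  mask
}

#' Watershed segmentation of nuclei
#'
#' Segments nuclei by applying a Euclidean distance transform to the
#' foreground mask and running watershed with the distance-transform local
#' maxima as seeds (basins of the negated distance transform, restricted to
#' the mask). Segments smaller than `min_area` pixels are discarded and the
#' remaining labels renumbered consecutively from 1; background is 0.
#' Segments touching the image border are kept (exclusion is a curation
#' decision, not a segmentation one).
#'
#' @inheritParams build_foreground_mask
#' @param min_separation Minimum seed separation in pixels (neighborhood
#'   radius used when splitting touching nuclei).
#' @param min_area Minimum segment area in pixels; smaller speckle is
#'   dropped.
#' @return Integer label matrix, same shape as the image.
#' @export
segment_nuclei <- function(stain_image, smoothing_sigma = 2,
                           clahe_clip = 0.01, clahe_tile = 64,
                           min_separation = 5, min_area = 10) {
  mask <- build_foreground_mask(stain_image, smoothing_sigma,
                                clahe_clip, clahe_tile)
  d <- EBImage::distmap(EBImage::Image(t(mask) * 1))
  labels <- EBImage::watershed(d, tolerance = 1, ext = min_separation)
  lab <- t(EBImage::imageData(labels))
  storage.mode(lab) <- "integer"
  relabel_consecutive(lab, min_area = min_area)
}

# Drop segments below min_area and renumber positive labels 1..n in order
# of first appearance of the original label values.
relabel_consecutive <- function(lab, min_area = 0) {
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts >= min_area)
  map <- integer(length(counts))
  map[keep] <- seq_along(keep)
  out <- lab
  pos <- lab > 0
  out[pos] <- map[lab[pos]]
  out
}

#' Per-nucleus mean fluorescence measurements
#'
#' Averages pixel intensities of every channel within each labeled segment
#' and records the segment's pixel centroid. Coordinates are 0-based with
#' x = column and y = row. The result does not depend on the numbering of
#' the labels (only on the pixel partition they induce).
#'
#' @param labels Integer label matrix (0 = background).
#' @param channels List of numeric matrices, one per channel, each the same
#'   shape as `labels`. Channel columns are named `ch0`, `ch1`, ... in list
#'   order (or by the list's names).
#' @return A [measurement_table()] with one row per positive label.
#' @export
measure_segments <- function(labels, channels) {
  labels <- as.matrix(labels)
  if (!is.list(channels)) channels <- list(channels)
  for (ch in channels) {
    if (!all(dim(ch) == dim(labels))) {
      qm_stop("channel shape does not match label matrix",
              "qmosaic_dimension_error")
    }
  }
  ch_names <- names(channels)
  if (is.null(ch_names) || any(ch_names == "")) {
    ch_names <- paste0("ch", seq_along(channels) - 1)
  }
  pos <- which(labels > 0)
  if (length(pos) == 0) {
    empty <- data.frame(cell_id = integer(), x = numeric(), y = numeric())
    for (nm in ch_names) empty[[nm]] <- numeric()
    return(measurement_table(empty))
  }
  lab <- labels[pos]
  ids <- sort(unique(lab))
  grp <- factor(lab, levels = ids)
  row0 <- (pos - 1) %% nrow(labels)       # 0-based row = y
  col0 <- (pos - 1) %/% nrow(labels)      # 0-based col = x
  out <- data.frame(
    cell_id = ids,
    x = as.numeric(tapply(col0, grp, mean)),
    y = as.numeric(tapply(row0, grp, mean))
  )
  for (k in seq_along(channels)) {
    vals <- channels[[k]][pos]
    out[[ch_names[k]]] <- as.numeric(tapply(vals, grp, mean))
  }
  measurement_table(out)
}
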