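#' Extract background pixels for bleedthrough characterization
#'
#' Morphologically dilates the nuclear foreground until no features remain
#' (operationally: until the per-iteration foreground growth falls below 1%
#' or 20 iterations have run), then collects the intensities of all pixels
#' outside the dilated foreground. These background pixels carry the
#' cross-channel contamination signal but no nuclear expression signal, so
#' they support unbiased estimation of bleedthrough strengths.
#'
#' @param channels List of numeric channel matrices (named `ch0`, ... or
#'   unnamed, in channel order).
#' @param foreground_mask Logical matrix from [build_foreground_mask()].
#' @param min_background_fraction Error if fewer than this fraction of
#'   pixels remain after dilation.
#' @return A `background_sample`: data.frame of per-channel pixel
#'   intensities with the pixel indices as attribute `pixels`.
#' @export
extract_background <- function(channels, foreground_mask,
                               min_background_fraction = 0.05) {
  if (!is.list(channels)) channels <- list(channels)
  ch_names <- names(channels)
  if (is.null(ch_names) || any(ch_names == "")) {
    ch_names <- paste0("ch", seq_along(channels) - 1)
  }
  mask <- as.matrix(foreground_mask)
  brush <- EBImage::makeBrush(3, shape = "disc")
  cur <- EBImage::Image(t(mask) * 1)
  frac <- mean(mask)
  for (it in seq_len(20)) {
    if (frac == 0) break
    nxt <- EBImage::dilate(cur, brush)
    new_frac <- mean(EBImage::imageData(nxt) > 0)
    grew <- new_frac - frac
    cur <- nxt
    frac <- new_frac
    if (grew < 0.01) break
  }
  bg <- !(t(EBImage::imageData(cur)) > 0)
  if (mean(bg) < min_background_fraction) {
    qm_stop(sprintf("background covers %.1f%% of image (< %.0f%%)",
                    100 * mean(bg), 100 * min_background_fraction),
            "qmosaic_insufficient_background_error")
  }
  idx <- which(bg)
  out <- as.data.frame(lapply(channels, function(ch) as.matrix(ch)[idx]))
  names(out) <- ch_names
  attr(out, "pixels") <- idx
  class(out) <- c("background_sample", class(out))
  out
}

#' Resample background pixels to a uniform source-intensity distribution
#'
#' Background pixel intensities are heavily skewed toward darkness, which
#' would let the dim pixels dominate the regression. Resampling draws pixels
#' with replacement such that every occupied equal-width intensity bin of
#' the source channel contributes the same expected count, flattening the
#' source distribution.
#'
#' @param sample A `background_sample` from [extract_background()].
#' @param source_channel Name of the channel whose intensities are
#'   flattened (the bleedthrough source).
#' @param n_bins Number of equal-width bins over the source intensity range.
#' @param n_out Number of pixels to draw (default: `min(100000, n)`).
#' @param seed Optional RNG seed.
#' @return A resampled `background_sample`.
#' @export
resample_uniform <- function(sample, source_channel, n_bins = 10,
                             n_out = NULL, seed = NULL) {
  if (nrow(sample) == 0) {
    qm_stop("empty background sample", "qmosaic_degenerate_distribution_error")
  }
  v <- sample[[source_channel]]
  rng <- range(v)
  if (rng[1] == rng[2]) {
    qm_stop("all background pixels share one source intensity",
            "qmosaic_degenerate_distribution_error")
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- findInterval(v, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  occupied <- sort(unique(bin))
  if (length(occupied) < 2) {
    qm_stop("all background pixels fall in one intensity bin",
            "qmosaic_degenerate_distribution_error")
  }
  n_out <- n_out %||% min(100000L, nrow(sample))
  idx_by_bin <- split(seq_along(v), bin)
  picks <- with_seed(seed, {
    which_bin <- sample(length(occupied), n_out, replace = TRUE)
    vapply(which_bin, function(b) {
      pool <- idx_by_bin[[b]]
      pool[sample.int(length(pool), 1L)]
    }, integer(1))
  })
  out <- sample[picks, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("background_sample", class(as.data.frame(out)))
  out
}

#' Fit a bleedthrough model on background pixels
#'
#' Models the target-channel background intensity as a linear superposition
#' of the other channels' intensities plus an intercept,
#' `B = sum_k alpha_k F_k + beta`, estimated by a gamma-family,
#' identity-link generalized linear model on the (resampled) background
#' pixels. The gamma fit runs by iteratively reweighted least squares with
#' fitted means floored at a small positive value; if it fails to converge
#' an ordinary least-squares fit is used instead, with a warning.
#'
#' @param sample A (typically resampled) `background_sample`.
#' @param target_channel Channel receiving the bleedthrough.
#' @param source_channels Channels contributing it (default: all others).
#' @return A `bleedthrough_model` with fields `target_channel`,
#'   `source_channels`, `alpha` (named coefficients) and `beta`.
#' @export
fit_bleedthrough <- function(sample, target_channel,
                             source_channels = NULL) {
  source_channels <- source_channels %||%
    setdiff(names(sample), target_channel)
  if (target_channel %in% source_channels) {
    qm_stop("target channel cannot be its own source",
            "qmosaic_schema_error")
  }
  df <- as.data.frame(sample)[, c(target_channel, source_channels)]
  # gamma family needs a strictly positive response; floor at a tiny
  # positive value relative to the data scale
  floor_val <- max(1e-8, 1e-6 * max(df[[target_channel]]))
  df[[target_channel]] <- pmax(df[[target_channel]], floor_val)
  fml <- stats::reformulate(source_channels, response = target_channel)
  start <- coef(lm(fml, data = df))
  fit <- tryCatch({
    g <- suppressWarnings(glm(fml, data = df,
                              family = Gamma(link = "identity"),
                              start = start,
                              control = list(maxit = 100)))
    if (!g$converged) stop("IRLS did not converge")
    g
  }, error = function(e) {
    warning(sprintf("gamma GLM failed (%s); falling back to least squares",
                    conditionMessage(e)), call. = FALSE)
    lm(fml, data = df)
  })
  cf <- coef(fit)
  cf[is.na(cf)] <- 0                     # constant source: no contribution
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  sm <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (!is.null(sm)) se[rownames(sm)] <- sm[, "Std. Error"]
  structure(list(target_channel = target_channel,
                 source_channels = source_channels,
                 alpha = cf[source_channels],
                 alpha_se = se[source_channels],
                 beta = unname(cf["(Intercept)"]),
                 beta_se = unname(se["(Intercept)"]),
                 method = if (inherits(fit, "glm")) "gamma-glm" else "ols"),
            class = "bleedthrough_model")
}

#' Predicted per-nucleus background intensity under a bleedthrough model
#'
#' @param model A `bleedthrough_model`.
#' @param table A measurement table (or data.frame) with the source
#'   channels' raw columns.
#' @return Numeric vector of estimated background intensities.
#' @export
predict_background <- function(model, table) {
  missing <- setdiff(model$source_channels, names(table))
  if (length(missing) > 0) {
    qm_stop(sprintf("missing source channel(s): %s",
                    paste(missing, collapse = ", ")),
            "qmosaic_schema_error")
  }
  b <- rep(model$beta, nrow(table))
  for (ch in model$source_channels) {
    b <- b + model$alpha[[ch]] * table[[ch]]
  }
  b
}

#' Subtract estimated bleedthrough from per-nucleus measurements
#'
#' Writes `corrected_level = raw_level - (sum_k alpha_k raw_k + beta)` for
#' the model's target channel into the column `<target>_corrected`. The
#' subtraction can undershoot zero; negative corrected values are retained
#' (silent clipping would bias downstream comparisons — the annotation
#' stage applies its own positivity floor before taking logs).
#'
#' @param table A [measurement_table()] with raw columns for the target and
#'   all source channels.
#' @param model A `bleedthrough_model`.
#' @return The table with the corrected column added (other channels are
#'   untouched).
#' @export
correct_measurements <- function(table, model) {
  table <- measurement_table(table)
  tgt <- model$target_channel
  if (!tgt %in% names(table)) {
    qm_stop(sprintf("missing target channel: %s", tgt),
            "qmosaic_schema_error")
  }
  table[[corrected_name(tgt)]] <- table[[tgt]] - predict_background(model, table)
  measurement_table(table)
}

#' @export
print.bleedthrough_model <- function(x, ...) {
  cat("Bleedthrough model for", x$target_channel,
      sprintf("(%s)\n", x$method))
  for (ch in x$source_channels) {
    cat(sprintf("  alpha[%s] = %.5f\n", ch, x$alpha[[ch]]))
  }
  cat(sprintf("  beta = %.5f\n", x$beta))
  invisible(x)
}
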