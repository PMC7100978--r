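#' Simulate clonal growth of a synthetic cell culture
#'
#' Grows a two-dimensional culture from a single heterozygous (dosage-1)
#' seed cell by synchronous stochastic rounds: each cell divides with
#' probability `division_prob` per round; while the recombination window is
#' open, each dividing dosage-1 parent undergoes mitotic recombination with
#' probability `recombination_prob`, partitioning its two marker copies
#' unequally so the daughters receive dosages (2, 0) instead of (1, 1).
#' Dosage-0 and dosage-2 parents are ineligible, sealing their lineages.
#' The window opens at the first round where the population reaches
#' `recombination_start_size` and stays open for `recombination_duration`
#' rounds (generations); earlier onsets produce larger clones. After every
#' round all cells are repositioned by spring relaxation
#' ([reposition()]) to preserve approximately uniform density while keeping
#' clonal siblings adjacent. Growth stops once the population exceeds
#' `final_size`.
#'
#' Every division conserves dosage (daughters sum to twice the parent) and
#' all randomness flows from `seed`, so identical seeds reproduce the
#' culture bit for bit.
#'
#' @param final_size Stop once the population exceeds this count.
#' @param division_prob Per-cell division probability per round.
#' @param recombination_prob Recombination probability per eligible
#'   division while the window is open.
#' @param recombination_start_size Minimum population at which
#'   recombination may begin.
#' @param recombination_duration Number of rounds the window stays open.
#' @param seed RNG seed.
#' @param relax_iters Spring-relaxation iterations per round.
#' @return A `synthetic_culture`: list with `cells` (data.frame: id,
#'   parent_id, dosage, clone_id, birth_generation, x, y), `divisions`
#'   (per-division bookkeeping), `params` and `n_generations`.
#' @export
grow_culture <- function(final_size = 2048, division_prob = 0.2,
                         recombination_prob = 0.2,
                         recombination_start_size = 32,
                         recombination_duration = 4,
                         seed = 1, relax_iters = 50) {
  if (division_prob <= 0 || division_prob > 1 ||
      recombination_prob < 0 || recombination_prob > 1) {
    qm_stop("probabilities must lie in (0, 1]", "qmosaic_parameter_error")
  }
  if (final_size < 2) {
    qm_stop("final_size must be at least 2", "qmosaic_parameter_error")
  }
  with_seed(seed, {
    cells <- data.frame(id = 1L, parent_id = NA_integer_, dosage = 1L,
                        clone_id = 0L, birth_generation = 0L,
                        x = 0, y = 0)
    next_id <- 2L
    next_clone <- 1L
    onset <- NA_integer_
    gen <- 0L
    div_log <- list()
    repeat {
      gen <- gen + 1L
      n <- nrow(cells)
      if (is.na(onset) && n >= recombination_start_size) onset <- gen
      window_open <- !is.na(onset) && gen < onset + recombination_duration
      dividing <- which(runif(n) < division_prob)
      if (length(dividing) > 0) {
        new_rows <- vector("list", length(dividing))
        for (w in seq_along(dividing)) {
          i <- dividing[w]
          d <- cells$dosage[i]
          recombines <- window_open && d == 1L &&
            runif(1) < recombination_prob
          if (recombines) {
            d1 <- 2L; d2 <- 0L
            c1 <- next_clone; c2 <- next_clone + 1L
            next_clone <- next_clone + 2L
          } else {
            d1 <- d; d2 <- d
            c1 <- cells$clone_id[i]; c2 <- cells$clone_id[i]
          }
          theta <- runif(1, 0, 2 * pi)
          div_log[[length(div_log) + 1L]] <-
            c(gen, cells$id[i], d, d1, d2)
          cells$dosage[i] <- d1
          cells$clone_id[i] <- c1
          new_rows[[w]] <- data.frame(
            id = next_id, parent_id = cells$id[i], dosage = d2,
            clone_id = c2, birth_generation = gen,
            x = cells$x[i] + 0.5 * cos(theta),
            y = cells$y[i] + 0.5 * sin(theta))
          next_id <- next_id + 1L
        }
        cells <- rbind(cells, do.call(rbind, new_rows))
      }
      if (nrow(cells) >= 3) {
        # fixed unit temperature scale: deriving it from the current median
        # edge would track any transient compression from newborn cells
        pos <- reposition(cbind(cells$x, cells$y), cells$dosage,
                          n_iter = relax_iters, rest_length = 1)
        cells$x <- pos[, 1]; cells$y <- pos[, 2]
      }
      if (nrow(cells) > final_size) break
    }
    div <- do.call(rbind, div_log)
    colnames(div) <- c("generation", "parent_id", "parent_dosage",
                       "daughter1_dosage", "daughter2_dosage")
    structure(list(cells = cells,
                   divisions = as.data.frame(div),
                   params = list(final_size = final_size,
                                 division_prob = division_prob,
                                 recombination_prob = recombination_prob,
                                 recombination_start_size = recombination_start_size,
                                 recombination_duration = recombination_duration,
                                 seed = seed),
                   n_generations = gen,
                   recombination_onset = onset),
              class = "synthetic_culture")
  })
}

#' Force-directed repositioning of a cell culture
#'
#' Connects cells by Delaunay triangulation, removes sliver edges on the
#' culture periphery (any triangle whose largest interior angle exceeds
#' `max_angle` degrees loses its longest edge), assigns edges between
#' same-dosage cells a 10% stiffer spring constant so clonal siblings stay
#' together, and equilibrates the network with a fixed budget of
#' force-directed (Fruchterman-Reingold) iterations seeded from the
#' current coordinates. Neighbor attraction plus node repulsion generates
#' the outward pressure that keeps the packing at approximately uniform
#' density as the population grows; springs alone cannot, because opposing
#' neighbor forces cancel in the bulk. The relaxed layout is recentered on
#' the input centroid; its scale is the layout's natural equilibrium
#' spacing (pinning a different scale between growth rounds fights that
#' equilibrium and degrades density uniformity).
#'
#' Two cells have a closed-form equilibrium: they are placed `rest_length`
#' apart on their common axis.
#'
#' @param positions Two-column coordinate matrix (>= 2 cells).
#' @param dosages Integer dosage per cell (drives the stiffness bias).
#' @param n_iter Relaxation iterations.
#' @param stiffness_bias Attraction multiplier for same-dosage edges.
#' @param max_angle Sliver-triangle threshold in degrees.
#' @param rest_length Two-cell equilibrium separation and temperature
#'   scale; default: the median Delaunay edge length of the input.
#' @return Updated coordinate matrix.
#' @export
reposition <- function(positions, dosages, n_iter = 50,
                       stiffness_bias = 1.1, max_angle = 150,
                       rest_length = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) qm_stop("need at least 2 cells", "qmosaic_parameter_error")
  if (n == 2) {
    rest <- rest_length %||% 1
    ctr <- colMeans(positions)
    v <- positions[2, ] - positions[1, ]
    nv <- sqrt(sum(v^2))
    u <- if (nv == 0) c(1, 0) else v / nv
    return(rbind(ctr - u * rest / 2, ctr + u * rest / 2))
  }
  # duplicate coordinates break the triangulation: jitter deterministically
  if (anyDuplicated(positions)) {
    dup <- duplicated(positions)
    positions[dup, ] <- positions[dup, ] +
      1e-3 * cbind(sin(seq_len(sum(dup))), cos(seq_len(sum(dup))))
  }
  edges <- .filtered_delaunay(positions, max_angle)
  rest <- rest_length %||% median(edges$length)
  w <- ifelse(dosages[edges$i] == dosages[edges$j], stiffness_bias, 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i, to = edges$j), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  new_pos <- igraph::layout_with_fr(g, coords = positions, niter = n_iter,
                                    weights = w, start.temp = 0.5 * rest,
                                    grid = "nogrid")
  ctr_old <- colMeans(positions)
  ctr_new <- colMeans(new_pos)
  new_pos[, 1] <- new_pos[, 1] - ctr_new[1] + ctr_old[1]
  new_pos[, 2] <- new_pos[, 2] - ctr_new[2] + ctr_old[2]
  new_pos
}

# Delaunay edges with sliver triangles (max interior angle > max_angle
# degrees) stripped of their longest edge; these occur along the hull and
# would otherwise connect distant peripheral cells.
.filtered_delaunay <- function(positions, max_angle = 150) {
  dd <- tryCatch(
    suppressWarnings(deldir::deldir(positions[, 1], positions[, 2])),
    error = function(e) {
      qm_stop("triangulation failed", "qmosaic_triangulation_error")
    })
  edges <- delaunay_edges(positions)
  tris <- deldir::triang.list(dd)
  drop <- character(0)
  cos_lim <- cos(max_angle * pi / 180)
  for (tr in tris) {
    p <- as.matrix(tr[, c("x", "y")])
    idx <- tr$ptNum
    side <- function(a, b) sqrt(sum((p[a, ] - p[b, ])^2))
    L <- c(side(2, 3), side(1, 3), side(1, 2))  # opposite vertex 1, 2, 3
    # law of cosines: angle at vertex v is opposite side L[v]
    cosv <- c((L[2]^2 + L[3]^2 - L[1]^2) / (2 * L[2] * L[3]),
              (L[1]^2 + L[3]^2 - L[2]^2) / (2 * L[1] * L[3]),
              (L[1]^2 + L[2]^2 - L[3]^2) / (2 * L[1] * L[2]))
    if (any(cosv < cos_lim)) {
      v <- which.min(cosv)
      pair <- sort(idx[-v])
      drop <- c(drop, paste(pair[1], pair[2]))
    }
  }
  if (length(drop) > 0) {
    key <- paste(edges$i, edges$j)
    edges <- edges[!key %in% drop, , drop = FALSE]
  }
  edges
}

#' Sample dosage-conditioned fluorescence levels
#'
#' Marker levels are lognormal conditioned on gene dosage:
#' `ln x ~ Normal(mu_n, sigma_alpha^2)` with `mu_n = ln(2^(n-1))`, so the
#' mean (and median) fluorescence doubles with each additional gene copy
#' (medians 0.5, 1, 2 for dosages 0, 1, 2). `sigma_alpha`, the fluorescence
#' ambiguity, controls how much adjacent dosage distributions overlap.
#'
#' @param dosages Integer vector of gene dosages in \{0, 1, 2\}.
#' @param sigma_alpha Log-scale standard deviation (> 0).
#' @param seed Optional RNG seed.
#' @return Numeric vector of fluorescence levels.
#' @export
sample_fluorescence <- function(dosages, sigma_alpha, seed = NULL) {
  if (sigma_alpha <= 0) {
    qm_stop("sigma_alpha must be positive", "qmosaic_parameter_error")
  }
  mu <- (dosages - 1) * log(2)
  with_seed(seed, exp(rnorm(length(dosages), mu, sigma_alpha)))
}

#' Synthetic measurement table from a simulated culture
#'
#' Samples clonal-marker fluorescence for every cell of a grown culture and
#' assembles a measurement table with the ground-truth dosage carried in a
#' `dosage_true` column. Optionally co-samples a dosage-independent control
#' reporter whose observed level receives an injected linear bleedthrough
#' contribution `bleed_alpha * marker + bleed_beta`, emulating a
#' single-reporter control experiment for the correction stage.
#'
#' @param culture A `synthetic_culture`.
#' @param sigma_alpha Fluorescence ambiguity of the marker.
#' @param seed RNG seed.
#' @param control_reporter Add a control reporter channel (`ch2`)?
#' @param control_sigma Log-scale spread of the control reporter.
#' @param bleed_alpha,bleed_beta Injected bleedthrough coefficients from
#'   marker (`ch1`) into the control channel.
#' @return A [measurement_table()] with columns `cell_id`, `x`, `y`, `ch1`
#'   (marker), optionally `ch2`, and `dosage_true`.
#' @export
synthesize_measurements <- function(culture, sigma_alpha, seed = NULL,
                                    control_reporter = FALSE,
                                    control_sigma = 0.25,
                                    bleed_alpha = 0, bleed_beta = 0) {
  cells <- culture$cells
  with_seed(seed, {
    marker <- sample_fluorescence(cells$dosage, sigma_alpha)
    out <- data.frame(cell_id = cells$id, x = cells$x, y = cells$y,
                      ch1 = marker)
    if (control_reporter) {
      ctrl <- exp(rnorm(nrow(cells), 0, control_sigma))
      out$ch2 <- ctrl + bleed_alpha * marker + bleed_beta
    }
    out$dosage_true <- cells$dosage
    measurement_table(out)
  })
}

#' Mean clone size of a simulated culture
#'
#' Clones are the maximal lineage subtrees of constant dosage founded at
#' recombination events, plus the residual dosage-1 population descending
#' from the unrecombined seed. Returns total cells divided by the number of
#' clones present in the final population.
#'
#' @param culture A `synthetic_culture`.
#' @return Mean cells per clone.
#' @export
mean_clone_size <- function(culture) {
  nrow(culture$cells) / length(unique(culture$cells$clone_id))
}

#' Render a synthetic multichannel image of a culture
#'
#' Draws each cell as a uniform disk: the nuclear-stain channel gets
#' intensity 1 inside every disk, and each supplied level vector becomes a
#' channel whose disks are shaded by the per-cell level. Positions are
#' rescaled into the image frame with a margin; an integer label matrix of
#' the drawn disks is returned alongside the channels. Optional additive
#' Gaussian read noise. A warning (not an error) is raised when the disk
#' radius exceeds half the minimum nearest-neighbor spacing, since disks
#' then overlap by construction.
#'
#' @param culture A `synthetic_culture`, or a two-column position matrix.
#' @param levels Named list of per-cell level vectors (e.g.
#'   `list(ch1 = marker_levels)`), or a single numeric vector.
#' @param image_size Output image side length in pixels.
#' @param nucleus_radius Disk radius in pixels.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param seed Optional RNG seed for the noise.
#' @return List with `channels` (named list of matrices, first `ch0` =
#'   stain), `labels` (integer matrix) and `positions` (pixel coordinates).
#' @export
render_image <- function(culture, levels, image_size = 512,
                         nucleus_radius = 4, noise_sd = 0, seed = NULL) {
  positions <- if (inherits(culture, "synthetic_culture")) {
    cbind(culture$cells$x, culture$cells$y)
  } else as.matrix(culture)
  if (!is.list(levels)) levels <- list(ch1 = levels)
  n <- nrow(positions)
  margin <- 2 * nucleus_radius + 2
  rng_x <- range(positions[, 1]); rng_y <- range(positions[, 2])
  span <- max(rng_x[2] - rng_x[1], rng_y[2] - rng_y[1], 1e-9)
  scale <- (image_size - 2 * margin) / span
  px <- (positions[, 1] - rng_x[1]) * scale + margin
  py <- (positions[, 2] - rng_y[1]) * scale + margin
  if (n > 1) {
    dm <- as.matrix(stats::dist(cbind(px, py)))
    diag(dm) <- Inf
    if (nucleus_radius > min(dm) / 2) {
      warning("nucleus radius exceeds half the minimum spacing; disks overlap",
              call. = FALSE)
    }
  }
  lab <- matrix(0L, image_size, image_size)
  stain <- matrix(0, image_size, image_size)
  chans <- lapply(levels, function(v) matrix(0, image_size, image_size))
  r <- nucleus_radius
  for (i in seq_len(n)) {
    rows <- max(1, floor(py[i] - r)):min(image_size, ceiling(py[i] + r))
    cols <- max(1, floor(px[i] - r)):min(image_size, ceiling(px[i] + r))
    sub <- outer((rows - 1) - py[i], (cols - 1) - px[i],
                 function(dy, dx) dx^2 + dy^2) <= r^2
    lab[rows, cols][sub] <- i
    stain[rows, cols][sub] <- 1
    for (cn in names(chans)) {
      chans[[cn]][rows, cols][sub] <- levels[[cn]][i]
    }
  }
  channels <- c(list(ch0 = stain), chans)
  if (noise_sd > 0) {
    channels <- with_seed(seed, lapply(channels, function(m) {
      pmax(m + matrix(rnorm(length(m), 0, noise_sd), nrow(m)), 0)
    }))
  }
  list(channels = channels, labels = lab, positions = cbind(x = px, y = py))
}

#' Render a synthetic bleedthrough control experiment
#'
#' Emulates a single-reporter control experiment at the image level: every
#' cell carries the same dosage of a control reporter, so any variation of
#' measured reporter levels across clones must come from spectral
#' bleedthrough. The clonal-marker channel receives a smooth background
#' gradient (so its contamination of the reporter channel is identifiable
#' from background pixels); the reporter channel is the rendered control
#' disks plus `bleed_alpha` times the full marker channel plus read noise.
#'
#' @param culture A `synthetic_culture`.
#' @param sigma_alpha Marker fluorescence ambiguity.
#' @param control_sigma Log-scale spread of the dosage-independent control
#'   reporter.
#' @param bleed_alpha Injected pixel-level bleedthrough coefficient
#'   (marker into reporter).
#' @param image_size,nucleus_radius Rendering geometry.
#' @param background_amplitude Peak intensity of the marker-channel
#'   background gradient.
#' @param noise_sd Additive Gaussian read noise per channel.
#' @param seed RNG seed.
#' @return List with `channels` (`ch0` stain, `ch1` marker, `ch2` observed
#'   reporter), `labels` (ground-truth disk label matrix), `truth`
#'   (dosage, marker and control levels per cell) and `bleed_alpha`.
#' @export
render_control_experiment <- function(culture, sigma_alpha = 0.25,
                                      control_sigma = 0.25,
                                      bleed_alpha = 0.3,
                                      image_size = 512, nucleus_radius = 4,
                                      background_amplitude = 0.3,
                                      noise_sd = 0.01, seed = NULL) {
  n <- nrow(culture$cells)
  with_seed(seed, {
    marker <- sample_fluorescence(culture$cells$dosage, sigma_alpha)
    ctrl <- exp(rnorm(n, 0, control_sigma))
    img <- render_image(culture, list(ch1 = marker, ch2 = ctrl),
                        image_size = image_size,
                        nucleus_radius = nucleus_radius)
    # gradient keeps a positive baseline so read noise never drives the
    # background against the zero clip (which would bias the fitted slope)
    grad <- background_amplitude *
      matrix(seq(0.25, 1, length.out = image_size),
             image_size, image_size, byrow = TRUE)
    noise <- function() matrix(rnorm(image_size^2, 0, noise_sd),
                               image_size, image_size)
    stain <- pmax(img$channels$ch0 + noise(), 0)
    marker_img <- pmax(img$channels$ch1 + grad + noise(), 0)
    reporter_img <- pmax(img$channels$ch2 + bleed_alpha * marker_img +
                           noise(), 0)
    list(channels = list(ch0 = stain, ch1 = marker_img,
                         ch2 = reporter_img),
         labels = img$labels,
         truth = list(dosage = culture$cells$dosage, marker = marker,
                      control = ctrl),
         bleed_alpha = bleed_alpha)
  })
}

#' @export
print.synthetic_culture <- function(x, ...) {
  cat(sprintf("Synthetic culture: %d cells, %d generations, %d clones\n",
              nrow(x$cells), x$n_generations,
              length(unique(x$cells$clone_id))))
  cat(sprintf("  dosage counts: %s\n",
              paste(sprintf("%d: %d", 0:2,
                            tabulate(x$cells$dosage + 1L, 3)),
                    collapse = ", ")))
  cat(sprintf("  mean clone size: %.1f cells\n", mean_clone_size(x)))
  invisible(x)
}
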