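# Shared fixture builders: everything is generated in code at test time.

# Minimal valid measurement table.
tiny_table <- function(n = 5, channels = "ch0", seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(cell_id = seq_len(n),
                     x = runif(n, 0, 100), y = runif(n, 0, 100))
    for (ch in channels) df[[ch]] <- runif(n, 1, 10)
    measurement_table(df)
  })
}

# Image with disks of intensity `fg` at given centers on a noisy background;
# returns the image and the ground-truth disk mask.
disk_image <- function(centers, radius = 6, size = 128, fg = 200,
                       bg_mean = 50, bg_sd = 5, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(rnorm(size * size, bg_mean, bg_sd), size, size)
    mask <- matrix(FALSE, size, size)
    for (i in seq_len(nrow(centers))) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      rows <- max(1, floor(cy - radius)):min(size, ceiling(cy + radius))
      cols <- max(1, floor(cx - radius)):min(size, ceiling(cx + radius))
      sub <- outer((rows - 1) - cy, (cols - 1) - cx,
                   function(dy, dx) dx^2 + dy^2) <= radius^2
      img[rows, cols][sub] <- fg
      mask[rows, cols][sub] <- TRUE
    }
    img[img < 0] <- 0
    list(image = img, mask = mask)
  })
}

# Grid of disk centers with given spacing (0-based pixel coordinates).
disk_grid <- function(n, spacing = 16, margin = 10) {
  per_side <- ceiling(sqrt(n))
  g <- expand.grid(x = margin + spacing * (seq_len(per_side) - 1),
                   y = margin + spacing * (seq_len(per_side) - 1))
  as.matrix(g[seq_len(n), ])
}

# Three well-separated dosage groups on the (X, Y) plane, mimicking the
# fluorescence generator: means ln(0.5), ln(1), ln(2), sd sigma; Y is X
# plus small noise (tight spatial context).
three_group_sample <- function(n_per = 100, sigma = 0.1, seed = 1) {
  withr::with_seed(seed, {
    mu <- rep(c(-log(2), 0, log(2)), each = n_per)
    X <- rnorm(3 * n_per, mu, sigma)
    Y <- mu + rnorm(3 * n_per, 0, sigma / 3)
    list(X = X, Y = Y, dosage = rep(0:2, each = n_per))
  })
}

# Grow a culture that is actually mosaic (>= 3 clones); cultures whose
# recombination window passes without an event have no clones and no
# defined clone size, so they are replaced from derived seeds.
mosaic_culture <- function(final_size, start, duration, seed) {
  for (k in 0:5) {
    cu <- grow_culture(final_size = final_size,
                       recombination_start_size = start,
                       recombination_duration = duration,
                       seed = seed + 1000L * k)
    if (length(unique(cu$cells$clone_id)) >= 3) return(cu)
  }
  cu
}

# Brute-force two-sided exact Mann-Whitney p-value by enumerating all
# C(n_a + n_b, n_a) group assignments of the pooled sample (tie-free data).
mwu_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combos <- utils::combn(length(pooled), n_a)
  us <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n_a * (n_a + 1) / 2
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(p, 1)
}

# Optimal grouping of 1-D values into `g` contiguous groups (minimum
# within-group sum of squares) by brute force over all cut placements;
# independent oracle for the component-to-dosage k-means mapping.
contiguous_partition_oracle <- function(values, g = 3) {
  ord <- order(values)
  v <- values[ord]
  K <- length(v)
  cuts <- utils::combn(K - 1, g - 1)
  best <- NULL; best_ss <- Inf
  for (ci in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, ci], K)
    ss <- 0
    grp <- integer(K)
    for (gi in seq_len(g)) {
      idx <- (bounds[gi] + 1):bounds[gi + 1]
      ss <- ss + sum((v[idx] - mean(v[idx]))^2)
      grp[idx] <- gi - 1L
    }
    if (ss < best_ss) { best_ss <- ss; best <- grp }
  }
  out <- integer(K)
  out[ord] <- best
  out
}
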