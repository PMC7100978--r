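test_that("growth conserves dosage and respects the recombination window", {
  cu <- grow_culture(final_size = 256, recombination_start_size = 8,
                     recombination_duration = 4, seed = 3)
  div <- cu$divisions
  # every division partitions the duplicated genes between the daughters
  expect_true(all(div$daughter1_dosage + div$daughter2_dosage ==
                    2 * div$parent_dosage))
  # recombination only within the window, only from heterozygous parents
  rec <- div[div$daughter1_dosage != div$daughter2_dosage, ]
  expect_true(all(rec$parent_dosage == 1))
  expect_true(all(rec$generation >= cu$recombination_onset))
  expect_true(all(rec$generation < cu$recombination_onset +
                    cu$params$recombination_duration))
  # lineage is a forest rooted at the seed cell
  expect_equal(sum(is.na(cu$cells$parent_id)), 1)
  expect_true(all(stats::na.omit(cu$cells$parent_id) %in% cu$cells$id))

  # no recombination: a single heterozygous clone
  cu0 <- grow_culture(final_size = 64, recombination_prob = 0, seed = 5)
  expect_true(all(cu0$cells$dosage == 1L))
  expect_equal(mean_clone_size(cu0), nrow(cu0$cells))

  expect_error(grow_culture(division_prob = 0),
               class = "qmosaic_parameter_error")
  expect_error(grow_culture(final_size = 1),
               class = "qmosaic_parameter_error")
})

test_that("population growth follows the branching-process rate", {
  # E[N_t] = (1 + p)^t: observed per-generation log growth near ln(1.2)
  rates <- vapply(1:20, function(s) {
    cu <- grow_culture(final_size = 128, recombination_prob = 0, seed = 400 + s)
    log(nrow(cu$cells)) / cu$n_generations
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lte(abs(mean(rates) - log(1.2)), 3 * se + 0.01)
})

test_that("identical seeds reproduce the culture bit for bit", {
  a <- grow_culture(final_size = 128, recombination_start_size = 8, seed = 9)
  b <- grow_culture(final_size = 128, recombination_start_size = 8, seed = 9)
  expect_identical(a$cells, b$cells)
  c <- grow_culture(final_size = 128, recombination_start_size = 8, seed = 10)
  expect_false(identical(a$cells, c$cells))
})

test_that("repositioning preserves density and clonal cohesion", {
  # two cells: closed-form spring equilibrium at the rest length
  two <- reposition(rbind(c(0, 0), c(3, 0)), c(1L, 1L), rest_length = 1)
  expect_equal(sqrt(sum((two[1, ] - two[2, ])^2)), 1, tolerance = 1e-9)

  cu <- grow_culture(final_size = 512, recombination_start_size = 8, seed = 42)
  pos <- cbind(cu$cells$x, cu$cells$y)
  dm <- as.matrix(stats::dist(pos)); diag(dm) <- Inf
  nnd <- apply(dm, 1, min)
  expect_lte(sd(nnd) / mean(nnd), 0.5)

  # same-dosage neighbor fraction beats the label-permuted baseline
  nn <- apply(dm, 1, which.min)
  cohesion <- mean(cu$cells$dosage == cu$cells$dosage[nn])
  withr::with_seed(1, {
    baseline <- replicate(50, {
      p <- sample(cu$cells$dosage)
      mean(p == p[nn])
    })
  })
  expect_gt(cohesion, quantile(baseline, 0.99))
})

test_that("fluorescence sampling doubles with each gene copy", {
  withr::with_seed(19, {
    for (d in 0:2) {
      x <- sample_fluorescence(rep(d, 10000), sigma_alpha = 0.3)
      expect_equal(median(x), 2^(d - 1), tolerance = 0.03)
      expect_equal(var(log(x)), 0.3^2, tolerance = 0.05)
    }
    # ratio of group means is 2 between consecutive dosages
    m <- vapply(0:2, function(d) {
      mean(sample_fluorescence(rep(d, 20000), sigma_alpha = 0.4))
    }, numeric(1))
    expect_equal(m[2] / m[1], 2, tolerance = 0.05)
    expect_equal(m[3] / m[2], 2, tolerance = 0.05)
  })
  expect_error(sample_fluorescence(0:2, sigma_alpha = 0),
               class = "qmosaic_parameter_error")
})

test_that("dosage-0 and dosage-2 fractions balance across seeds", {
  fracs <- vapply(1:20, function(s) {
    cu <- grow_culture(final_size = 128, recombination_start_size = 8,
                       seed = 600 + s)
    n <- nrow(cu$cells)
    c(mean(cu$cells$dosage == 0), mean(cu$cells$dosage == 2))
  }, numeric(2))
  d <- fracs[1, ] - fracs[2, ]
  se <- sd(d) / sqrt(length(d))
  expect_lte(abs(mean(d)), 3 * se + 1e-9)
})

test_that("later recombination onset yields smaller clones", {
  sizes <- vapply(c(16, 64, 256), function(start) {
    mean(vapply(1:5, function(s) {
      mean_clone_size(grow_culture(final_size = 512,
                                   recombination_start_size = start,
                                   seed = 700 + s))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sizes) < 0))
})

test_that("ambiguity increases the overlap of adjacent dosage distributions", {
  bhattacharyya <- function(x, y) {
    breaks <- seq(min(x, y), max(x, y), length.out = 60)
    px <- hist(x, breaks = breaks, plot = FALSE)$counts / length(x)
    py <- hist(y, breaks = breaks, plot = FALSE)$counts / length(y)
    sum(sqrt(px * py))
  }
  overlaps <- vapply(c(0.2, 0.4, 0.8), function(sg) {
    x1 <- sample_fluorescence(rep(1, 20000), sg, seed = 23)
    x2 <- sample_fluorescence(rep(2, 20000), sg, seed = 29)
    bhattacharyya(log(x1), log(x2))
  }, numeric(1))
  expect_true(all(diff(overlaps) > 0))
})

test_that("rendered images close the loop with segmentation", {
  cu <- grow_culture(final_size = 200, recombination_start_size = 8, seed = 55)
  levels <- sample_fluorescence(cu$cells$dosage, sigma_alpha = 0.3, seed = 56)
  img <- suppressWarnings(render_image(cu, list(ch1 = levels),
                                       image_size = 360,
                                       nucleus_radius = 4))
  # ground-truth label means equal the sampled levels exactly (no noise)
  tab_true <- measure_segments(img$labels, img$channels)
  expect_equal(tab_true$ch1, levels[tab_true$cell_id], tolerance = 1e-12)

  # one cell, one disk per channel
  single <- render_image(rbind(c(0, 0), c(10, 0), c(0, 10)),
                         list(ch1 = c(5, 5, 5)), image_size = 128,
                         nucleus_radius = 5)
  expect_equal(max(single$labels), 3)
  expect_equal(sort(unique(as.vector(single$channels$ch0))), c(0, 1))

  # segment the rendered stain, then recover the marker levels
  noisy <- suppressWarnings(render_image(cu, list(ch1 = levels),
                                         image_size = 360,
                                         nucleus_radius = 4,
                                         noise_sd = 0.02, seed = 57))
  labs <- segment_nuclei(noisy$channels$ch0 * 200, min_area = 15)
  meas <- measure_segments(labs, noisy$channels)
  expect_gte(nrow(meas), 0.9 * 200)
  # match segments to generating cells by nearest rendered position
  nearest <- apply(meas[, c("x", "y")], 1, function(p) {
    which.min((img$positions[, 1] - p[1])^2 + (img$positions[, 2] - p[2])^2)
  })
  expect_gte(cor(meas$ch1, levels[nearest]), 0.95)
})

test_that("overlapping disks trigger a warning, not an error", {
  pos <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_warning(render_image(pos, list(ch1 = c(1, 2, 3)), image_size = 64,
                              nucleus_radius = 20),
                 "overlap")
})
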