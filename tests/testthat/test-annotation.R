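test_that("spatial correlation is flat for iid fields, high for clones", {
  withr::with_seed(21, {
    pos <- cbind(runif(400, 0, 100), runif(400, 0, 100))
    X <- rnorm(400)
    sc <- spatial_correlation(pos, X, seed = 1)
    # permutation spread: psi under no spatial structure
    perm <- replicate(20, {
      spatial_correlation(pos, sample(X), seed = 1)$psi
    })
    sds <- apply(perm, 1, sd)
    later <- 2:length(sc$psi)
    expect_true(all(abs(sc$psi[later]) <= 4 * sds[later]))
  })

  # two half-plane clones: near-unity short-range correlation, decaying
  g <- expand.grid(x = 1:25, y = 1:20)
  X2 <- ifelse(g$x <= 12, -1, 1)
  sc2 <- spatial_correlation(cbind(g$x, g$y), X2, seed = 1)
  expect_gt(sc2$psi[1], 0.8)
  expect_lt(stats::cor(sc2$delta, sc2$psi_smooth, method = "spearman"), -0.7)
  expect_gt(sc2$decay_length, 1)

  expect_error(spatial_correlation(cbind(1:60, 1:60), rep(1, 60)),
               class = "qmosaic_zero_variance_error")
})

test_that("coincident duplicated cells give unit correlation at zero range", {
  withr::with_seed(3, {
    base <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
    Xb <- rnorm(200)
    pos <- rbind(base, base)       # each location duplicated exactly
    X <- c(Xb, Xb)                 # equal expression within each pair
    sc <- spatial_correlation(pos, X, n_bins = 400, seed = 1)
    expect_equal(sc$psi[1], 1, tolerance = 0.05)
  })
})

test_that("radius context averages neighbors with self-fallback", {
  pos <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  X <- c(5, 0, 2)
  Y <- sample_context(pos, X, radius = 1.5)
  expect_equal(Y[1], 1)                     # mean of {0, 2}
  expect_equal(sample_context(pos, rep(3, 3), radius = 1.5), rep(3, 3))
  expect_equal(sample_context(pos, X, radius = 0.5), X)  # no neighbors
  expect_error(sample_context(pos, X, radius = 0),
               class = "qmosaic_parameter_error")
})

test_that("cell graph weights follow the expression-similarity kernel", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, 1))
  # equal expression: all weights 1
  cg0 <- build_cell_graph(tri, c(2, 2, 2))
  expect_equal(cg0$edges$weight, rep(1, 3))
  # |X_i - X_j| = mean log fold-change: weight exactly e^-1
  cg <- build_cell_graph(tri, c(0, 1, 3))
  e <- cg$edges
  target <- e[e$logfc == 2, ]
  expect_equal(cg$mean_logfc, 2)
  expect_equal(target$weight, exp(-1), tolerance = 1e-12)
  expect_error(build_cell_graph(rbind(c(0, 0), c(1, 1)), c(1, 2)),
               class = "qmosaic_triangulation_error")
})

test_that("edge-length filter isolates a distant outlier", {
  g <- as.matrix(expand.grid(x = 1:20, y = 1:20))
  n <- nrow(g) + 1
  pos <- rbind(g, c(500, 500))
  cg <- build_cell_graph(pos, rnorm(n), max_edge_quantile = 0.95)
  expect_false(n %in% c(cg$edges$i, cg$edges$j))
})

test_that("community detection separates expression blocks", {
  withr::with_seed(13, {
    g <- expand.grid(x = 1:10, y = 1:10)
    block <- ifelse(g$x <= 5, 0, 1)
    X <- block * 3 + rnorm(100, 0, 0.05)
    cg <- build_cell_graph(cbind(g$x, g$y), X)
    comm <- detect_communities(cg, decay_length = 8, seed = 5)
    expect_length(comm, 100)
    expect_false(any(is.na(comm)))
    # the two expression blocks should be (near-)pure communities
    purity <- sum(vapply(split(block, comm), function(b) {
      max(table(b))
    }, numeric(1))) / 100
    expect_gte(purity, 0.95)

    # complete graph with equal weights has no structure: one community
    n <- 6
    pts <- cbind(cos(2 * pi * (1:n) / n), sin(2 * pi * (1:n) / n))
    pairs <- t(utils::combn(n, 2))
    complete <- structure(list(
      graph = igraph::make_full_graph(n),
      edges = data.frame(i = pairs[, 1], j = pairs[, 2], length = 1,
                         logfc = 0, weight = 1),
      positions = pts, X = rep(1, n), mean_logfc = 0),
      class = "cell_graph")
    igraph::E(complete$graph)$weight <- 1
    comm_c <- detect_communities(complete, decay_length = 100, seed = 5)
    expect_equal(length(unique(comm_c)), 1)
  })
})

test_that("community context is the within-community mean", {
  X <- c(1, 3, 10)
  expect_equal(community_context(X, c(1, 1, 2)), c(2, 2, 10))
  expect_equal(community_context(X, c(1, 2, 3)), X)   # singletons
  expect_equal(community_context(rep(4, 5), c(1, 1, 2, 2, 2)), rep(4, 5))
})

test_that("posterior diffusion solves the Katz recursion", {
  # alpha = 0: identity
  W2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 1))
  p <- rbind(c(1, 0), c(0, 1))
  expect_equal(diffuse_posteriors(W2, p, 0), p)

  # hand-solved 2-node system: (I - 0.5 W)^-1 (0.5) (1,0) = (2/3, 1/3)
  ph <- diffuse_posteriors(W2, p, 0.5)
  expect_equal(ph[, 1], c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(ph[, 2], c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(rowSums(ph), c(1, 1), tolerance = 1e-10)

  # attenuation beyond the spectral bound is rejected
  expect_error(diffuse_posteriors(W2, p, 1.1),
               class = "qmosaic_attenuation_error")

  # dense solve equals the power-iteration oracle on random graphs
  withr::with_seed(31, {
    for (rep_i in 1:5) {
      n <- sample(10:50, 1)
      A <- matrix(runif(n * n) < 0.2, n, n)
      A[lower.tri(A, diag = TRUE)] <- FALSE
      W <- (A + t(A)) * matrix(runif(n * n, 0.1, 1), n, n)
      W <- Matrix::Matrix((W + t(W)) / 2, sparse = TRUE)
      p0 <- matrix(runif(n * 3), n, 3)
      p0 <- p0 / rowSums(p0)
      alpha <- 0.9 / qmosaic:::spectral_radius(W)
      got <- diffuse_posteriors(W, p0, alpha)
      ph_or <- (1 - alpha) * p0
      for (it in 1:4000) {
        nxt <- alpha * as.matrix(W %*% ph_or) + (1 - alpha) * p0
        if (max(abs(nxt - ph_or)) < 1e-14) { ph_or <- nxt; break }
        ph_or <- nxt
      }
      ph_or <- ph_or / rowSums(ph_or)
      expect_lt(max(abs(got - ph_or)), 1e-8)
    }
  })
})

test_that("increasing diffusion strengthens neighbor label agreement", {
  withr::with_seed(31, {
    # two loose spatial blocks with noisy posteriors
    g <- expand.grid(x = 1:8, y = 1:8)
    block <- ifelse(g$x <= 4, 1, 2)
    X <- (block - 1) * 2 + rnorm(64, 0, 0.9)
    cg <- build_cell_graph(cbind(g$x, g$y), X)
    p <- cbind(stats::plogis(-1.2 * (X - 1)), stats::plogis(1.2 * (X - 1)))
    W <- qmosaic:::graph_weight_matrix(cg)
    rho <- qmosaic:::spectral_radius(W)
    agree <- vapply(c(0, 0.5, 0.9), function(a) {
      ph <- diffuse_posteriors(cg, p, a / rho)
      lab <- max.col(ph, ties.method = "first")
      e <- cg$edges
      mean(lab[e$i] == lab[e$j])
    }, numeric(1))
    expect_true(all(diff(agree) > 0))
  })
})

test_that("marginal classification follows the X-axis posterior", {
  model <- structure(list(K = 3, lambda = rep(1 / 3, 3),
                          mu = cbind(c(-2, 0, 2), 0),
                          sigma2 = matrix(0.04, 3, 2)),
                     class = "mixture_model")
  f <- map_components(model)
  expect_equal(classify_marginal(c(-2, 0, 2), model, f), c(0L, 1L, 2L))
  # equidistant tie resolves to the lowest component index
  tie_model <- structure(list(K = 3, lambda = c(0.4, 0.4, 0.2),
                              mu = cbind(c(1, 1, 5), 0),
                              sigma2 = matrix(1, 3, 2)),
                         class = "mixture_model")
  p <- posterior_marginal(tie_model, 1)
  expect_equal(p[1, 1], p[1, 2])
  ftie <- c(0L, 1L, 2L)
  expect_equal(classify_marginal(1, tie_model, ftie), 0L)
})

test_that("annotation labels perfectly separated bands exactly", {
  g <- expand.grid(x = 1:30, y = 1:10)
  dosage <- ifelse(g$x <= 10, 0L, ifelse(g$x <= 20, 1L, 2L))
  tab <- measurement_table(data.frame(
    cell_id = seq_len(300), x = g$x, y = g$y,
    ch1 = 2^(dosage - 1)))              # exact levels 0.5, 1, 2
  res <- annotate(tab, marker_channel = "ch1", k_range = 3:5, seed = 11,
                  details = TRUE)
  interior <- !flag_borders(cbind(g$x, g$y), dosage)
  expect_equal(res$table$dosage[interior], dosage[interior])
  expect_true(all(res$table$confidence >= 0 & res$table$confidence <= 1))
  # confidence equals the diffused posterior mass of the assigned label
  kept <- which(!res$replaced)
  conf <- vapply(kept, function(i) {
    sum(res$diffused[i, res$f == res$table$dosage[i]])
  }, numeric(1))
  expect_equal(res$table$confidence[kept], conf, tolerance = 1e-12)
  expect_setequal(sort(unique(res$f)), 0:2)   # f onto {0,1,2}
})

test_that("annotation leaves the input unchanged on failure", {
  tab <- tiny_table(30, channels = "ch1")
  expect_error(annotate(tab), class = "qmosaic_fit_error")
  expect_error(annotate(tiny_table(60, channels = "ch0"),
                        marker_channel = "ch5"),
               class = "qmosaic_schema_error")
})
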