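#' Spatial correlation of expression and its decay length
#'
#' Estimates the radial correlation function
#' `psi(delta) = <(X_i - mu)(X_j - mu)>_{|r_i - r_j| = delta} / var(X)`
#' over binned pair separations, smooths it with a moving average, and fits
#' a least-squares exponential decay `a exp(-delta / L)` to the smoothed
#' curve. The decay length `L` sets the neighborhood radius for spatial
#' context sampling and the community-aggregation cut.
#'
#' Pair separations are grouped into equal-count bins; when the number of
#' pairs exceeds `max_pairs` a uniform random subsample of pairs is used
#' (seeded), keeping the cost bounded for large images. Normalization uses
#' the population variance, so coincident duplicated cells with equal
#' expression give `psi = 1` at zero separation.
#'
#' @param positions Two-column matrix of cell centroids.
#' @param X Numeric vector of log clonal-marker levels.
#' @param n_bins Number of equal-count separation bins.
#' @param window Moving-average window (bins).
#' @param max_pairs Cap on the number of cell pairs used.
#' @param seed Optional RNG seed for pair subsampling.
#' @return List with `delta` (bin centers), `psi`, `psi_smooth`, and
#'   `decay_length` (pixels).
#' @export
spatial_correlation <- function(positions, X, n_bins = 50, window = 5,
                                max_pairs = 5e5, seed = NULL) {
  positions <- as.matrix(positions)
  n <- length(X)
  if (n < 50) {
    qm_stop("need at least 50 cells to estimate spatial correlation",
            "qmosaic_fit_error")
  }
  v <- mean((X - mean(X))^2)
  if (v == 0) {
    qm_stop("expression is constant: correlation undefined",
            "qmosaic_zero_variance_error")
  }
  n_pairs_total <- n * (n - 1) / 2
  if (n_pairs_total > max_pairs) {
    pair_idx <- with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n, max_pairs, replace = TRUE)
      keep <- i != j
      cbind(pmin(i, j), pmax(i, j))[keep, , drop = FALSE]
    })
    i <- pair_idx[, 1]; j <- pair_idx[, 2]
  } else {
    combos <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- combos[, 1]; j <- combos[, 2]
  }
  d <- sqrt((positions[i, 1] - positions[j, 1])^2 +
              (positions[i, 2] - positions[j, 2])^2)
  prod <- (X[i] - mean(X)) * (X[j] - mean(X)) / v
  ord <- order(d)
  d <- d[ord]; prod <- prod[ord]
  bin <- ceiling(seq_along(d) / (length(d) / n_bins))
  bin[bin > n_bins] <- n_bins
  delta <- as.numeric(tapply(d, bin, mean))
  psi <- as.numeric(tapply(prod, bin, mean))
  psi_smooth <- stats::filter(psi, rep(1 / window, window), sides = 2)
  psi_smooth <- as.numeric(psi_smooth)
  na <- is.na(psi_smooth)
  psi_smooth[na] <- psi[na]
  decay_length <- .fit_exp_decay(delta, psi_smooth)
  list(delta = delta, psi = psi, psi_smooth = psi_smooth,
       decay_length = decay_length)
}

# Least-squares fit of a * exp(-b * delta); returns 1/b. Falls back to a
# log-linear regression over the initial positive stretch of the curve if
# the nonlinear fit does not converge.
.fit_exp_decay <- function(delta, psi) {
  loglin <- function() {
    pos <- which(psi > 0.02)
    pos <- pos[pos <= (which(c(psi <= 0.02, TRUE))[1])]  # initial stretch
    if (length(pos) < 2) return(delta[2] %||% delta[1])
    fit <- lm(log(psi[pos]) ~ delta[pos])
    b <- -unname(coef(fit)[2])
    if (!is.finite(b) || b <= 0) delta[2] else 1 / b
  }
  start_L <- unname(loglin())
  fit <- tryCatch(
    minpack.lm::nlsLM(psi ~ a * exp(-delta / L),
                      start = list(a = max(psi[1], 0.5), L = start_L),
                      lower = c(a = 1e-6, L = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(unname(start_L))
  unname(coef(fit)[["L"]])
}

#' Radius-based spatial context
#'
#' `Y_i` is the mean log expression over all cells within `radius` of cell
#' i, excluding i itself; a cell with no neighbor falls back to its own
#' value.
#'
#' @inheritParams spatial_correlation
#' @param radius Neighborhood radius in pixels (> 0), typically the decay
#'   length from [spatial_correlation()].
#' @return Numeric vector `Y` of the same length as `X`.
#' @export
sample_context <- function(positions, X, radius) {
  if (radius <= 0) qm_stop("radius must be positive", "qmosaic_parameter_error")
  positions <- as.matrix(positions)
  n <- length(X)
  dm <- as.matrix(stats::dist(positions))
  Y <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] <= radius)
    nb <- nb[nb != i]
    Y[i] <- if (length(nb) == 0) X[i] else mean(X[nb])
  }
  Y
}

#' Cell adjacency graph with expression-similarity weights
#'
#' Builds an undirected graph over cells from the Delaunay triangulation of
#' their positions, drops edges longer than the `max_edge_quantile` of edge
#' lengths, and weights each remaining edge by
#' `w_ij = exp(-|X_i - X_j| / <|X - X|>)` where the denominator is the mean
#' absolute log fold-change across retained edges. Similar neighbors thus
#' get weights near 1 and dissimilar neighbors near 0; the exponential form
#' spreads the weights approximately uniformly.
#'
#' @inheritParams spatial_correlation
#' @param max_edge_quantile Quantile of Delaunay edge lengths above which
#'   edges are discarded.
#' @return A `cell_graph`: list with the `igraph` object (`graph`), the
#'   edge table (`edges`: i, j, length, logfc, weight), `positions` and `X`.
#' @export
build_cell_graph <- function(positions, X, max_edge_quantile = 0.95) {
  positions <- as.matrix(positions)
  edges <- delaunay_edges(positions, max_edge_quantile)
  edges$logfc <- abs(X[edges$i] - X[edges$j])
  mean_e <- mean(edges$logfc)
  edges$weight <- if (mean_e == 0) rep(1, nrow(edges)) else
    exp(-edges$logfc / mean_e)
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j", "weight")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(positions))))
  structure(list(graph = g, edges = edges, positions = positions, X = X,
                 mean_logfc = mean_e),
            class = "cell_graph")
}

# Symmetric sparse weight matrix of a cell graph.
graph_weight_matrix <- function(cgraph) {
  n <- nrow(cgraph$positions)
  e <- cgraph$edges
  Matrix::sparseMatrix(i = c(e$i, e$j), j = c(e$j, e$i),
                       x = c(e$weight, e$weight), dims = c(n, n))
}

# Largest-magnitude eigenvalue of a symmetric nonnegative matrix by power
# iteration.
spectral_radius <- function(W, n_iter = 200, tol = 1e-10) {
  n <- nrow(W)
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(n_iter)) {
    u <- as.numeric(W %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) return(0)
    u <- u / nu
    new_lam <- as.numeric(t(u) %*% (W %*% u))
    if (abs(new_lam - lam) < tol) return(new_lam)
    lam <- new_lam
    v <- u
  }
  lam
}

#' Hierarchical community detection with a correlation-length cut
#'
#' Partitions the cell graph with the Infomap algorithm, then deepens the
#' partition recursively (Infomap re-run inside each community) to build a
#' hierarchy of nested levels. The returned assignment is the coarsest
#' level whose mean community spatial extent (twice the RMS distance of
#' members from the community centroid) stays below `decay_length`; if no
#' level qualifies the finest level is used. If the chosen cut degenerates
#' to (mean) singleton communities the result carries
#' `attr(, "fallback") = TRUE`, signalling the caller to use radius-based
#' context instead.
#'
#' @param cgraph A `cell_graph`.
#' @param decay_length Spatial correlation decay length (pixels).
#' @param max_depth Maximum hierarchy depth.
#' @param seed Optional RNG seed (Infomap is stochastic).
#' @return Integer community id per cell.
#' @export
detect_communities <- function(cgraph, decay_length, max_depth = 6,
                               seed = NULL) {
  g <- cgraph$graph
  n <- igraph::vcount(g)
  with_seed(seed, {
    levels <- list()
    top <- igraph::membership(igraph::cluster_infomap(
      g, e.weights = igraph::E(g)$weight))
    levels[[1]] <- as.integer(top)
    depth <- 1
    repeat {
      if (depth >= max_depth) break
      cur <- levels[[depth]]
      nxt <- cur
      offset <- 0L
      split_any <- FALSE
      for (cid in sort(unique(cur))) {
        members <- which(cur == cid)
        if (length(members) >= 4) {
          sub <- igraph::induced_subgraph(g, members)
          subm <- igraph::membership(igraph::cluster_infomap(
            sub, e.weights = igraph::E(sub)$weight))
          if (max(subm) > 1) split_any <- TRUE
          nxt[members] <- offset + as.integer(subm)
          offset <- offset + max(subm)
        } else {
          nxt[members] <- offset + 1L
          offset <- offset + 1L
        }
      }
      if (!split_any) break
      depth <- depth + 1
      levels[[depth]] <- as.integer(nxt)
    }
    # choose the coarsest level whose mean community extent <= decay length
    extents <- vapply(levels, function(m) {
      mean(vapply(split(seq_len(n), m), function(idx) {
        p <- cgraph$positions[idx, , drop = FALSE]
        ctr <- colMeans(p)
        2 * sqrt(mean((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2))
      }, numeric(1)))
    }, numeric(1))
    pick <- which(extents <= decay_length)
    chosen <- if (length(pick) > 0) levels[[min(pick)]] else
      levels[[length(levels)]]
    comm <- match(chosen, sort(unique(chosen)))
    if (mean(tabulate(comm)) <= 1) attr(comm, "fallback") <- TRUE
    comm
  })
}

#' Community-based spatial context
#'
#' `Y_c[i]` is the mean log expression over all cells in i's community
#' (including i); singleton communities reduce to the cell's own value.
#'
#' @param X Numeric vector of log expression levels.
#' @param communities Integer community ids from [detect_communities()].
#' @return Numeric vector `Y_c`.
#' @export
community_context <- function(X, communities) {
  ave(X, communities)
}

#' Katz-style diffusion of posterior probabilities over the cell graph
#'
#' Solves the recursion `p_hat = alpha W p_hat + (1 - alpha) p` in closed
#' form, `p_hat = (I - alpha W)^{-1} (1 - alpha) p`, independently for each
#' mixture component, then renormalizes per cell so the diffused values sum
#' to 1 (the linear solve does not preserve the probability scale for
#' general weight matrices; the argmax label is unaffected but confidences
#' need a probability scale). Requires `alpha * rho(W) < 1`.
#'
#' @param cgraph A `cell_graph` (or a weight matrix).
#' @param p `n x K` matrix of per-cell component posteriors.
#' @param alpha Attenuation factor in `[0, 1)` relative to the spectral
#'   radius constraint.
#' @return `n x K` matrix of diffused, renormalized posteriors.
#' @export
diffuse_posteriors <- function(cgraph, p, alpha) {
  W <- if (inherits(cgraph, "cell_graph")) graph_weight_matrix(cgraph) else
    methods::as(cgraph, "CsparseMatrix")
  p <- as.matrix(p)
  if (alpha == 0) return(p / rowSums(p))
  rho <- spectral_radius(W)
  if (alpha * rho >= 1) {
    qm_stop(sprintf("attenuation too large: alpha * rho(W) = %.3f >= 1",
                    alpha * rho),
            "qmosaic_attenuation_error")
  }
  n <- nrow(p)
  A <- Matrix::Diagonal(n) - alpha * W
  sol <- as.matrix(Matrix::solve(A, (1 - alpha) * p))
  sol[sol < 0] <- 0
  sol / rowSums(sol)
}

#' Marginal dosage classification
#'
#' Labels each cell by the dosage of the component maximizing the X-axis
#' marginal posterior `p(k | X)`, ignoring spatial context entirely. Ties
#' resolve to the lowest component index.
#'
#' @param X Log clonal-marker levels.
#' @param model A fitted `mixture_model`.
#' @param f Component-to-dosage map from [map_components()].
#' @return Integer dosage per cell.
#' @export
classify_marginal <- function(X, model, f = map_components(model)) {
  p <- posterior_marginal(model, X)
  f[max.col(p, ties.method = "first")]
}

#' Log marker level with positivity floor
#'
#' Bleedthrough subtraction can push corrected levels to or below zero;
#' values at or below a small positive floor (a fraction of the positive
#' median) are clipped to the floor before the log.
#'
#' @param x Marker levels (raw or corrected).
#' @param floor_fraction Floor as a fraction of the median positive level.
#' @return `log(pmax(x, floor))`.
#' @export
log_marker_level <- function(x, floor_fraction = 0.01) {
  pos <- x[x > 0]
  if (length(pos) == 0) {
    qm_stop("no positive marker levels", "qmosaic_fit_error")
  }
  eps <- floor_fraction * median(pos)
  log(pmax(x, eps))
}

#' Annotate gene dosage for every nucleus
#'
#' Runs the full unsupervised annotation pipeline on a measurement table:
#' estimate the spatial correlation decay length; sample radius-based
#' context `Y`; fit the bivariate mixture over `(X, Y)` with BIC model
#' selection; map components to dosages; build the weighted Delaunay cell
#' graph; detect communities and recompute context as the community mean;
#' evaluate joint posteriors at `(X, Y_c)`; diffuse them over the graph;
#' and label each cell by the most probable dosage. Labels whose total
#' posterior confidence falls below `confidence_threshold` are replaced by
#' the marginal classifier's labels (with the marginal posterior mass as
#' their confidence).
#'
#' @param table A [measurement_table()].
#' @param marker_channel Raw channel column holding the clonal marker
#'   (its `_corrected` column is used when present).
#' @param k_range BIC scan range for the mixture size.
#' @param edge_quantile Delaunay edge-length filter quantile.
#' @param alpha_frac Diffusion attenuation as a fraction of `1 / rho(W)`.
#' @param confidence_threshold Minimum confidence to keep a
#'   context-informed label.
#' @param n_labels Number of dosage labels (default ternary).
#' @param seed RNG seed for all stochastic stages.
#' @param details If `TRUE`, return a list with the table plus the fitted
#'   model, map, graph, posteriors and marginal labels.
#' @return The table with `dosage` and `confidence` columns filled in (or a
#'   detail list when `details = TRUE`).
#' @export
annotate <- function(table, marker_channel = "ch1", k_range = 3:8,
                     edge_quantile = 0.95, alpha_frac = 0.9,
                     confidence_threshold = 0.8, n_labels = 3,
                     seed = NULL, details = FALSE) {
  table <- measurement_table(table)
  if (nrow(table) < 50) {
    qm_stop("need at least 50 cells for annotation", "qmosaic_fit_error")
  }
  col <- intensity_column(table, marker_channel)
  if (!col %in% names(table)) {
    qm_stop(sprintf("missing marker channel: %s", marker_channel),
            "qmosaic_schema_error")
  }
  positions <- cbind(table$x, table$y)
  X <- log_marker_level(table[[col]])

  sc <- spatial_correlation(positions, X, seed = seed)
  Y <- sample_context(positions, X, radius = sc$decay_length)
  model <- fit_mixture(X, Y, k_range = k_range, seed = seed)
  f <- map_components(model, n_labels = n_labels)
  cg <- build_cell_graph(positions, X, max_edge_quantile = edge_quantile)
  comm <- detect_communities(cg, sc$decay_length, seed = seed)
  Yc <- if (isTRUE(attr(comm, "fallback"))) Y else community_context(X, comm)

  p <- posterior(model, X, Yc)
  W <- graph_weight_matrix(cg)
  alpha <- alpha_frac / max(spectral_radius(W), .Machine$double.eps)
  p_hat <- diffuse_posteriors(cg, p, alpha)

  k_star <- max.col(p_hat, ties.method = "first")
  dosage <- f[k_star]
  confidence <- vapply(seq_len(nrow(p_hat)), function(i) {
    sum(p_hat[i, f == dosage[i]])
  }, numeric(1))

  p_marg <- posterior_marginal(model, X)
  marg_k <- max.col(p_marg, ties.method = "first")
  marginal_dosage <- f[marg_k]
  marginal_confidence <- vapply(seq_along(marg_k), function(i) {
    sum(p_marg[i, f == marginal_dosage[i]])
  }, numeric(1))

  low <- confidence < confidence_threshold
  dosage[low] <- marginal_dosage[low]
  confidence[low] <- marginal_confidence[low]

  table$dosage <- as.integer(dosage)
  table$confidence <- pmin(pmax(confidence, 0), 1)  # guard float round-off
  out <- measurement_table(table)
  if (!details) return(out)
  list(table = out, model = model, f = f, graph = cg, communities = comm,
       decay_length = sc$decay_length, context = Yc,
       posteriors = p, diffused = p_hat,
       marginal_dosage = as.integer(marginal_dosage),
       alpha = alpha, replaced = low)
}
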