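# Shared planar-geometry helpers: Delaunay neighbor extraction (via deldir)
# and small polygon predicates used by ROI curation.

# Delaunay edge list for a set of points. Returns data.frame(i, j, length)
# with i < j. Optionally drops edges longer than the given quantile of edge
# lengths (the same filter is used by the cell graph and border flagging so
# "neighbor" means one thing throughout).
delaunay_edges <- function(positions, max_edge_quantile = NULL) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3) {
    qm_stop("need at least 3 points for triangulation",
            "qmosaic_triangulation_error")
  }
  dd <- tryCatch(
    suppressWarnings(deldir::deldir(positions[, 1], positions[, 2])),
    error = function(e) {
      qm_stop(sprintf("triangulation failed (degenerate geometry?): %s",
                      conditionMessage(e)), "qmosaic_triangulation_error")
    })
  if (is.null(dd) || nrow(dd$delsgs) == 0) {
    qm_stop("triangulation produced no edges (collinear points?)",
            "qmosaic_triangulation_error")
  }
  e <- dd$delsgs
  i <- pmin(e$ind1, e$ind2)
  j <- pmax(e$ind1, e$ind2)
  len <- sqrt((e$x1 - e$x2)^2 + (e$y1 - e$y2)^2)
  edges <- data.frame(i = i, j = j, length = len)
  edges <- edges[!duplicated(edges[, c("i", "j")]), , drop = FALSE]
  if (!is.null(max_edge_quantile)) {
    cutoff <- quantile(edges$length, max_edge_quantile, names = FALSE)
    edges <- edges[edges$length <= cutoff, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

# Orientation of the triple (a, b, c): >0 counter-clockwise, <0 clockwise,
# 0 collinear.
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_segment <- function(ax, ay, bx, by, px, py, eps = 1e-12) {
  abs(.orient(ax, ay, bx, by, px, py)) <= eps &
    px >= pmin(ax, bx) - eps & px <= pmax(ax, bx) + eps &
    py >= pmin(ay, by) - eps & py <= pmax(ay, by) + eps
}

.segments_cross <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- .orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- .orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- .orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  if (d1 == 0 && .on_segment(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) return(TRUE)
  if (d2 == 0 && .on_segment(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) return(TRUE)
  if (d3 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) return(TRUE)
  if (d4 == 0 && .on_segment(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])) return(TRUE)
  FALSE
}

# TRUE iff the polygon (vertex matrix, implicitly closed) has no two
# non-adjacent edges that intersect.
polygon_is_simple <- function(poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  idx <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      # skip adjacent edges (they share a vertex)
      if (b == a + 1 || (a == 1 && b == n)) next
      if (.segments_cross(poly[idx[a, 1], ], poly[idx[a, 2], ],
                          poly[idx[b, 1], ], poly[idx[b, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# Even-odd (ray casting) point-in-polygon test; points exactly on the
# boundary count as inside. Vectorized over points.
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- c(xs[-1], xs[1]); ye <- c(ys[-1], ys[1])
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (e in seq_len(n)) {
    on_edge <- on_edge |
      .on_segment(xs[e], ys[e], xe[e], ye[e], px, py)
    crosses <- ((ys[e] > py) != (ye[e] > py)) &
      (px < (xe[e] - xs[e]) * (py - ys[e]) / (ye[e] - ys[e]) + xs[e])
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}
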