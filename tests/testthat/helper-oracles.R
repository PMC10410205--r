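# Independent oracles and fixture builders. Everything here is written
# from first principles (or delegates to an unrelated library), never by
# calling the implementation under test.

# --- fixture builders -------------------------------------------------

square_poly <- function(x0 = 0, y0 = 0, side = 1) {
  cbind(c(x0, x0 + side, x0 + side, x0),
        c(y0, y0, y0 + side, y0 + side))
}

random_triangle <- function(scale = 1, shift = c(0, 0)) {
  repeat {
    p <- matrix(runif(6, -scale, scale), 3, 2)
    a <- abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
               (p[2, 2] - p[1, 2]) * (p[3, 1] - p[1, 1])) / 2
    if (a > 0.05 * scale^2) break
  }
  sweep(p, 2, shift, "+")
}

# convex polygon: random points -> convex hull (>= 3 vertices)
random_convex <- function(n = 8, scale = 1, shift = c(0, 0)) {
  repeat {
    p <- matrix(runif(2 * n, -scale, scale), n, 2)
    h <- p[chull(p), , drop = FALSE]
    if (nrow(h) >= 3) return(sweep(h, 2, shift, "+"))
  }
}

make_site <- function(polys, site_id = "t", species = "grey",
                      window = NULL, crs = "EPSG:28992") {
  anns <- lapply(seq_along(polys), function(i)
    seal_annotation(sprintf("%s_%03d", site_id, i), site_id,
                    if (length(species) > 1) species[i] else species,
                    polys[[i]]))
  haulout_site(site_id, anns, window = window, crs = crs)
}

# --- geometry oracles -------------------------------------------------

# point-to-segment distance, re-derived
o_pt_seg <- function(p, a, b) {
  v <- b - a
  L2 <- sum(v^2)
  t <- if (L2 == 0) 0 else max(0, min(1, sum((p - a) * v) / L2))
  sqrt(sum((p - (a + t * v))^2))
}

o_segs_cross <- function(a, b, c, d) {
  o <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  o(a, b, c) * o(a, b, d) < 0 && o(c, d, a) * o(c, d, b) < 0
}

o_seg_seg <- function(a, b, c, d) {
  if (o_segs_cross(a, b, c, d)) return(0)
  min(o_pt_seg(a, c, d), o_pt_seg(b, c, d),
      o_pt_seg(c, a, b), o_pt_seg(d, a, b))
}

# boundary distance: double loop over all segment pairs
o_boundary_dist <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  best <- Inf
  for (i in seq_len(na)) {
    a1 <- A[i, ]; a2 <- A[i %% na + 1, ]
    for (j in seq_len(nb)) {
      d <- o_seg_seg(a1, a2, B[j, ], B[j %% nb + 1, ])
      if (d < best) best <- d
    }
  }
  best
}

# containment via an unrelated implementation (sp)
o_inside <- function(p, P) {
  sp::point.in.polygon(p[1], p[2], P[, 1], P[, 2]) == 1
}

o_edge_distance <- function(A, B) {
  d <- o_boundary_dist(A, B)
  if (d > 0 && (o_inside(A[1, ], B) || o_inside(B[1, ], A))) return(0)
  d
}

# dense boundary sampling at `spacing` metres
o_sample_boundary <- function(P, spacing = 0.001) {
  n <- nrow(P)
  pts <- list()
  for (i in seq_len(n)) {
    a <- P[i, ]; b <- P[i %% n + 1, ]
    L <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(L / spacing)))
    pts[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, pts)
}

o_sampled_distance <- function(A, B, spacing = 0.001) {
  pa <- o_sample_boundary(A, spacing)
  pb <- o_sample_boundary(B, spacing)
  best <- Inf
  for (k in seq_len(nrow(pa))) {
    d2 <- min((pb[, 1] - pa[k, 1])^2 + (pb[, 2] - pa[k, 2])^2)
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

o_shoelace_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  i2 <- c(seq_len(nrow(P))[-1], 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

o_shoelace_centroid <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  i2 <- c(seq_len(nrow(P))[-1], 1)
  cr <- x * y[i2] - x[i2] * y
  c(sum((x + x[i2]) * cr), sum((y + y[i2]) * cr)) / (6 * o_shoelace_area(P))
}

o_perimeter <- function(P) {
  i2 <- c(seq_len(nrow(P))[-1], 1)
  sum(sqrt((P[i2, 1] - P[, 1])^2 + (P[i2, 2] - P[, 2])^2))
}

# Sutherland-Hodgman clip of polygon S by CONVEX clip polygon C
o_convex_clip <- function(S, C) {
  if (o_shoelace_area(C) < 0) C <- C[rev(seq_len(nrow(C))), ]
  out <- S
  nc <- nrow(C)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(NULL)
    a <- C[i, ]; b <- C[i %% nc + 1, ]
    inside <- function(p)
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= 0
    isect <- function(p, q) {
      dc <- a - b; dp <- p - q
      n1 <- a[1] * b[2] - a[2] * b[1]
      n2 <- p[1] * q[2] - p[2] * q[1]
      den <- dc[1] * dp[2] - dc[2] * dp[1]
      c(n1 * dp[1] - n2 * dc[1], n1 * dp[2] - n2 * dc[2]) / den
    }
    nw <- list()
    m <- nrow(out)
    for (k in seq_len(m)) {
      p <- out[k, ]; q <- out[k %% m + 1, ]
      if (inside(p)) {
        nw[[length(nw) + 1]] <- p
        if (!inside(q)) nw[[length(nw) + 1]] <- isect(p, q)
      } else if (inside(q)) nw[[length(nw) + 1]] <- isect(p, q)
    }
    out <- if (length(nw)) do.call(rbind, nw) else NULL
  }
  out
}

o_convex_intersection_area <- function(A, B) {
  clip <- o_convex_clip(A, B)
  if (is.null(clip) || nrow(clip) < 3) return(0)
  abs(o_shoelace_area(clip))
}

# --- misc -------------------------------------------------------------

no_pair_overlaps <- function(polys, tol = 1e-9) {
  n <- length(polys)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (overlaps(polys[[i]], polys[[j]], tol = tol)) return(FALSE)
  TRUE
}

unit_window <- function(side)
  cbind(c(0, side, side, 0), c(0, 0, side, side))
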