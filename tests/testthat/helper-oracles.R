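# Independent brute-force oracles for the Voronoi metrics, built from
# first principles (half-plane intersection, exhaustive search) and shared
# by the unit and acceptance tests. Deliberately no code shared with the
# package's Delaunay-based implementation.

# Sutherland-Hodgman clip of a convex polygon by the half-plane of points
# closer to p than to q.
clip_halfplane <- function(poly, p, q) {
  m <- (p + q) / 2
  u <- q - p
  s <- (poly[, 1] - m[1]) * u[1] + (poly[, 2] - m[2]) * u[2]
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    a <- poly[k, ]; b <- poly[k2, ]
    sa <- s[k]; sb <- s[k2]
    if (sa <= 0) {
      out <- rbind(out, a)
      if (sb > 0) out <- rbind(out, a + (sa / (sa - sb)) * (b - a))
    } else if (sb <= 0) {
      out <- rbind(out, a + (sa / (sa - sb)) * (b - a))
    }
  }
  out
}

# Voronoi cells by direct half-plane intersection against every other
# point, starting from a huge bounding box. A cell is infinite iff it
# retains a vertex on that box.
oracle_voronoi <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  rx <- range(xy[, 1]); ry <- range(xy[, 2])
  big <- 20 * max(diff(rx), diff(ry), 1)
  box <- rbind(c(rx[1] - big, ry[1] - big), c(rx[2] + big, ry[1] - big),
               c(rx[2] + big, ry[2] + big), c(rx[1] - big, ry[2] + big))
  lapply(seq_len(n), function(i) {
    poly <- box
    for (j in seq_len(n)[-i]) {
      if (nrow(poly) == 0L) break
      poly <- clip_halfplane(poly, xy[i, ], xy[j, ])
    }
    on_box <- nrow(poly) > 0L &&
      any(abs(poly[, 1] - (rx[1] - big)) < 1e-6 |
          abs(poly[, 1] - (rx[2] + big)) < 1e-6 |
          abs(poly[, 2] - (ry[1] - big)) < 1e-6 |
          abs(poly[, 2] - (ry[2] + big)) < 1e-6)
    list(poly = poly, finite = !on_box)
  })
}

oracle_polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Voronoi adjacency read off the clipped cell: each polygon edge of
# positive length lies on the bisector between the generator and exactly
# one other point -- the non-generator point nearest the edge midpoint.
oracle_neighbors <- function(xy, i, poly) {
  n <- nrow(poly)
  nbr <- integer(0)
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    if (sqrt(sum((poly[k, ] - poly[k2, ])^2)) < 1e-9) next
    mp <- (poly[k, ] + poly[k2, ]) / 2
    d <- sqrt((xy[, 1] - mp[1])^2 + (xy[, 2] - mp[2])^2)
    di <- d[i]
    d[i] <- Inf
    j <- which.min(d)
    if (abs(d[j] - di) < 1e-7 * max(1, di)) nbr <- c(nbr, j)
  }
  sort(unique(nbr))
}

# All three metrics from the oracle tessellation: bound-cell flags, bound
# density, exhaustive-search mean NND and adjacency-based mean ICD.
oracle_metrics <- function(xy, r) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  cells <- oracle_voronoi(xy)
  x0 <- r$origin[1]; y0 <- r$origin[2]
  x1 <- x0 + r$size[1]; y1 <- y0 + r$size[2]
  in_roi_poly <- function(v) {
    all(v[, 1] >= x0 & v[, 1] <= x1 & v[, 2] >= y0 & v[, 2] <= y1)
  }
  bound <- vapply(seq_len(n), function(i) {
    cells[[i]]$finite && nrow(cells[[i]]$poly) >= 3L &&
      in_roi_poly(cells[[i]]$poly)
  }, logical(1))
  areas <- rep(NA_real_, n)
  for (i in which(bound)) areas[i] <- oracle_polygon_area(cells[[i]]$poly)

  inside <- xy[, 1] >= x0 & xy[, 1] <= x1 & xy[, 2] >= y0 & xy[, 2] <= y1
  nnd <- vapply(which(inside), function(i) {
    min(sqrt((xy[-i, 1] - xy[i, 1])^2 + (xy[-i, 2] - xy[i, 2])^2))
  }, numeric(1))

  icd <- vapply(which(bound), function(i) {
    nb <- oracle_neighbors(xy, i, cells[[i]]$poly)
    mean(sqrt((xy[nb, 1] - xy[i, 1])^2 + (xy[nb, 2] - xy[i, 2])^2))
  }, numeric(1))

  list(bound = bound,
       density = sum(bound) / sum(areas[bound]) * 1e6,
       areas = areas,
       nnd_mean = mean(nnd),
       icd_mean = mean(icd))
}
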