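#' Region of interest on the retina
#'
#' An axis-aligned rectangular region in the image plane, in um, with
#' optional retinal-location metadata. The default size is the 200 x 200 um
#' (0.04 mm^2) sampling window used for parafoveal cone metrics.
#'
#' @param origin Numeric length 2, (x, y) of the top-left corner in um
#'   (y-down image frame).
#' @param size Numeric length 2, (width, height) in um. Default c(200, 200).
#' @param eccentricity_deg Retinal eccentricity of the ROI center, degrees.
#' @param meridian Retinal meridian label, "superior" or "temporal".
#' @return An object of class `roi`.
#' @export
roi <- function(origin = c(0, 0), size = c(200, 200),
                eccentricity_deg = NA_real_, meridian = NA_character_) {
  stopifnot(length(origin) == 2L, length(size) == 2L)
  check_positive(size, "size")
  if (!is.na(meridian) && !meridian %in% c("superior", "temporal")) {
    stop("meridian must be 'superior' or 'temporal'", call. = FALSE)
  }
  structure(list(origin = as.numeric(origin), size = as.numeric(size),
                 eccentricity_deg = eccentricity_deg, meridian = meridian),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("ROI %g x %g um at (%g, %g)", x$size[1], x$size[2],
              x$origin[1], x$origin[2]))
  if (!is.na(x$eccentricity_deg)) {
    cat(sprintf(" [%s, %.1f deg]", x$meridian, x$eccentricity_deg))
  }
  cat("\n")
  invisible(x)
}

# Closed containment: a point exactly on the ROI edge counts as inside.
roi_contains <- function(r, xy) {
  xy <- as_xy(xy)
  xy[, 1] >= r$origin[1] & xy[, 1] <= r$origin[1] + r$size[1] &
    xy[, 2] >= r$origin[2] & xy[, 2] <= r$origin[2] + r$size[2]
}

# Deterministic symmetry-breaking jitter. Exactly cocircular configurations
# (hexagonal and square lattices) make Delaunay adjacency ambiguous; a fixed
# 1e-9 um perturbation from a dedicated RNG stream resolves ties
# reproducibly without measurably moving any metric.
perturb_coords <- function(xy, eps = 1e-9) {
  n <- nrow(xy)
  xy + with_seed(181402L, matrix(runif(2L * n, -eps, eps), n, 2L))
}

# Delaunay tessellation plus the derived quantities every metric needs:
# triangle circumcenters (= Voronoi vertices), point->triangle incidence,
# convex-hull membership (hull points have unbounded Voronoi cells) and
# Delaunay adjacency lists.
tessellate <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) stop("undefined metric: need at least 3 points", call. = FALSE)
  p <- perturb_coords(xy)
  tri <- .delaunay_cpp(p[, 1], p[, 2])
  m <- nrow(tri)

  ax <- p[tri[, 1], 1]; ay <- p[tri[, 1], 2]
  bx <- p[tri[, 2], 1]; by <- p[tri[, 2], 2]
  cx <- p[tri[, 3], 1]; cy <- p[tri[, 3], 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ccx <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  ccy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d

  pt_tris <- split(rep(seq_len(m), 3L),
                   factor(as.vector(tri), levels = seq_len(n)))

  e1 <- pmin(c(tri[, 1], tri[, 2], tri[, 3]), c(tri[, 2], tri[, 3], tri[, 1]))
  e2 <- pmax(c(tri[, 1], tri[, 2], tri[, 3]), c(tri[, 2], tri[, 3], tri[, 1]))
  key <- e1 * (n + 1) + e2
  shared <- duplicated(key) | duplicated(key, fromLast = TRUE)
  on_hull <- rep(FALSE, n)
  on_hull[unique(c(e1[!shared], e2[!shared]))] <- TRUE

  first <- !duplicated(key)
  u1 <- e1[first]; u2 <- e2[first]
  nbrs <- split(c(u2, u1), factor(c(u1, u2), levels = seq_len(n)))

  list(xy = p, n = n, tri = tri, cc = cbind(ccx, ccy),
       pt_tris = pt_tris, on_hull = on_hull, nbrs = nbrs)
}

# Voronoi cell of an interior point: circumcenters of its incident
# triangles, ordered by angle about the generating point (the generator
# always lies inside its own convex cell, so angular order is valid).
voronoi_cell <- function(tess, i) {
  v <- tess$cc[tess$pt_tris[[i]], , drop = FALSE]
  o <- order(atan2(v[, 2] - tess$xy[i, 2], v[, 1] - tess$xy[i, 1]))
  v[o, , drop = FALSE]
}

polygon_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Bound-cell classification: a cell is bound iff it is finite (its point is
# not on the convex hull) and its polygon lies entirely inside the ROI
# (all vertices inside; cells are convex). Returns per-point flags and
# areas (um^2, NA for unbound cells). Containment is tested once per
# Voronoi vertex (triangle circumcenter) rather than per cell.
bound_cells <- function(tess, r) {
  n <- tess$n
  cc_in <- roi_contains(r, tess$cc)
  bound <- !tess$on_hull &
    unname(vapply(tess$pt_tris, function(t) length(t) > 0L && all(cc_in[t]),
                  logical(1)))
  area <- rep(NA_real_, n)
  for (i in which(bound)) area[i] <- polygon_area(voronoi_cell(tess, i))
  list(bound = bound, area = area)
}

#' Bound Voronoi cone density
#'
#' Tessellates the full coordinate set (points outside the ROI are used to
#' close the cells of points near the edge), classifies each Voronoi cell
#' as *bound* when it is finite and lies entirely inside the ROI, and
#' returns the number of bound cells divided by their summed area. On a
#' jitter-free hexagonal lattice of spacing `s` um this equals
#' `2 / (sqrt(3) * s^2)` cones per um^2 exactly, reported per mm^2.
#'
#' @param coords Cone coordinates in um: a 2-column matrix or a data frame
#'   with `x_um`, `y_um`. May (and for edge cells should) extend beyond the
#'   ROI.
#' @param r An [roi()].
#' @return List with `density` (cones/mm^2) and `n_bound` (number of bound
#'   cells).
#' @export
#' @examples
#' mos <- generate_mosaic(11547, field_size = c(300, 300), seed = 1)
#' voronoi_bound_density(mos$points, roi(origin = c(50, 50)))
voronoi_bound_density <- function(coords, r) {
  xy <- as_xy(coords)
  if (sum(roi_contains(r, xy)) < 3L) {
    stop("undefined metric: fewer than 3 points inside the ROI", call. = FALSE)
  }
  tess <- tessellate(xy)
  bc <- bound_cells(tess, r)
  nb <- sum(bc$bound)
  if (nb == 0L) {
    stop("undefined metric: no Voronoi cell is bound inside the ROI",
         call. = FALSE)
  }
  list(density = nb / sum(bc$area[bc$bound]) * 1e6, n_bound = nb)
}

#' Mean nearest-neighbor distance (NND)
#'
#' For every point inside the ROI, the distance to the closest other point
#' (neighbor candidates include points outside the ROI); returns the mean.
#'
#' @inheritParams voronoi_bound_density
#' @return Mean NND in um.
#' @export
nnd_mean <- function(coords, r) {
  xy <- as_xy(coords)
  if (nrow(xy) < 2L) stop("undefined metric: need at least 2 points", call. = FALSE)
  inside <- roi_contains(r, xy)
  if (!any(inside)) stop("undefined metric: no points inside the ROI", call. = FALSE)
  dm <- as.matrix(dist(xy))
  diag(dm) <- Inf
  nn <- apply(dm[inside, , drop = FALSE], 1L, min)
  mean(nn)
}

#' Mean intercell distance (ICD)
#'
#' For every point whose Voronoi cell is bound inside the ROI, the mean
#' distance to its Voronoi (Delaunay) neighbors; returns the mean over
#' those points. Neighbors may lie outside the ROI.
#'
#' @inheritParams voronoi_bound_density
#' @return Mean ICD in um.
#' @export
icd_mean <- function(coords, r) {
  xy <- as_xy(coords)
  if (sum(roi_contains(r, xy)) < 3L) {
    stop("undefined metric: fewer than 3 points inside the ROI", call. = FALSE)
  }
  tess <- tessellate(xy)
  bc <- bound_cells(tess, r)
  if (!any(bc$bound)) {
    stop("undefined metric: no Voronoi cell is bound inside the ROI",
         call. = FALSE)
  }
  icd_i <- vapply(which(bc$bound), function(i) {
    nb <- tess$nbrs[[i]]
    mean(sqrt((tess$xy[nb, 1] - tess$xy[i, 1])^2 +
              (tess$xy[nb, 2] - tess$xy[i, 2])^2))
  }, numeric(1))
  mean(icd_i)
}

#' All mosaic metrics for one ROI
#'
#' Computes bound Voronoi density, mean NND and mean ICD from one
#' tessellation, with bookkeeping labels, as one `metric_set`.
#'
#' @inheritParams voronoi_bound_density
#' @param grader,modality,roi_id Labels carried into the result.
#' @return A `metric_set`: list with `bound_density` (cones/mm^2),
#'   `nnd_mean` and `icd_mean` (um), `n_cones_total` (points inside the
#'   ROI), `n_cones_bound`, labels and the ROI.
#' @export
mosaic_metrics <- function(coords, r, grader = NA_character_,
                           modality = NA_character_, roi_id = NA_character_) {
  xy <- as_xy(coords)
  inside <- roi_contains(r, xy)
  if (sum(inside) < 3L) {
    stop("undefined metric: fewer than 3 points inside the ROI", call. = FALSE)
  }
  tess <- tessellate(xy)
  bc <- bound_cells(tess, r)
  nb <- sum(bc$bound)
  if (nb == 0L) {
    stop("undefined metric: no Voronoi cell is bound inside the ROI",
         call. = FALSE)
  }
  dm <- as.matrix(dist(xy))
  diag(dm) <- Inf
  nnd <- mean(apply(dm[inside, , drop = FALSE], 1L, min))
  icd_i <- vapply(which(bc$bound), function(i) {
    nb_i <- tess$nbrs[[i]]
    mean(dm[i, nb_i])
  }, numeric(1))
  structure(list(bound_density = nb / sum(bc$area[bc$bound]) * 1e6,
                 nnd_mean = nnd, icd_mean = mean(icd_i),
                 n_cones_total = sum(inside), n_cones_bound = nb,
                 grader = grader, modality = modality, roi_id = roi_id,
                 roi = r),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("mosaic metrics [%s/%s/%s]\n", x$roi_id, x$modality, x$grader))
  cat(sprintf("  bound density: %0.0f cones/mm^2 (%d bound / %d in ROI)\n",
              x$bound_density, x$n_cones_bound, x$n_cones_total))
  cat(sprintf("  NND %.2f um, ICD %.2f um\n", x$nnd_mean, x$icd_mean))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  data.frame(roi_id = x$roi_id, modality = x$modality, grader = x$grader,
             bound_density = x$bound_density, nnd_um = x$nnd_mean,
             icd_um = x$icd_mean, n_bound = x$n_cones_bound,
             n_total = x$n_cones_total, stringsAsFactors = FALSE)
}

#' Hexagonal-equivalent spacing for a density
#'
#' Converts a cone density in cones/mm^2 to the spacing of the hexagonal
#' lattice with that density, `s = 1000 * sqrt(2 / (sqrt(3) * d))` um, and
#' back. The two functions are exact inverses.
#'
#' @param d Density in cones/mm^2.
#' @return Spacing in um.
#' @export
#' @examples
#' density_to_spacing(11547)   # 10 um
#' spacing_to_density(10)      # 11547 cones/mm^2
density_to_spacing <- function(d) {
  check_positive(d, "d")
  1000 * sqrt(2 / (sqrt(3) * d))
}

#' @rdname density_to_spacing
#' @param s Spacing in um.
#' @export
spacing_to_density <- function(s) {
  check_positive(s, "s")
  2 / (sqrt(3) * (s / 1000)^2)
}

#' Affine transform between two modalities' image frames
#'
#' A 2 x 3 matrix `[A | b]` mapping um coordinates of one modality's image
#' into the other's. The linear part must be invertible and near-rigid
#' (determinant in [0.8, 1.25], i.e. scale agreement within ~ +/-12% per
#' axis), as expected for coarse alignment of co-localized retinal images.
#'
#' @param m Numeric 2 x 3 matrix.
#' @return An object of class `roi_transform`.
#' @export
roi_transform <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(2L, 3L))) stop("transform must be 2 x 3", call. = FALSE)
  dt <- m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1]
  if (!is.finite(dt) || abs(dt) < 1e-12) {
    stop("transform is not invertible", call. = FALSE)
  }
  if (dt < 0.8 || dt > 1.25) {
    warning(sprintf("transform is not near-rigid (determinant %.3f)", dt))
  }
  structure(list(m = unname(m), det = dt), class = "roi_transform")
}

#' Co-localize an ROI in the other modality
#'
#' Maps the ROI center through the inter-modality transform and returns an
#' axis-aligned ROI of identical physical size centered there. Any rotation
#' or scale in the transform is applied to the center only and otherwise
#' discarded (reported via a message), keeping the sampled area identical
#' across modalities.
#'
#' @param roi_src An [roi()] in the source modality.
#' @param t An [roi_transform()].
#' @return An [roi()] in the target modality.
#' @export
colocalize_roi <- function(roi_src, t) {
  stopifnot(inherits(roi_src, "roi"), inherits(t, "roi_transform"))
  ctr <- roi_src$origin + roi_src$size / 2
  a <- t$m[, 1:2]
  ctr2 <- as.numeric(a %*% ctr + t$m[, 3])
  rot <- atan2(a[2, 1], a[1, 1]) * 180 / pi
  if (abs(rot) > 1e-9 || abs(t$det - 1) > 1e-9) {
    message(sprintf(
      "colocalize_roi: rotation %.3f deg and scale det %.4f applied to center only",
      rot, t$det))
  }
  roi(origin = ctr2 - roi_src$size / 2, size = roi_src$size,
      eccentricity_deg = roi_src$eccentricity_deg,
      meridian = roi_src$meridian)
}
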