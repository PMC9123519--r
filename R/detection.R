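#' Image patch with physical scale
#'
#' @param pixels Numeric matrix, `[row = y, col = x]`, y-down.
#' @param scale_um_per_px Linear scale in um/pixel.
#' @param provenance Optional list of processing metadata.
#' @return An object of class `image_patch`.
#' @export
image_patch <- function(pixels, scale_um_per_px, provenance = list()) {
  pixels <- as.matrix(pixels)
  check_positive(scale_um_per_px, "scale_um_per_px")
  structure(list(pixels = pixels, scale_um_per_px = scale_um_per_px,
                 provenance = provenance), class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  cat(sprintf("image patch: %d x %d px at %.3f um/px\n",
              nrow(x$pixels), ncol(x$pixels), x$scale_um_per_px))
  invisible(x)
}

#' Cone detection configuration
#'
#' @param lowpass_sigma SD of the smaller difference-of-Gaussians kernel,
#'   um; should be on the order of the optical spot size.
#' @param min_separation Minimum distance between detected cones, um;
#'   closer candidates are suppressed (brighter wins).
#' @param threshold_quantile Candidate maxima must exceed this quantile of
#'   the filtered image, strictly; in (0, 1).
#' @param roi_margin Margin in um kept around an analysis ROI when cropping
#'   coordinates, so that edge Voronoi cells can be closed.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(lowpass_sigma = 1.2, min_separation = 4,
                             threshold_quantile = 0.8, roi_margin = 15) {
  check_positive(lowpass_sigma, "lowpass_sigma")
  check_positive(min_separation, "min_separation")
  if (!(threshold_quantile > 0 && threshold_quantile < 1)) {
    stop("'threshold_quantile' must be in (0, 1)", call. = FALSE)
  }
  stopifnot(roi_margin >= 0)
  structure(list(lowpass_sigma = lowpass_sigma,
                 min_separation = min_separation,
                 threshold_quantile = threshold_quantile,
                 roi_margin = roi_margin), class = "detection_config")
}

#' Manual edits to an automatic detection
#'
#' The semi-automatic workflow: removals are matched to the nearest
#' automatic detection within `match_radius` and deleted, then additions
#' are appended verbatim.
#'
#' @param additions Coordinates (um) to add; matrix/data frame or NULL.
#' @param removals Coordinates (um) to remove; matrix/data frame or NULL.
#' @param match_radius Match radius for removals, um.
#' @return An object of class `edit_list`.
#' @export
edit_list <- function(additions = NULL, removals = NULL, match_radius = 2) {
  check_positive(match_radius, "match_radius")
  structure(list(additions = if (is.null(additions)) NULL else as_xy(additions),
                 removals = if (is.null(removals)) NULL else as_xy(removals),
                 match_radius = match_radius), class = "edit_list")
}

# translate matrix content by (dy, dx) integer pixels, filling vacated
# pixels with the matrix median (registration shifts are small relative to
# the frame, so edge fill does not reach analysis ROIs)
shift_matrix <- function(m, dy, dx, fill = median(m)) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(fill, ny, nx)
  src_i <- seq_len(ny) - dy; src_j <- seq_len(nx) - dx
  ok_i <- src_i >= 1L & src_i <= ny; ok_j <- src_j >= 1L & src_j <= nx
  out[ok_i, ok_j] <- m[src_i[ok_i], src_j[ok_j]]
  out
}

# circular index helper for FFT correlation surfaces
wrap_index <- function(i, n) ((i - 1) %% n) + 1

# quadratic (3-point parabola) sub-sample peak refinement, clamped to
# +/- 0.5; xm/x0/xp are the values at peak-1, peak, peak+1
parabolic_offset <- function(xm, x0, xp) {
  den <- xm - 2 * x0 + xp
  if (!is.finite(den) || den >= 0) return(0)
  max(-0.5, min(0.5, 0.5 * (xm - xp) / den))
}

# FFT cross-correlation of two equal-size frames (mean-removed); returns
# the translation (dy, dx) in pixels that best aligns `frame` to `ref`,
# with quadratic subpixel refinement, plus a border flag for implausibly
# large shifts (correlation peak in the wrap-around zone).
xcorr_shift <- function(ref, frame) {
  a <- ref - mean(ref); b <- frame - mean(frame)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  ny <- nrow(cc); nx <- ncol(cc)
  p <- arrayInd(which.max(cc), dim(cc))
  iy <- p[1]; ix <- p[2]
  dy <- if (iy - 1 <= ny / 2) iy - 1 else iy - 1 - ny
  dx <- if (ix - 1 <= nx / 2) ix - 1 else ix - 1 - nx
  oy <- parabolic_offset(cc[wrap_index(iy - 1, ny), ix], cc[iy, ix],
                         cc[wrap_index(iy + 1, ny), ix])
  ox <- parabolic_offset(cc[iy, wrap_index(ix - 1, nx)], cc[iy, ix],
                         cc[iy, wrap_index(ix + 1, nx)])
  list(dy = dy + oy, dx = dx + ox,
       flagged = abs(dy) > ny / 4 || abs(dx) > nx / 4)
}

#' Register a frame stack by translation
#'
#' Chooses as reference the frame with the highest mean correlation to the
#' other frames, estimates each frame's translation relative to it by FFT
#' cross-correlation with quadratic subpixel interpolation, and shifts each
#' frame by the rounded estimate. A single-frame stack is returned
#' unchanged. Frames whose correlation peak lies implausibly far out
#' (beyond a quarter of the frame) are flagged in the shift log.
#'
#' @param stack A [render_frames()] stack (or compatible `frame_stack`).
#' @return The stack with aligned frames and a `registration` element: data
#'   frame `frame`, `dx_px`, `dy_px` (subpixel estimates), `applied_dx`,
#'   `applied_dy` (integer shifts), `flagged`, plus `ref_frame`.
#' @export
register_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (n == 1L) {
    stack$registration <- data.frame(frame = 1L, dx_px = 0, dy_px = 0,
                                     applied_dx = 0L, applied_dy = 0L,
                                     flagged = FALSE)
    stack$ref_frame <- 1L
    return(stack)
  }
  v <- vapply(stack$frames, as.vector, numeric(length(stack$frames[[1]])))
  cm <- cor(v)
  ref_idx <- which.max(colMeans(cm))
  ref <- stack$frames[[ref_idx]]
  reg <- data.frame(frame = seq_len(n), dx_px = 0, dy_px = 0,
                    applied_dx = 0L, applied_dy = 0L, flagged = FALSE)
  for (f in seq_len(n)) {
    if (f == ref_idx) next
    s <- xcorr_shift(ref, stack$frames[[f]])
    reg$dx_px[f] <- s$dx; reg$dy_px[f] <- s$dy; reg$flagged[f] <- s$flagged
    adx <- as.integer(round(s$dx)); ady <- as.integer(round(s$dy))
    reg$applied_dx[f] <- adx; reg$applied_dy[f] <- ady
    if (adx != 0L || ady != 0L) {
      stack$frames[[f]] <- shift_matrix(stack$frames[[f]], ady, adx)
    }
  }
  stack$registration <- reg
  stack$ref_frame <- ref_idx
  stack
}

#' Quality-select and average a registered stack
#'
#' Ranks frames by correlation to the pixelwise median image (a robust
#' template), keeps the top `keep_frac` fraction, and averages them
#' pixelwise (mean projection).
#'
#' @param stack A registered `frame_stack`.
#' @param keep_frac Fraction of frames to keep, in (0, 1]. If
#'   `keep_frac * n < 1` the single best frame is kept, with a warning.
#' @return An [image_patch()]; `provenance` records kept and excluded
#'   frame indices and their template correlations.
#' @export
select_and_average <- function(stack, keep_frac = 1) {
  stopifnot(inherits(stack, "frame_stack"))
  check_fraction(keep_frac, "keep_frac")
  n <- length(stack$frames)
  arr <- array(unlist(stack$frames), dim = c(dim(stack$frames[[1]]), n))
  med <- apply(arr, c(1, 2), median)
  r <- vapply(stack$frames, function(f) {
    if (sd(f) == 0 || sd(med) == 0) return(1)
    cor(as.vector(f), as.vector(med))
  }, numeric(1))
  n_keep <- floor(keep_frac * n)
  if (n_keep < 1L) {
    warning("keep_frac * n < 1; keeping the single best frame")
    n_keep <- 1L
  }
  kept <- order(r, decreasing = TRUE)[seq_len(n_keep)]
  avg <- apply(arr[, , kept, drop = FALSE], c(1, 2), mean)
  image_patch(avg, stack$scale_um_per_px,
              provenance = list(kept_frames = sort(kept),
                                excluded_frames = setdiff(seq_len(n), kept),
                                template_correlation = r,
                                n_averaged = n_keep))
}

#' Detect cone centers in an averaged image
#'
#' Difference-of-Gaussians band-pass filtering (SDs `lowpass_sigma` and
#' 1.6 x `lowpass_sigma`), strict local maxima above the configured
#' quantile of the filtered image (and above a fixed prominence floor of
#' 0.25 x the maximum band-pass response, which rejects background noise
#' peaks in sparse fields), greedy non-maximum suppression within
#' `min_separation` (brighter candidate wins; ties broken by lower y, then
#' lower x), quadratic subpixel refinement, then manual edits (removals
#' before additions). The quantile threshold makes detection invariant to
#' positive affine rescaling of the intensities.
#'
#' @param img An [image_patch()] with a valid scale.
#' @param cfg A [detection_config()].
#' @param edits Optional [edit_list()].
#' @return Data frame `id`, `x_um`, `y_um` of detected cone centers.
#' @export
detect_cones <- function(img, cfg = detection_config(), edits = NULL) {
  stopifnot(inherits(img, "image_patch"), inherits(cfg, "detection_config"))
  sc <- img$scale_um_per_px
  if (!is.finite(sc) || sc <= 0) stop("image patch has no valid scale", call. = FALSE)
  m <- img$pixels
  s1 <- cfg$lowpass_sigma / sc
  dog <- EBImage::gblur(m, sigma = s1) - EBImage::gblur(m, sigma = 1.6 * s1)
  # quantile threshold (intensity-affine invariant) plus a relative
  # prominence floor at a quarter of the strongest band-pass response, so
  # background noise maxima are rejected even in sparse images where the
  # quantile alone sits at the noise level
  thr <- max(quantile(dog, cfg$threshold_quantile, names = FALSE),
             0.25 * max(dog))

  ny <- nrow(dog); nx <- ncol(dog)
  core <- dog[2:(ny - 1), 2:(nx - 1)]
  is_max <- core > thr &
    core > dog[1:(ny - 2), 2:(nx - 1)] & core > dog[3:ny, 2:(nx - 1)] &
    core > dog[2:(ny - 1), 1:(nx - 2)] & core > dog[2:(ny - 1), 3:nx] &
    core > dog[1:(ny - 2), 1:(nx - 2)] & core > dog[1:(ny - 2), 3:nx] &
    core > dog[3:ny, 1:(nx - 2)] & core > dog[3:ny, 3:nx]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    pts <- matrix(numeric(0), 0, 2)
  } else {
    ri <- idx[, 1] + 1L; ci <- idx[, 2] + 1L
    val <- dog[cbind(ri, ci)]
    o <- order(-val, ri, ci)
    ri <- ri[o]; ci <- ci[o]
    min_px2 <- (cfg$min_separation / sc)^2
    keep <- logical(length(ri))
    ky <- numeric(0); kx <- numeric(0)
    for (k in seq_along(ri)) {
      if (length(ky) == 0L ||
          all((ky - ri[k])^2 + (kx - ci[k])^2 >= min_px2)) {
        keep[k] <- TRUE
        ky <- c(ky, ri[k]); kx <- c(kx, ci[k])
      }
    }
    ri <- ri[keep]; ci <- ci[keep]
    off_y <- vapply(seq_along(ri), function(k) {
      parabolic_offset(dog[ri[k] - 1L, ci[k]], dog[ri[k], ci[k]],
                       dog[ri[k] + 1L, ci[k]])
    }, numeric(1))
    off_x <- vapply(seq_along(ri), function(k) {
      parabolic_offset(dog[ri[k], ci[k] - 1L], dog[ri[k], ci[k]],
                       dog[ri[k], ci[k] + 1L])
    }, numeric(1))
    pts <- cbind((ci - 0.5 + off_x) * sc, (ri - 0.5 + off_y) * sc)
  }

  if (!is.null(edits)) {
    stopifnot(inherits(edits, "edit_list"))
    if (!is.null(edits$removals) && nrow(pts) > 0L) {
      for (k in seq_len(nrow(edits$removals))) {
        if (nrow(pts) == 0L) break
        d2 <- (pts[, 1] - edits$removals[k, 1])^2 +
          (pts[, 2] - edits$removals[k, 2])^2
        j <- which.min(d2)
        if (d2[j] <= edits$match_radius^2) pts <- pts[-j, , drop = FALSE]
      }
    }
    if (!is.null(edits$additions)) pts <- rbind(pts, edits$additions)
  }
  xy_df(pts)
}
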