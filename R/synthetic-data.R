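#' Generate a ground-truth cone mosaic
#'
#' Builds a row-offset hexagonal lattice whose spacing
#' `s = sqrt(2 / (sqrt(3) * d))` realizes the requested density, applies
#' isotropic Gaussian positional jitter, and removes cones at random
#' (dropout). Coordinates are continuous um in a y-down frame with the
#' origin at the field's top-left corner; all points lie inside the field.
#'
#' @param density Target cone density in cones/mm^2.
#' @param field_size Numeric length 2, field (width, height) in um. Each
#'   side must be at least 5 lattice spacings.
#' @param jitter_sd Positional jitter SD in um (per axis).
#' @param dropout_frac Fraction of cones removed at random, in [0, 1).
#' @param seed Integer seed; identical seed and parameters give an
#'   identical mosaic. Sub-streams for jitter and dropout are derived from
#'   it, independent of the rendering and grading streams.
#' @return An object of class `cone_mosaic`: list with `points` (data frame
#'   `id`, `x_um`, `y_um`), `density_nominal`, `spacing_um`, `jitter_sd`,
#'   `dropout_frac`, `field_size`, `seed`.
#' @export
#' @examples
#' mos <- generate_mosaic(12375, field_size = c(300, 300), jitter_sd = 1, seed = 7)
#' mos
generate_mosaic <- function(density, field_size = c(300, 300), jitter_sd = 0,
                            dropout_frac = 0, seed = 1L) {
  check_positive(density, "density")
  stopifnot(length(field_size) == 2L)
  check_positive(field_size, "field_size")
  if (jitter_sd < 0) stop("'jitter_sd' must be non-negative", call. = FALSE)
  check_fraction(dropout_frac, "dropout_frac", open_right = TRUE)

  s <- density_to_spacing(density)          # um
  if (any(field_size < 5 * s)) {
    stop(sprintf("field sides must be at least 5 lattice spacings (%.1f um)",
                 5 * s), call. = FALSE)
  }
  dy <- s * sqrt(3) / 2
  w <- field_size[1]; h <- field_size[2]
  rows <- seq_len(max(1L, floor(h / dy))) - 1L
  pts <- do.call(rbind, lapply(rows, function(j) {
    off <- (j %% 2L) * s / 2
    x <- seq(s / 2 + off, w, by = s)
    cbind(x, rep((j + 0.5) * dy, length(x)))
  }))

  pts <- with_seed(substream_seed(seed, "mosaic"), {
    if (jitter_sd > 0) {
      pts <- pts + matrix(rnorm(2L * nrow(pts), sd = jitter_sd), ncol = 2L)
    }
    if (dropout_frac > 0) {
      pts <- pts[runif(nrow(pts)) >= dropout_frac, , drop = FALSE]
    }
    pts
  })
  # jitter may push points past the field edge; clamp to keep the invariant
  pts[, 1] <- pmin(pmax(pts[, 1], 0), w)
  pts[, 2] <- pmin(pmax(pts[, 2], 0), h)

  structure(list(points = xy_df(pts), density_nominal = density,
                 spacing_um = s, jitter_sd = jitter_sd,
                 dropout_frac = dropout_frac, field_size = field_size,
                 seed = as.integer(seed)),
            class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("cone mosaic: %d cones in %g x %g um (nominal %0.0f cones/mm^2, s = %.2f um)\n",
              nrow(x$points), x$field_size[1], x$field_size[2],
              x$density_nominal, x$spacing_um))
  cat(sprintf("  jitter %.2f um, dropout %.2f, seed %d\n",
              x$jitter_sd, x$dropout_frac, x$seed))
  invisible(x)
}

#' Rendering configuration for synthetic retinal images
#'
#' Parameters of the forward image model: each cone is rendered as a
#' Gaussian spot (the effective point-spread function), with per-cone
#' per-frame multiplicative reflectance variability (the short-term
#' fluctuation of cone reflectivity across frames), rigid per-frame
#' translational eye motion, additive Gaussian sensor noise, and an
#' optional central hyperreflective artifact mimicking lens reflections.
#'
#' @param psf_sigma Gaussian spot SD in um. High-resolution (AOSLO-like)
#'   renders use ~1-1.5 um; lower-resolution (HMM-like) renders 2-3 um.
#' @param pixel_scale um per pixel.
#' @param reflectance_cv Coefficient of variation of the per-cone,
#'   per-frame reflectance multiplier (lognormal with unit median).
#' @param noise_sd Additive Gaussian noise SD, intensity units (spot peak
#'   amplitude has median 1).
#' @param artifact_on Add the central hyperreflective blob?
#' @param artifact_center (x, y) um of the blob, default field center.
#' @param artifact_radius Blob radius in um (Gaussian with SD radius/2).
#' @param artifact_amplitude Blob peak intensity.
#' @param n_frames Number of frames in the stack.
#' @param motion_sd SD of the per-frame rigid translation, um per axis.
#' @return An object of class `render_config`.
#' @export
render_config <- function(psf_sigma = 1.2, pixel_scale = 1.0,
                          reflectance_cv = 0.05, noise_sd = 0.03,
                          artifact_on = FALSE, artifact_center = NULL,
                          artifact_radius = 30, artifact_amplitude = 0.6,
                          n_frames = 15L, motion_sd = 0.6) {
  check_positive(psf_sigma, "psf_sigma")
  check_positive(pixel_scale, "pixel_scale")
  stopifnot(reflectance_cv >= 0, noise_sd >= 0, motion_sd >= 0, n_frames >= 1)
  structure(list(psf_sigma = psf_sigma, pixel_scale = pixel_scale,
                 reflectance_cv = reflectance_cv, noise_sd = noise_sd,
                 artifact_on = isTRUE(artifact_on),
                 artifact_center = artifact_center,
                 artifact_radius = artifact_radius,
                 artifact_amplitude = artifact_amplitude,
                 n_frames = as.integer(n_frames), motion_sd = motion_sd),
            class = "render_config")
}

#' Render a mosaic as a frame stack
#'
#' Applies the forward model of [render_config()] to a mosaic. Pixel
#' (1, 1) has its center at (0.5, 0.5) * `pixel_scale` um; frames are
#' matrices indexed `[row = y, col = x]` and share one scale.
#'
#' @param mosaic A [generate_mosaic()] result.
#' @param cfg A [render_config()].
#' @param seed Integer seed for the render stream; defaults to a sub-stream
#'   derived from the mosaic's seed.
#' @return An object of class `frame_stack`: list with `frames` (list of
#'   matrices), `scale_um_per_px`, `n_frames`, `motion_log` (data frame of
#'   per-frame true shifts in um), `field_size`, `config`, `seed`.
#' @export
render_frames <- function(mosaic, cfg = render_config(), seed = NULL) {
  stopifnot(inherits(mosaic, "cone_mosaic"), inherits(cfg, "render_config"))
  if (nrow(mosaic$points) == 0L) stop("mosaic has no cones", call. = FALSE)
  if (is.null(seed)) seed <- substream_seed(mosaic$seed, "render")
  if (cfg$pixel_scale >= 2 * cfg$psf_sigma) {
    warning("undersampled render: pixel_scale >= 2 * psf_sigma")
  }
  w <- mosaic$field_size[1]; h <- mosaic$field_size[2]
  sc <- cfg$pixel_scale
  nx <- max(1L, round(w / sc)); ny <- max(1L, round(h / sc))
  xc <- (seq_len(nx) - 0.5) * sc
  yc <- (seq_len(ny) - 0.5) * sc
  xy <- as_xy(mosaic$points)
  ncone <- nrow(xy)
  sig <- cfg$psf_sigma
  win <- ceiling(4 * sig / sc)

  artifact <- NULL
  if (cfg$artifact_on) {
    ctr <- if (is.null(cfg$artifact_center)) c(w, h) / 2 else cfg$artifact_center
    sa <- cfg$artifact_radius / 2
    ax <- exp(-(xc - ctr[1])^2 / (2 * sa^2))
    ay <- exp(-(yc - ctr[2])^2 / (2 * sa^2))
    artifact <- cfg$artifact_amplitude * outer(ay, ax)
  }

  with_seed(seed, {
    shifts <- matrix(rnorm(2L * cfg$n_frames, sd = cfg$motion_sd),
                     ncol = 2L)
    sdlog <- sqrt(log(1 + cfg$reflectance_cv^2))
    mult <- if (cfg$reflectance_cv > 0) {
      matrix(rlnorm(ncone * cfg$n_frames, meanlog = 0, sdlog = sdlog),
             nrow = ncone)
    } else {
      matrix(1, nrow = ncone, ncol = cfg$n_frames)
    }
    frames <- vector("list", cfg$n_frames)
    for (f in seq_len(cfg$n_frames)) {
      img <- matrix(0, ny, nx)
      cx <- xy[, 1] + shifts[f, 1]
      cy <- xy[, 2] + shifts[f, 2]
      jc <- round(cx / sc + 0.5); ic <- round(cy / sc + 0.5)
      for (k in seq_len(ncone)) {
        j0 <- max(1L, jc[k] - win); j1 <- min(nx, jc[k] + win)
        i0 <- max(1L, ic[k] - win); i1 <- min(ny, ic[k] + win)
        if (j0 > j1 || i0 > i1) next
        gx <- exp(-(xc[j0:j1] - cx[k])^2 / (2 * sig^2))
        gy <- exp(-(yc[i0:i1] - cy[k])^2 / (2 * sig^2))
        img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + mult[k, f] * outer(gy, gx)
      }
      if (!is.null(artifact)) img <- img + artifact
      if (cfg$noise_sd > 0) img <- img + matrix(rnorm(ny * nx, sd = cfg$noise_sd), ny, nx)
      frames[[f]] <- img
    }
    structure(list(frames = frames, scale_um_per_px = sc,
                   n_frames = cfg$n_frames,
                   motion_log = data.frame(frame = seq_len(cfg$n_frames),
                                           dx_um = shifts[, 1],
                                           dy_um = shifts[, 2]),
                   field_size = mosaic$field_size, config = cfg,
                   seed = as.integer(seed)),
              class = "frame_stack")
  })
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("frame stack: %d frames of %d x %d px at %.3f um/px\n",
              x$n_frames, d[1], d[2], x$scale_um_per_px))
  invisible(x)
}

#' Grader behavior model
#'
#' Simulates a human grader marking cone centers: retained marks are
#' jittered isotropically, a fraction of cones is missed, and spurious
#' marks are added uniformly at a fixed rate. With all parameters zero the
#' grader is the identity.
#'
#' @param jitter_sd Marking jitter SD in um per axis.
#' @param miss_rate Probability of missing a cone, in [0, 1].
#' @param false_rate Spurious marks per mm^2 (Poisson).
#' @param seed Integer seed for the grading stream.
#' @return An object of class `grader_model`.
#' @export
grader_model <- function(jitter_sd = 0, miss_rate = 0, false_rate = 0,
                         seed = 1L) {
  stopifnot(jitter_sd >= 0, false_rate >= 0)
  check_fraction(miss_rate, "miss_rate")
  structure(list(jitter_sd = jitter_sd, miss_rate = miss_rate,
                 false_rate = false_rate, seed = as.integer(seed)),
            class = "grader_model")
}

#' Simulate a grader's cone annotations
#'
#' @param coords True cone coordinates (matrix or data frame, um).
#' @param model A [grader_model()].
#' @param field_size (width, height) um over which spurious marks are
#'   placed; defaults to the coordinate bounding box.
#' @return Data frame `id`, `x_um`, `y_um` of simulated marks. With an
#'   all-zero model the input coordinates are returned unchanged.
#' @export
simulate_grader <- function(coords, model = grader_model(),
                            field_size = NULL) {
  stopifnot(inherits(model, "grader_model"))
  xy <- as_xy(coords)
  if (model$jitter_sd == 0 && model$miss_rate == 0 && model$false_rate == 0) {
    return(xy_df(xy))
  }
  if (is.null(field_size)) {
    field_size <- c(max(xy[, 1]) - min(xy[, 1]), max(xy[, 2]) - min(xy[, 2]))
    field_origin <- c(min(xy[, 1]), min(xy[, 2]))
  } else {
    field_origin <- c(0, 0)
  }
  with_seed(substream_seed(model$seed, "grader"), {
    keep <- runif(nrow(xy)) >= model$miss_rate
    kept <- xy[keep, , drop = FALSE]
    if (model$jitter_sd > 0 && nrow(kept) > 0L) {
      kept <- kept + matrix(rnorm(2L * nrow(kept), sd = model$jitter_sd),
                            ncol = 2L)
    }
    if (model$false_rate > 0) {
      area_mm2 <- prod(field_size) / 1e6
      nf <- rpois(1L, model$false_rate * area_mm2)
      if (nf > 0L) {
        fp <- cbind(field_origin[1] + runif(nf) * field_size[1],
                    field_origin[2] + runif(nf) * field_size[2])
        kept <- rbind(kept, fp)
      }
    }
    xy_df(kept)
  })
}
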