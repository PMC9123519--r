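# Internal helpers: seeded sub-streams and light argument checking.

# One user-facing integer seed drives independent, label-keyed RNG streams
# (mosaic generation, rendering, grading, study stages) so that changing one
# stage's draws never perturbs another's. Plain polynomial hash mod 2^31 - 1;
# all arithmetic stays below 2^53 so doubles are exact.
substream_seed <- function(seed, label) {
  m <- 2147483647
  r <- as.numeric(seed) %% m
  for (ch in utf8ToInt(as.character(label))) r <- (r * 31 + ch) %% m
  as.integer(max(1, r))
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}

check_fraction <- function(x, name, open_right = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 &&
    (if (open_right) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be in [0, %s]", name,
                        if (open_right) "1)" else "1]"), call. = FALSE)
  invisible(x)
}

# Accept a 2-column matrix or a data frame with x_um / y_um (or x / y).
as_xy <- function(coords) {
  if (is.data.frame(coords)) {
    xn <- intersect(c("x_um", "x"), names(coords))[1]
    yn <- intersect(c("y_um", "y"), names(coords))[1]
    if (is.na(xn) || is.na(yn)) {
      stop("coordinate data frame needs columns x_um/y_um (or x/y)", call. = FALSE)
    }
    xy <- cbind(coords[[xn]], coords[[yn]])
  } else {
    xy <- as.matrix(coords)
    if (ncol(xy) != 2L) stop("coordinates must have two columns", call. = FALSE)
  }
  storage.mode(xy) <- "double"
  if (any(!is.finite(xy))) stop("coordinates must be finite", call. = FALSE)
  unname(xy)
}

xy_df <- function(xy) {
  data.frame(id = seq_len(nrow(xy)), x_um = xy[, 1], y_um = xy[, 2])
}
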