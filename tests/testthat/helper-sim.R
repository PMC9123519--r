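# Shared simulation helpers for the tests.

# greedy nearest matching of detected to true points within a radius;
# returns recall and precision
match_points <- function(truth, detected, radius = 2) {
  truth <- as.matrix(truth)
  detected <- as.matrix(detected)
  if (nrow(detected) == 0L) return(list(recall = 0, precision = NA_real_))
  used <- rep(FALSE, nrow(detected))
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected[, 1] - truth[i, 1])^2 + (detected[, 2] - truth[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= radius^2) {
      hits <- hits + 1L
      used[j] <- TRUE
    }
  }
  list(recall = hits / nrow(truth), precision = hits / nrow(detected))
}

coords_mat <- function(df) as.matrix(df[, c("x_um", "y_um")])

# simulated paired rater table with known variance components
sim_rating_table <- function(n, between_sd, within_sd) {
  subj <- rnorm(n, 0, between_sd)
  cbind(subj + rnorm(n, 0, within_sd), subj + rnorm(n, 0, within_sd))
}
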