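# Motion signatures, 2-D motion maps (PCA), unsupervised clustering of
# superpixel tracks, and control-based quantification cut-offs.

#' @importFrom mclust Mclust mclustBIC
NULL

#' Fixed-length motion signature of a video
#'
#' Resamples a mesh strain curve onto a common time grid (linear
#' interpolation) and normalizes by the maximum within the window, giving
#' a fixed-length vector in `[0, 1]` that summarizes the global motion
#' pattern of the video. Multi-channel input (list of curves) is averaged
#' before resampling.
#'
#' @param curve strain curve ([mesh_strain_curve()]) or list of
#'   per-channel curves.
#' @param frame_interval hours per frame (default 1).
#' @param window common comparison window in hours (default 96; must not
#'   exceed the video span).
#' @param n_points signature length (default `window + 1`, i.e. 97
#'   hourly samples for a 96 h window).
#' @return Numeric vector of length `n_points` with values in `[0, 1]`.
#' @export
motion_signature <- function(curve, frame_interval = 1, window = 96,
                             n_points = window + 1) {
  if (is.list(curve)) curve <- Reduce(`+`, curve) / length(curve)
  times <- (seq_along(curve) - 1) * frame_interval
  if (window > max(times))
    stop_invalid("window exceeds the video duration")
  grid <- seq(0, window, length.out = n_points)
  sig <- approx(times, curve, xout = grid)$y
  m <- max(sig)
  if (m > 0) sig <- sig / m
  sig
}

#' Fit a 2-D motion map (PCA) over a cohort of signatures
#'
#' Principal component analysis of the signature matrix; the first two
#' components define a plane onto which new videos can be projected
#' without refitting.
#'
#' @param signatures matrix (videos x signature length) or list of
#'   signature vectors.
#' @return A `motion_map`: list with `components` (2 x L, orthonormal
#'   rows), `center` (mean signature), `scores` (training projections,
#'   videos x 2) and `var_explained`.
#' @export
fit_motion_map <- function(signatures) {
  X <- if (is.list(signatures)) do.call(rbind, signatures) else
    as.matrix(signatures)
  if (nrow(X) < 3) stop_invalid("need at least 3 signatures")
  if (anyNA(X)) stop_invalid("signatures contain missing values")
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
  structure(list(components = t(p$rotation), center = p$center,
                 scores = p$x[, 1:2, drop = FALSE],
                 var_explained = (p$sdev^2 / sum(p$sdev^2))[1:2]),
            class = "motion_map")
}

#' Project signatures onto a fitted motion map
#'
#' Centers by the training mean and projects onto the frozen components;
#' the projection is affine, so the training-cohort mean maps to the
#' origin and interpolated signatures map onto the segment between their
#' projections.
#'
#' @param map a `motion_map` from [fit_motion_map()].
#' @param signature one signature vector or a matrix of rows.
#' @return `n x 2` matrix of map coordinates.
#' @export
project_motion_map <- function(map, signature) {
  X <- if (is.null(dim(signature))) matrix(signature, nrow = 1) else
    as.matrix(signature)
  if (ncol(X) != length(map$center))
    stop_invalid("signature length does not match the map")
  sweep(X, 2, map$center) %*% t(map$components)
}

#' Cluster superpixel tracks by their local strain dynamics
#'
#' Features are the per-superpixel local mesh strain curves (N x T); a
#' Gaussian mixture model is fitted for k = 1..`k_max` and the number of
#' clusters chosen by BIC (mclust's model-based hierarchical
#' initialisation makes the fit deterministic). Zero-variance time points
#' (e.g. the all-zero first frame) are dropped from the features.
#'
#' @param tracks `(n, T, 2)` track array.
#' @param mesh frozen `mesh` over the tracks.
#' @param k_max largest cluster count considered (must be < n).
#' @return List with `labels` (length n; `NA` for superpixels without mesh
#'   neighbours, which carry no local-context signal), `k`, `posterior`
#'   (rows for clustered superpixels), `bic` (per k, mclust convention:
#'   larger is better) and the fitted `model`.
#' @export
cluster_superpixel_tracks <- function(tracks, mesh, k_max = 8) {
  n <- dim(tracks)[1]
  if (k_max >= n) stop_invalid("k_max must be smaller than the track count")
  X <- mesh_strain_curve(tracks, mesh, per_superpixel = TRUE)
  rows <- which(lengths(mesh$neighbours) > 0)
  cols <- which(apply(X[rows, , drop = FALSE], 2, var) > 0)
  if (!length(cols))
    stop_degenerate("all strain curves are constant; nothing to cluster")
  fit <- Mclust(X[rows, cols, drop = FALSE], G = 1:k_max, verbose = FALSE)
  if (is.null(fit)) stop_degenerate("mixture fitting failed")
  labels <- rep(NA_integer_, n)
  labels[rows] <- fit$classification
  bic <- apply(fit$BIC, 1, max, na.rm = TRUE)
  list(labels = labels, k = fit$G,
       posterior = fit$z, bic = bic, model = fit)
}

#' Control-based quantification cut-off
#'
#' One sample standard deviation above (or below) the pooled mean of
#' control measurements, the decision threshold used to call an effect
#' relative to a control cohort.
#'
#' @param control_values numeric control measurements (>= 2 values).
#' @param side `"above"` (mean + sd) or `"below"` (mean - sd).
#' @return The threshold.
#' @export
control_cutoff <- function(control_values, side = c("above", "below")) {
  side <- match.arg(side)
  if (length(control_values) < 2)
    stop_invalid("need at least 2 control values")
  m <- mean(control_values)
  s <- sd(control_values)
  if (side == "above") m + s else m - s
}
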