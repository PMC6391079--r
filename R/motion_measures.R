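# Track- and mesh-derived motion statistics.

#' Mesh strain curve
#'
#' Per-superpixel strain at frame t is the mean absolute change of the
#' Euclidean distance to each frozen-mesh neighbour relative to frame 0,
#' `eps_i(t) = mean_j | d_ij(t) - d_ij(0) |` (L1 across neighbours for
#' robustness to tracking errors). The curve is the mean of `eps_i(t)` over
#' all non-isolated superpixels; for multi-channel input pass a list of
#' track arrays and the per-channel curves are averaged.
#'
#' @param tracks `(n, T, 2)` track array, or a list of track arrays (one
#'   per channel, each with its own mesh in `mesh`).
#' @param mesh `mesh` from [build_moses_mesh()], or a list of meshes
#'   parallel to `tracks`.
#' @param per_superpixel return the `n x T` matrix of local strain curves
#'   instead of the global mean curve.
#' @return Numeric vector of length `T` (strain in pixels, value 0 at
#'   frame 1), or an `n x T` matrix when `per_superpixel = TRUE`.
#' @export
mesh_strain_curve <- function(tracks, mesh, per_superpixel = FALSE) {
  if (is.list(tracks) && !is_track_array(tracks)) {
    if (per_superpixel) stop_invalid("per_superpixel needs a single channel")
    curves <- mapply(mesh_strain_curve, tracks, mesh, SIMPLIFY = FALSE)
    return(Reduce(`+`, curves) / length(curves))
  }
  n <- dim(tracks)[1]; T_ <- dim(tracks)[2]
  e <- mesh$edges
  eps <- matrix(0, n, T_)
  if (nrow(e) > 0) {
    dx0 <- tracks[e[, 1], 1, 1] - tracks[e[, 2], 1, 1]
    dy0 <- tracks[e[, 1], 1, 2] - tracks[e[, 2], 1, 2]
    d0 <- sqrt(dx0^2 + dy0^2)
    deg <- lengths(mesh$neighbours)
    for (t in seq_len(T_)) {
      dx <- tracks[e[, 1], t, 1] - tracks[e[, 2], t, 1]
      dy <- tracks[e[, 1], t, 2] - tracks[e[, 2], t, 2]
      a <- abs(sqrt(dx^2 + dy^2) - d0)
      s <- numeric(n)
      acc <- rowsum(c(a, a), c(e[, 1], e[, 2]))
      s[as.integer(rownames(acc))] <- acc[, 1]
      eps[, t] <- ifelse(deg > 0, s / deg, 0)
    }
  }
  if (per_superpixel) return(eps)
  deg <- lengths(mesh$neighbours)
  if (any(deg > 0)) colMeans(eps[deg > 0, , drop = FALSE]) else rep(0, T_)
}

#' Normalize a strain curve by its maximum over a window
#'
#' Divides by the maximum strain within the common comparison window so
#' curves from different acquisitions are comparable; an identically-zero
#' curve (rigid or static motion) maps to an identically-zero curve.
#' Values outside the window may exceed 1.
#'
#' @param curve numeric strain curve.
#' @param window frame indices over which the maximum is taken (default:
#'   whole curve).
#' @return The normalized curve with attributes `normalized` and
#'   `norm_window`.
#' @export
normalize_strain_curve <- function(curve, window = seq_along(curve)) {
  if (any(window < 1 | window > length(curve)))
    stop_invalid("window outside curve range")
  m <- max(curve[window])
  out <- if (m > 0) curve / m else curve
  attr(out, "normalized") <- TRUE
  attr(out, "norm_window") <- range(window)
  out
}

#' Mesh stability index
#'
#' One minus the end gradient of the normalized strain curve on time
#' rescaled to `[0, 1]`. The end gradient is the mean first-order
#' difference over the last `tail` frames divided by the normalized time
#' step `1/(T-1)`; a plateaued curve scores 1 (upper bound), a straight
#' rise from 0 to 1 scores 0. Use 10 frames for ~96-frame videos and 24
#' for ~144-frame videos.
#'
#' @param norm_curve normalized strain curve (see
#'   [normalize_strain_curve()]).
#' @param tail number of trailing frames for the end gradient; default
#'   `max(10, ceiling(0.1 * T))`.
#' @return Scalar index, at most 1.
#' @export
mesh_stability_index <- function(norm_curve,
                                 tail = max(10, ceiling(0.1 * length(norm_curve)))) {
  T_ <- length(norm_curve)
  if (tail >= T_) stop_invalid("tail must be smaller than the curve length")
  d <- diff(norm_curve)
  grad <- mean(utils::tail(d, tail)) * (T_ - 1)
  1 - grad
}

#' Velocity order parameter at a frame
#'
#' Mean resultant length of the unit velocity vectors,
#' `psi(t) = || mean_i V_i(t) / ||V_i(t)|| ||`, over superpixels moving at
#' frame t (speed below `eps` excluded). 1 means perfectly aligned motion,
#' values near 0 mean uncoordinated directions.
#'
#' @param tracks `(n, T, 2)` track array.
#' @param t frame index (`1..T-1`; the velocity uses frames t, t+1).
#' @param eps minimum speed (pixels/frame) to count as moving.
#' @return Scalar in `[0, 1]`, or `NA` if no superpixel moves.
#' @export
velocity_order <- function(tracks, t, eps = 1e-8) {
  T_ <- dim(tracks)[2]
  if (t < 1 || t >= T_) stop_invalid("t must be in [1, n_frames - 1]")
  v <- .frame_positions(tracks, t + 1) - .frame_positions(tracks, t)
  .order_parameter(v, eps, all_zero = NA_real_)
}

.order_parameter <- function(v, eps, all_zero) {
  sp <- sqrt(rowSums(v^2))
  keep <- sp >= eps
  if (!any(keep)) return(all_zero)
  u <- v[keep, , drop = FALSE] / sp[keep]
  sqrt(sum(colMeans(u)^2))
}

#' Mesh order parameter
#'
#' The velocity order parameter computed on resultant mesh strain vectors
#' ([mesh_strain_vector()]) instead of instantaneous velocities, which
#' makes it robust to frame-to-frame jitter: rigid collective motion has
#' all strain vectors zero and scores 1 by convention. Frames are scored
#' individually and the mean over frames is reported.
#'
#' @param tracks `(n, T, 2)` track array.
#' @param mesh frozen `mesh` built on the tracks.
#' @param eps minimum strain-vector norm to include.
#' @return List with `series` (length `T - 1`) and `mean`.
#' @export
mesh_order <- function(tracks, mesh, eps = 1e-8) {
  T_ <- dim(tracks)[2]
  series <- vapply(2:T_, function(t) {
    v <- mesh_strain_vector(tracks, mesh, t)
    .order_parameter(v, eps, all_zero = 1)
  }, numeric(1))
  list(series = series, mean = mean(series))
}

#' Mean squared displacement curve
#'
#' `MSD(dt) = <|r_i(t + dt) - r_i(t)|^2>` averaged over all start times t
#' and all superpixels, for `dt = 1..T-1` frames.
#'
#' @param tracks `(n, T, 2)` track array.
#' @return Numeric vector indexed by lag `dt` (pixels^2).
#' @export
msd <- function(tracks) {
  T_ <- dim(tracks)[2]
  if (T_ < 2) stop_invalid("need at least 2 frames")
  vapply(seq_len(T_ - 1), function(lag) {
    d <- tracks[, (1 + lag):T_, , drop = FALSE] -
      tracks[, 1:(T_ - lag), , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2)
  }, numeric(1))
}

#' Fit the power-law exponent of an MSD curve
#'
#' Log-log ordinary least squares of `MSD(dt) ~ dt^alpha` over small lags.
#' `alpha = 1` is diffusive (Brownian), `alpha = 2` ballistic.
#'
#' @param curve MSD values indexed by lag (from [msd()]).
#' @param fit_range lag indices to fit; default the first 10% of lags and
#'   at least 3 points.
#' @return The fitted exponent `alpha`.
#' @export
fit_msd_exponent <- function(curve,
                             fit_range = seq_len(min(length(curve),
                                                     max(3, floor(length(curve) / 10))))) {
  y <- curve[fit_range]
  if (any(y <= 0))
    stop_degenerate("MSD is zero over the fit range; exponent undefined")
  unname(coef(lm(log(y) ~ log(fit_range)))[2])
}

#' Root mean squared displacement from the initial frame
#'
#' `RMSD(t) = sqrt(<|r_i(t) - r_i(1)|^2>)` over superpixels, one value per
#' frame. Optionally normalized by the maximum within a window or by the
#' value at a reference frame.
#'
#' @param tracks `(n, T, 2)` track array, or a list of per-channel arrays
#'   (curves averaged).
#' @param normalize `"none"`, `"max"` (divide by max within `window`), or
#'   `"frame"` (divide by the value at `ref_frame`).
#' @param window frame indices for the `"max"` normalization.
#' @param ref_frame reference frame for the `"frame"` normalization.
#' @return Numeric vector of length `T` (pixels; unitless if normalized).
#' @export
rmsd <- function(tracks, normalize = c("none", "max", "frame"),
                 window = NULL, ref_frame = NULL) {
  normalize <- match.arg(normalize)
  if (is.list(tracks) && !is_track_array(tracks)) {
    curves <- lapply(tracks, rmsd)
    out <- Reduce(`+`, curves) / length(curves)
  } else {
    T_ <- dim(tracks)[2]
    out <- vapply(seq_len(T_), function(t) {
      d <- .frame_positions(tracks, t) - .frame_positions(tracks, 1)
      sqrt(mean(rowSums(d^2)))
    }, numeric(1))
  }
  if (normalize == "max") {
    if (is.null(window)) window <- seq_along(out)
    m <- max(out[window])
    if (m > 0) out <- out / m
  } else if (normalize == "frame") {
    if (is.null(ref_frame)) stop_invalid("ref_frame required")
    m <- out[ref_frame]
    if (m > 0) out <- out / m
  }
  out
}

# temporal correlation matrix of 2-D velocity series: covariance summed
# over x/y components normalized by total (2-D) standard deviations,
# population (1/T) convention
.velocity_correlation_matrix <- function(v) {
  T_ <- dim(v)[2]
  vx <- v[, , 1, drop = FALSE][, , 1] - rowMeans(v[, , 1, drop = FALSE][, , 1])
  vy <- v[, , 2, drop = FALSE][, , 1] - rowMeans(v[, , 2, drop = FALSE][, , 1])
  cov2 <- (vx %*% t(vx) + vy %*% t(vy)) / T_
  sdv <- sqrt(diag(cov2))
  cov2 / outer(sdv, sdv)
}

#' Spatial velocity correlation versus distance
#'
#' For each distance shell between consecutive radii, the mean over
#' superpixels of the mean temporal correlation between a superpixel's 2-D
#' velocity series and those of its neighbours in the shell (frame-0
#' centroid distances; covariance summed over x and y, normalized by the
#' product of total standard deviations). The decay is summarized by a
#' least-squares fit of `y = a * exp(-x / b)`.
#'
#' @param tracks `(n, T, 2)` track array.
#' @param radii ascending distances in multiples of `avg_width`; shell k
#'   collects pairs with distance in `(radii[k-1], radii[k]]` (first shell
#'   from 0).
#' @param avg_width average superpixel width, pixels.
#' @return List with `r` (the radii), `correlation` (per shell, `NA` for
#'   empty shells), and `fit` (`a`, `b`), `fit` being `NULL` when fewer
#'   than 3 shells are estimable.
#' @export
spatial_correlation <- function(tracks, radii = 1:8, avg_width = 1) {
  if (dim(tracks)[2] < 2) stop_invalid("need at least 2 frames")
  if (is.unsorted(radii, strictly = TRUE)) stop_invalid("radii must be ascending")
  v <- track_velocities(tracks)
  cm <- .velocity_correlation_matrix(v)
  ok <- is.finite(diag(cm))  # drop zero-variance (static) series
  d <- pdist2(.frame_positions(tracks, 1)) / avg_width
  n <- dim(tracks)[1]
  breaks <- c(0, radii)
  stats_r <- vapply(seq_along(radii), function(k) {
    vals <- dists <- NULL
    for (i in which(ok)) {
      js <- which(d[i, ] > breaks[k] & d[i, ] <= breaks[k + 1] & ok &
                    seq_len(n) != i)
      if (length(js)) {
        vals <- c(vals, mean(cm[i, js]))
        dists <- c(dists, mean(d[i, js]))
      }
    }
    if (length(vals)) c(mean(vals), mean(dists)) else c(NA_real_, NA_real_)
  }, numeric(2))
  cor_r <- stats_r[1, ]
  x_eff <- stats_r[2, ]  # mean pair distance per shell, for the fit
  est <- which(is.finite(cor_r))
  fit <- NULL
  if (length(est) >= 3) {
    df <- data.frame(x = x_eff[est], y = cor_r[est])
    b0 <- diff(range(df$x)) / 2
    f <- try(minpack.lm::nlsLM(y ~ a * exp(-x / b), data = df,
                               start = list(a = max(df$y), b = b0),
                               control = minpack.lm::nls.lm.control(maxiter = 200)),
             silent = TRUE)
    if (!inherits(f, "try-error")) {
      fit <- as.list(coef(f))
    } else if (all(df$y > 0)) {  # flat or noiseless curves: log-linear fit
      cf <- coef(lm(log(y) ~ x, data = df))
      fit <- list(a = unname(exp(cf[1])),
                  b = unname(if (cf[2] < 0) -1 / cf[2] else Inf))
    }
  }
  list(r = radii, x = x_eff, correlation = cor_r, fit = fit)
}

#' Normalized velocity cross-correlation of two tracks
#'
#' Both 2-D velocity series are standardized (`(V - mean(V)) / sigma`, with
#' `sigma` the total standard deviation over both components, population
#' convention); the cross-correlation
#' `C(m) = (1/T) sum_t Vhat_i(t + m) . Vhat_j(t)` is evaluated over all
#' lags `m` in `[-T, T]` with zero padding, and the maximum absolute value
#' is returned. Self-correlation is exactly 1 at lag 0 and all values are
#' bounded by 1.
#'
#' @param track_i,track_j `(T, 2)` position matrices or `(1, T, 2)` track
#'   slices.
#' @return List with `value` (max absolute correlation, in `[0, 1]`),
#'   `lag` (the arg-max lag, frames) and `ccf` (the full correlation
#'   function, lags `-T..T`).
#' @export
velocity_cross_correlation <- function(track_i, track_j) {
  vi <- .track_velocity_series(track_i)
  vj <- .track_velocity_series(track_j)
  if (nrow(vi) != nrow(vj)) stop_invalid("tracks must share the frame count")
  T_ <- nrow(vi)
  if (T_ < 2) stop_invalid("need velocity series of length >= 2")
  vi <- .standardize_velocity(vi)
  vj <- .standardize_velocity(vj)
  cc <- .xcorr(vi[, 1], vj[, 1]) + .xcorr(vi[, 2], vj[, 2])
  cc <- cc / T_
  lags <- -(T_ - 1):(T_ - 1)
  cc <- c(0, cc, 0)          # lags -T and T fall entirely outside: zero
  lags <- c(-T_, lags, T_)
  k <- which.max(abs(cc))
  list(value = abs(cc[k]), lag = lags[k], ccf = stats::setNames(cc, lags))
}

.track_velocity_series <- function(track) {
  if (is_track_array(track)) track <- matrix(track[1, , ], ncol = 2)
  track <- as.matrix(track)
  diff(track)
}

.standardize_velocity <- function(v) {
  T_ <- nrow(v)
  vc <- sweep(v, 2, colMeans(v))
  sigma <- sqrt(sum(vc^2) / T_)  # total 2-D population standard deviation
  if (sigma == 0)
    stop_degenerate("zero-variance velocity series: normalization undefined")
  vc / sigma
}

# full linear cross-correlation sum_t a(t + m) b(t), m = -(T-1)..(T-1)
.xcorr <- function(a, b) {
  T_ <- length(a)
  out <- numeric(2 * T_ - 1)
  for (m in -(T_ - 1):(T_ - 1)) {
    t0 <- max(1, 1 - m):min(T_, T_ - m)
    out[m + T_] <- sum(a[t0 + m] * b[t0])
  }
  out
}

#' Sheet-to-sheet velocity cross-correlation before and after gap closure
#'
#' Averages the maximum-absolute normalized velocity cross-correlation
#' over red-green superpixel pairings, separately for the pre-closure
#' window `[1, closure - offset]` and the post-closure window
#' `[closure + offset, T]`. The offset keeps frames near the (uncertain)
#' closure point out of both windows. Zero-variance pairs are skipped.
#'
#' @param tracks_red,tracks_green `(n, T, 2)` track arrays.
#' @param closure_frame gap-closure frame (1-based).
#' @param offset frames excluded on each side of closure (default 5, the
#'   closure-detection accuracy).
#' @param max_pairs random subsample size of red x green pairings (all
#'   pairs if smaller).
#' @param seed subsampling seed.
#' @return List with `before` and `after` mean correlations in `[0, 1]`.
#' @export
sheet_vcc <- function(tracks_red, tracks_green, closure_frame, offset = 5,
                      max_pairs = 2000, seed = 0) {
  T_ <- dim(tracks_red)[2]
  wb <- seq_len(closure_frame - offset)
  wa <- seq(min(closure_frame + offset, T_), T_)
  if (length(wb) < 3 || length(wa) < 3)
    stop_invalid("closure windows shorter than 2 velocity samples")
  pairs <- expand.grid(i = seq_len(dim(tracks_red)[1]),
                       j = seq_len(dim(tracks_green)[1]))
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[with_seed(seed, sample.int(nrow(pairs), max_pairs)), ]
  avg <- function(w) {
    vals <- apply(pairs, 1, function(p) {
      r <- matrix(tracks_red[p[1], w, ], ncol = 2)
      g <- matrix(tracks_green[p[2], w, ], ncol = 2)
      tryCatch(velocity_cross_correlation(r, g)$value,
               motionmesh_degenerate_input = function(e) NA_real_)
    })
    mean(vals, na.rm = TRUE)
  }
  list(before = avg(wb), after = avg(wa))
}

#' Motion saliency map
#'
#' Per frame, the radius-neighbour graph over current superpixel positions
#' is built and each superpixel's neighbour count (node degree) is written
#' at its rounded position into a frame-sized accumulator. The accumulated
#' image is averaged over frames, then spatially averaged over the frame-0
#' superpixel partition (each region replaced by its mean), revealing
#' temporally persistent motion sinks such as boundaries. The backward
#' direction runs on time-reversed tracks and highlights motion sources.
#'
#' @param tracks `(n, T, 2)` track array, or a list of per-channel arrays
#'   pooled into one point set.
#' @param grid the frame partition ([make_superpixel_grid()]).
#' @param radius_factor neighbour cutoff in average superpixel widths
#'   (5.0 for boundary formation).
#' @param direction `"forward"` or `"backward"`.
#' @param frame_range frames to accumulate (default: all).
#' @return A `saliency_map`: a `height x width` non-negative matrix with
#'   attributes `direction` and `radius_factor`.
#' @export
motion_saliency_map <- function(tracks, grid, radius_factor = 5,
                                direction = c("forward", "backward"),
                                frame_range = NULL) {
  direction <- match.arg(direction)
  if (is.list(tracks) && !is_track_array(tracks)) {
    n_all <- sum(vapply(tracks, function(x) dim(x)[1], integer(1)))
    T_ <- dim(tracks[[1]])[2]
    pooled <- array(NA_real_, c(n_all, T_, 2))
    at <- 0
    for (tr in tracks) {
      pooled[at + seq_len(dim(tr)[1]), , ] <- tr
      at <- at + dim(tr)[1]
    }
    tracks <- pooled
  }
  T_ <- dim(tracks)[2]
  if (is.null(frame_range)) frame_range <- seq_len(T_)
  if (direction == "backward")
    tracks <- tracks[, rev(seq_len(T_)), , drop = FALSE]
  H <- grid$height; W <- grid$width
  acc <- matrix(0, H, W)
  radius <- radius_factor * grid$avg_width
  for (t in frame_range) {
    pos <- .frame_positions(tracks, t)
    deg <- .radius_degree(pos, radius)
    x <- round(pos[, 1]); y <- round(pos[, 2])
    inb <- x >= 1 & x <= W & y >= 1 & y <= H
    idx <- cbind(y[inb], x[inb])
    for (k in seq_len(nrow(idx)))
      acc[idx[k, 1], idx[k, 2]] <- acc[idx[k, 1], idx[k, 2]] + deg[inb][k]
  }
  acc <- acc / length(frame_range)
  # spatial average over the frame-0 partition
  region_mean <- rowsum(as.vector(acc), as.vector(grid$labels)) /
    as.vector(table(factor(as.vector(grid$labels), levels = seq_len(grid$n))))
  out <- matrix(region_mean[as.vector(grid$labels)], H, W)
  structure(out, direction = direction, radius_factor = radius_factor,
            class = c("saliency_map", "matrix", "array"))
}

.radius_degree <- function(positions, radius) {
  d <- pdist2(positions)
  diag(d) <- Inf
  rowSums(d <= radius)
}

#' Boundary formation index of a saliency map
#'
#' Otsu-thresholds the map into high and low regions and returns the
#' normalized signal-to-noise ratio
#' `(mean(high) - mean(low)) / mean(high)`, in `[0, 1]`: 0 for spatially
#' uniform motion, 1 when motion concentrates on a single line or point
#' with empty background. A constant map (degenerate threshold) scores 0.
#'
#' @param map a `saliency_map` or any non-negative numeric matrix.
#' @return Scalar in `[0, 1]`.
#' @export
boundary_formation_index <- function(map) {
  v <- as.vector(map)
  lo <- min(v); hi <- max(v)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) return(0)
  th <- EBImage::otsu(EBImage::Image((v - lo) / (hi - lo), dim = dim(map)),
                      range = c(0, 1))
  high <- v[(v - lo) / (hi - lo) > th]
  low <- v[(v - lo) / (hi - lo) <= th]
  if (!length(high) || !length(low)) return(0)
  (mean(high) - mean(low)) / mean(high)
}
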