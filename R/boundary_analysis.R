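# Intensity-based sheet segmentation, automatic gap-closure detection,
# boundary-line extraction and boundary descriptors.

#' Asymmetric least-squares (Whittaker) baseline
#'
#' Fits a smooth baseline hugging the lower envelope of a signal: a
#' Whittaker smoother (second-difference penalty `lambda`) iterated with
#' asymmetric weights (`p` for points above the baseline, `1 - p` below).
#'
#' @param y numeric signal.
#' @param lambda smoothness penalty (default 1e5).
#' @param p asymmetry (default 0.001; small values push the baseline under
#'   the data).
#' @param iters reweighting iterations (default 10).
#' @return Numeric baseline, same length as `y`.
#' @export
whittaker_als <- function(y, lambda = 1e5, p = 0.001, iters = 10) {
  m <- length(y)
  if (m < 4) stop_invalid("signal too short for a baseline")
  D <- Matrix::bandSparse(m - 2, m, k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2),
                                           rep(1, m - 2)))
  P <- lambda * Matrix::crossprod(D)
  # Two guards against the secant-line fixed point on monotone
  # descent-to-floor curves: start from a flat (median) baseline rather
  # than uniform weights, and keep points within the estimated noise band
  # of the baseline anchored at full weight.
  w <- ifelse(y > median(y), p, 1 - p)
  z <- y
  for (it in seq_len(iters)) {
    Wm <- Matrix::Diagonal(m, w)
    z <- as.numeric(Matrix::solve(Wm + P, w * y))
    r <- y - z
    neg <- r[r <= 0]
    d <- if (length(neg) >= 2) 2 * sd(neg) else 0
    w <- ifelse(r > d, p, 1 - p)
  }
  z
}

#' Segment an epithelial sheet in one channel frame
#'
#' Two strategies. `"kmeans"` (gap-closure pipeline): median filter with a
#' kernel of about the average superpixel width, k-means on pixel
#' intensities keeping the brightest `k - 1` classes, binary closing
#' (disk 5), removal of objects under 5% of the frame area and hole
#' filling. `"entropy"` (texture pipeline): edge-preserving anisotropic
#' diffusion, a local-entropy transform, Otsu thresholding and row-wise
#' line-raster hole filling. In both, only the largest connected component
#' is retained.
#'
#' @param channel_image numeric matrix (single channel, any scale).
#' @param strategy `"kmeans"` or `"entropy"`.
#' @param k intensity classes for k-means (2; use 3 for dim leading
#'   cells).
#' @param avg_width median-filter kernel size, pixels.
#' @return Logical sheet mask (same shape); empty for a blank image.
#' @export
segment_sheet_frame <- function(channel_image, strategy = c("kmeans", "entropy"),
                                k = 2, avg_width = 15) {
  strategy <- match.arg(strategy)
  img <- as.matrix(channel_image)
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  img <- (img - rng[1]) / diff(rng)
  if (strategy == "kmeans") {
    sm <- EBImage::medianFilter(EBImage::Image(img), max(1L, as.integer(avg_width / 2)))
    v <- as.vector(EBImage::imageData(sm))
    centers <- matrix(quantile(v, probs = seq(0.05, 0.95, length.out = k)),
                      ncol = 1)
    if (length(unique(centers)) < k)
      return(matrix(FALSE, nrow(img), ncol(img)))
    km <- kmeans(v, centers = centers, iter.max = 50)
    bright <- order(km$centers[, 1], decreasing = TRUE)[seq_len(k - 1)]
    mask <- matrix(km$cluster %in% bright, nrow(img), ncol(img))
    mask <- .postprocess_mask(mask)
  } else {
    sm <- .anisodiff(img, iters = 8, kappa = 0.1, gamma = 0.2)
    ent <- .local_entropy(sm, half = 4, nbins = 16)
    ent <- (ent - min(ent)) / max(diff(range(ent)), .Machine$double.eps)
    th <- EBImage::otsu(EBImage::Image(ent), range = c(0, 1))
    mask <- ent > th
    mask <- .raster_fill(mask)
    mask <- .largest_component(mask)
  }
  mask
}

.postprocess_mask <- function(mask) {
  im <- EBImage::Image(mask * 1)
  im <- EBImage::closing(im, EBImage::makeBrush(5, "disc"))
  lab <- EBImage::bwlabel(im)
  sizes <- table(EBImage::imageData(lab)[EBImage::imageData(lab) > 0])
  keep <- as.integer(names(sizes)[sizes >= 0.05 * length(mask)])
  m2 <- matrix(EBImage::imageData(lab) %in% keep, nrow(mask), ncol(mask))
  if (!any(m2)) return(m2)
  m2 <- matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(m2 * 1))) > 0,
               nrow(mask), ncol(mask))
  .largest_component(m2)
}

.largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  sizes <- table(lab[lab > 0])
  big <- as.integer(names(sizes)[which.max(sizes)])
  matrix(lab == big, nrow(mask), ncol(mask))
}

# Perona-Malik diffusion, exponential conductance
.anisodiff <- function(img, iters = 8, kappa = 0.1, gamma = 0.2) {
  u <- img
  H <- nrow(u); W <- ncol(u)
  for (it in seq_len(iters)) {
    dn <- rbind(u[1, ], u[-H, ]) - u
    ds <- rbind(u[-1, ], u[H, ]) - u
    de <- cbind(u[, -1], u[, W]) - u
    dw <- cbind(u[, 1], u[, -W]) - u
    u <- u + gamma * (exp(-(dn / kappa)^2) * dn + exp(-(ds / kappa)^2) * ds +
                        exp(-(de / kappa)^2) * de + exp(-(dw / kappa)^2) * dw)
  }
  u
}

# windowed Shannon entropy via binned indicator images and box filtering
.local_entropy <- function(img, half = 4, nbins = 16) {
  bins <- matrix(pmin(1L + floor(img * nbins), nbins), nrow(img), ncol(img))
  side <- 2 * half + 1
  kern <- matrix(1 / side^2, side, side)
  ent <- matrix(0, nrow(img), ncol(img))
  for (b in seq_len(nbins)) {
    ind <- (bins == b) * 1
    if (!any(ind > 0)) next
    p <- EBImage::imageData(EBImage::filter2(EBImage::Image(ind), kern,
                                             boundary = "replicate"))
    p <- pmax(p, 0)
    ent <- ent - ifelse(p > 0, p * log2(p), 0)
  }
  ent
}

# row-wise fill between the first and last mask pixel of each row
.raster_fill <- function(mask) {
  for (r in seq_len(nrow(mask))) {
    w <- which(mask[r, ])
    if (length(w) >= 2) mask[r, w[1]:w[length(w)]] <- TRUE
  }
  mask
}

#' Migrating-front points by horizontal sweepline
#'
#' Divides the frame into `n_strips` horizontal strips and records, per
#' strip, the extreme mask pixel in the direction of sheet motion (the
#' right-most pixel for a rightward-moving sheet). Strips without mask
#' pixels contribute no point.
#'
#' @param mask logical sheet mask.
#' @param direction `"right"` or `"left"`: the direction the sheet is
#'   moving (decides max vs min x).
#' @param n_strips number of strips (default 100).
#' @return Matrix with columns `x`, `y` (at most `n_strips` rows).
#' @export
sweepline_fronts <- function(mask, direction = c("right", "left"),
                             n_strips = 100) {
  direction <- match.arg(direction)
  if (n_strips < 1) stop_invalid("n_strips must be >= 1")
  H <- nrow(mask)
  bounds <- floor(H * (0:n_strips) / n_strips)
  pts <- NULL
  for (s in seq_len(n_strips)) {
    rows <- (bounds[s] + 1):bounds[s + 1]
    if (!length(rows) || bounds[s + 1] <= bounds[s]) next
    sub <- which(mask[rows, , drop = FALSE], arr.ind = TRUE)
    if (!nrow(sub)) next
    k <- if (direction == "right") which.max(sub[, 2]) else which.min(sub[, 2])
    pts <- rbind(pts, c(x = sub[k, 2], y = rows[sub[k, 1]]))
  }
  if (is.null(pts)) pts <- matrix(numeric(0), 0, 2)
  colnames(pts) <- c("x", "y")
  pts
}

#' Mean front-to-front distance over time
#'
#' Per frame, extracts the migrating fronts of both sheets by sweepline,
#' pairs every front point with the nearest point of the opposing colour,
#' and averages the Euclidean pair distances.
#'
#' @param masks_red,masks_green lists of per-frame logical masks.
#' @param dir_red,dir_green motion directions passed to
#'   [sweepline_fronts()]; `"auto"` infers them from which half of the
#'   frame each sheet starts in.
#' @param n_strips sweepline strips.
#' @return A `gap_curve`: numeric vector of per-frame mean distances
#'   (pixels, 0 when either front is empty at contact).
#' @export
gap_distance_curve <- function(masks_red, masks_green, dir_red = "auto",
                               dir_green = "auto", n_strips = 100) {
  infer <- function(mask) {
    cols <- which(mask, arr.ind = TRUE)[, 2]
    if (!length(cols)) return("right")
    if (mean(cols) <= ncol(mask) / 2) "right" else "left"
  }
  if (dir_red == "auto") dir_red <- infer(masks_red[[1]])
  if (dir_green == "auto") dir_green <- infer(masks_green[[1]])
  curve <- vapply(seq_along(masks_red), function(t) {
    fr <- sweepline_fronts(masks_red[[t]], dir_red, n_strips)
    fg <- sweepline_fronts(masks_green[[t]], dir_green, n_strips)
    if (!nrow(fr) || !nrow(fg)) return(0)
    d <- pdist2(fr, fg)
    mean(c(apply(d, 1, min), apply(d, 2, min)))
  }, numeric(1))
  structure(curve, class = c("gap_curve", "numeric"))
}

#' Detect the gap-closure frame from a front-distance curve
#'
#' Fits an asymmetric least-squares baseline (the post-closure floor due
#' to segmentation noise) and a smoothing spline to the curve; closure is
#' the first frame at which the spline falls below
#' `baseline + 2 * sd(baseline)`.
#'
#' @param curve per-frame mean front distance ([gap_distance_curve()]).
#' @param lambda,p,iters baseline parameters ([whittaker_als()]).
#' @return 1-based closure frame, or `NA` if the curve never closes.
#' @export
gap_closure_frame <- function(curve, lambda = 1e5, p = 0.001, iters = 10) {
  curve <- as.numeric(curve)
  if (length(curve) < 10) stop_invalid("curve must have at least 10 frames")
  base <- whittaker_als(curve, lambda = lambda, p = p, iters = iters)
  t <- seq_along(curve)
  spl <- predict(smooth.spline(t, curve), t)$y
  thr <- base + 2 * sd(base)
  above <- which(spl > thr)
  if (!length(above)) return(NA_integer_)  # never open: no closure event
  hit <- which(spl < thr & t > min(above))
  if (!length(hit)) return(NA_integer_)
  as.integer(hit[1])
}

#' Normalized boundary displacement after gap closure
#'
#' Absolute difference between the boundary's mean x-position at the final
#' frame and at the closure frame, normalized by the frame width.
#'
#' @param mean_x per-frame mean boundary x-position, pixels.
#' @param closure_frame 1-based closure frame.
#' @param width frame width, pixels.
#' @return Scalar in `[0, 1]`.
#' @export
boundary_displacement <- function(mean_x, closure_frame, width) {
  if (is.na(closure_frame) || closure_frame < 1 || closure_frame > length(mean_x))
    stop_invalid("closure_frame outside the series")
  abs(mean_x[length(mean_x)] - mean_x[closure_frame]) / width
}

.boundary_line <- function(y, x, frame = NA_integer_) {
  o <- order(y)
  y <- y[o]; x <- x[o]
  fun <- if (length(y) >= 2) splinefun(y, x, method = "natural") else NULL
  structure(list(samples = data.frame(y = y, x = x), frame = frame, fun = fun),
            class = "boundary_line")
}

#' @export
print.boundary_line <- function(x, ...) {
  cat(sprintf("boundary_line: %d samples, x in [%.1f, %.1f]\n",
              nrow(x$samples), min(x$samples$x), max(x$samples$x)))
  invisible(x)
}

#' Boundary line from the overlap of two sheet masks
#'
#' Intersects the red and green masks, collapses the overlap to one x per
#' unique y (the mean x along each row) and fits an interpolating cubic
#' spline.
#'
#' @param mask_red,mask_green logical masks of one frame.
#' @return A `boundary_line` (samples plus spline), or `NULL` when the
#'   masks do not overlap (no boundary yet).
#' @export
boundary_line_from_masks <- function(mask_red, mask_green) {
  inter <- mask_red & mask_green
  if (!any(inter)) return(NULL)
  px <- which(inter, arr.ind = TRUE)
  xs <- tapply(px[, 2], px[, 1], mean)
  .boundary_line(as.numeric(names(xs)), as.numeric(xs))
}

#' Boundary line from superpixel tracks at a frame
#'
#' Candidate points are red and green superpixels that have moved more
#' than `move_thresh` in total, moved since the previous frame, and have
#' at least one opposing-colour superpixel within `match_radius` at frame
#' `t`. Isolated candidates (fewer than `min_neighbours` candidates within
#' `neighbour_radius`) are discarded as spurious, then x is averaged per
#' unique (rounded) y and a spline is fitted.
#'
#' @param tracks_red,tracks_green `(n, T, 2)` track arrays.
#' @param t frame index (`t >= 2`).
#' @param avg_width average superpixel width, pixels.
#' @param move_thresh minimum total path length (default 5 average
#'   widths).
#' @param match_radius cross-colour match cutoff (default 2 average
#'   widths).
#' @param min_neighbours,neighbour_radius density filter: required
#'   candidate count within the radius (defaults 5 within 3 average
#'   widths).
#' @return A `boundary_line` or `NULL` when no matched pairs exist.
#' @export
boundary_line_from_tracks <- function(tracks_red, tracks_green, t, avg_width,
                                      move_thresh = 5 * avg_width,
                                      match_radius = 2 * avg_width,
                                      min_neighbours = 5,
                                      neighbour_radius = 3 * avg_width) {
  if (t < 2 || t > dim(tracks_red)[2]) stop_invalid("t must be in [2, n_frames]")
  cand <- function(tracks) {
    steps <- tracks[, -1, , drop = FALSE] - tracks[, -dim(tracks)[2], , drop = FALSE]
    total <- rowSums(sqrt(steps[, , 1, drop = FALSE]^2 +
                            steps[, , 2, drop = FALSE]^2), dims = 1)
    moved_now <- sqrt(rowSums((.frame_positions(tracks, t) -
                                 .frame_positions(tracks, t - 1))^2)) > 0
    which(total > move_thresh & moved_now)
  }
  ir <- cand(tracks_red); ig <- cand(tracks_green)
  if (!length(ir) || !length(ig)) return(NULL)
  pr <- .frame_positions(tracks_red, t)[ir, , drop = FALSE]
  pg <- .frame_positions(tracks_green, t)[ig, , drop = FALSE]
  d <- pdist2(pr, pg)
  mr <- apply(d, 1, min) <= match_radius
  mg <- apply(d, 2, min) <= match_radius
  pts <- rbind(pr[mr, , drop = FALSE], pg[mg, , drop = FALSE])
  if (!nrow(pts)) return(NULL)
  dd <- pdist2(pts)
  diag(dd) <- Inf
  dense <- rowSums(dd <= neighbour_radius) >= min_neighbours
  if (any(dense)) pts <- pts[dense, , drop = FALSE]
  ys <- round(pts[, 2])
  xs <- tapply(pts[, 1], ys, mean)
  .boundary_line(as.numeric(names(xs)), as.numeric(xs), frame = t)
}

#' Fraction of points that crossed the boundary line
#'
#' The fraction of the given cell or superpixel positions lying on the
#' invading side of the boundary line (strictly beyond it; points exactly
#' on the line count as non-invading).
#'
#' @param points `n x 2` matrix of `(x, y)` positions of the infiltrating
#'   population.
#' @param line a `boundary_line`.
#' @param invading_side `"right"` or `"left"`: the side of the line
#'   occupied by the opposing sheet.
#' @return Fraction in `[0, 1]`.
#' @export
infiltration_fraction <- function(points, line,
                                  invading_side = c("right", "left")) {
  invading_side <- match.arg(invading_side)
  points <- as.matrix(points)
  if (!nrow(points)) stop_degenerate("empty point set")
  bx <- if (!is.null(line$fun)) line$fun(points[, 2]) else
    rep(line$samples$x[1], nrow(points))
  across <- if (invading_side == "right") points[, 1] > bx else points[, 1] < bx
  mean(across)
}

#' Boundary shape index (arc length over chord)
#'
#' Total polyline length of the boundary samples divided by the straight
#' distance between its endpoints; 1 for a straight interface, larger for
#' wavy ones.
#'
#' @param line a `boundary_line` with at least 2 samples.
#' @return Scalar `>= 1`.
#' @export
boundary_shape_index <- function(line) {
  s <- line$samples
  if (nrow(s) < 2) stop_degenerate("boundary line has fewer than 2 samples")
  seg <- sqrt(diff(s$x)^2 + diff(s$y)^2)
  chord <- sqrt((s$x[nrow(s)] - s$x[1])^2 + (s$y[nrow(s)] - s$y[1])^2)
  if (chord == 0) stop_degenerate("degenerate boundary line (closed or single point)")
  sum(seg) / chord
}

#' Intermixing coefficients (image and motion based)
#'
#' The image coefficient is the boundary-mask area as a fraction of the
#' frame area; the motion (saliency) coefficient is the area fraction of
#' the thresholded motion saliency map. The two agree when the boundary is
#' stable and boundary motion coordinated, and diverge for dynamic or
#' disordered interfaces.
#'
#' @param boundary_mask logical boundary-region mask.
#' @param saliency_map a [motion_saliency_map()] result.
#' @param thresh threshold for the saliency map; `NULL` uses Otsu.
#' @return List with `image` and `moses` fractions in `[0, 1]`.
#' @export
intermixing_coefficients <- function(boundary_mask, saliency_map, thresh = NULL) {
  image_coeff <- mean(boundary_mask > 0)
  v <- as.matrix(saliency_map)
  rng <- range(v)
  if (diff(rng) == 0) {
    moses_coeff <- 0
  } else {
    if (is.null(thresh)) {
      sc <- (v - rng[1]) / diff(rng)
      th <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
      moses_coeff <- mean(sc > th)
    } else {
      moses_coeff <- mean(v > thresh)
    }
  }
  list(image = image_coeff, moses = moses_coeff)
}

#' Velocity kymograph
#'
#' Collapses the motion field to one row per time point: the median
#' x-velocity as a function of x-position. Track input bins superpixel
#' velocities by their current x; flow-field input bins per-pixel dx by
#' column.
#'
#' @param source `(n, T, 2)` track array or a list of `(H, W, 2)` flow
#'   fields.
#' @param n_bins number of x bins, or `"auto"` (tracks: twice the number
#'   of unique frame-0 centroid x values, per Nyquist; flows: the frame
#'   width).
#' @param width frame width in pixels (required for tracks).
#' @return `(T - 1) x n_bins` matrix of median x-velocities (pixels/frame,
#'   `NA` for empty bins), with bin centers in attribute `x`.
#' @export
velocity_kymograph <- function(source, n_bins = "auto", width = NULL) {
  if (is_track_array(source)) {
    if (is.null(width)) width <- max(source[, , 1])
    if (identical(n_bins, "auto"))
      n_bins <- 2L * length(unique(source[, 1, 1]))
    v <- track_velocities(source)
    T1 <- dim(v)[2]
    breaks <- seq(0.5, width + 0.5, length.out = n_bins + 1)
    out <- matrix(NA_real_, T1, n_bins)
    for (t in seq_len(T1)) {
      xb <- cut(source[, t, 1], breaks, labels = FALSE, include.lowest = TRUE)
      ok <- !is.na(xb)
      med <- tapply(v[ok, t, 1], xb[ok], median)
      out[t, as.integer(names(med))] <- med
    }
  } else {
    flows <- source
    W <- dim(flows[[1]])[2]
    if (identical(n_bins, "auto")) n_bins <- W
    breaks <- seq(0.5, W + 0.5, length.out = n_bins + 1)
    xb <- cut(rep(seq_len(W), each = dim(flows[[1]])[1]), breaks, labels = FALSE,
              include.lowest = TRUE)
    out <- t(vapply(flows, function(f)
      as.numeric(tapply(as.vector(f[, , 1]), xb, median))[seq_len(n_bins)],
      numeric(n_bins)))
  }
  attr(out, "x") <- (head(breaks, -1) + tail(breaks, -1)) / 2
  out
}
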