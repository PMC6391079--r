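#' Build a regular near-square superpixel partition of a frame
#'
#' Partitions a `height` x `width` frame into approximately `n_target`
#' rectangular, near-square superpixels (the regular tiling that seeded
#' superpixel algorithms degenerate to on a featureless image). Every pixel
#' belongs to exactly one superpixel.
#'
#' @param height,width frame dimensions in pixels.
#' @param n_target requested number of superpixels. The realised count is
#'   the closest achievable tiling, within 10% of `n_target` whenever such a
#'   tiling exists.
#' @return An object of class `superpixel_grid`: a list with `labels`
#'   (integer `height` x `width` matrix, values `1..n`), `centroids`
#'   (`n` x 2 matrix of integer `(x, y)` pixel coordinates, x = column,
#'   y = row, 1-based), `avg_width` (`sqrt(height * width / n_target)`,
#'   pixels), `n` and the tiling shape `nx`, `ny`.
#' @examples
#' g <- make_superpixel_grid(100, 100, 4)
#' table(g$labels)
#' @export
make_superpixel_grid <- function(height, width, n_target) {
  if (height < 1 || width < 1) stop_invalid("frame dimensions must be >= 1")
  if (n_target < 1 || n_target > height * width)
    stop_invalid("n_target must be in [1, height*width]")
  # choose a ny x nx tiling: prefer counts within 10% of target, then the
  # most square tiles, then the closest count
  best <- NULL
  for (ny in seq_len(min(n_target, height))) {
    nx <- max(1L, min(as.integer(round_half_up(n_target / ny)), width))
    cnt <- nx * ny
    rel <- abs(cnt - n_target) / n_target
    aspect <- max((height / ny) / (width / nx), (width / nx) / (height / ny))
    score <- c(rel > 0.1, aspect, rel)
    if (is.null(best) ||
        score[1] < best$score[1] ||
        (score[1] == best$score[1] && score[3] < best$score[3]) ||
        (score[1] == best$score[1] && score[3] == best$score[3] &&
         score[2] < best$score[2])) {
      best <- list(nx = nx, ny = ny, score = score)
    }
  }
  nx <- best$nx; ny <- best$ny
  rb <- floor(height * (0:ny) / ny)  # tile boundaries
  cb <- floor(width * (0:nx) / nx)
  row_lab <- rep(seq_len(ny), diff(rb))
  col_lab <- rep(seq_len(nx), diff(cb))
  labels <- matrix(0L, height, width)
  labels[] <- (rep(col_lab, each = height) - 1L) * ny + row_lab
  n <- nx * ny
  cy <- (rb[-1] + rb[-(ny + 1)] + 1) / 2  # 1-based pixel-center of each tile
  cx <- (cb[-1] + cb[-(nx + 1)] + 1) / 2
  centroids <- cbind(x = round_half_up(rep(cx, each = ny)),
                     y = round_half_up(rep(cy, times = nx)))
  structure(list(labels = labels, centroids = centroids,
                 avg_width = sqrt(height * width / n_target),
                 n = n, nx = nx, ny = ny,
                 height = height, width = width),
            class = "superpixel_grid")
}

#' @export
print.superpixel_grid <- function(x, ...) {
  cat(sprintf("superpixel_grid: %d superpixels (%d x %d tiling) on %d x %d px, avg width %.2f px\n",
              x$n, x$ny, x$nx, x$height, x$width, x$avg_width))
  invisible(x)
}

#' Dense optical-flow parameters
#'
#' Settings for the Farneback polynomial-expansion flow backend. The
#' defaults are the canonical ones for this estimator: a 3-level half-
#' resolution pyramid, a 15-pixel averaging window, 3 iterations per level
#' and an 11-tap (poly_n = 5) Gaussian expansion window of scale 1.2.
#'
#' @param pyr_scale pyramid downscale factor (only 0.5 is supported).
#' @param levels number of pyramid levels including the full resolution.
#' @param winsize side of the box window averaging the local normal
#'   equations, pixels.
#' @param iterations displacement refinement iterations per level.
#' @param poly_n half-width of the polynomial expansion window (window is
#'   `2 * poly_n + 1` pixels).
#' @param poly_sigma Gaussian weighting scale of the expansion window.
#' @return A list of class `flow_params`.
#' @export
flow_params <- function(pyr_scale = 0.5, levels = 3, winsize = 15,
                        iterations = 3, poly_n = 5, poly_sigma = 1.2) {
  if (!identical(as.numeric(pyr_scale), 0.5))
    stop_invalid("only pyr_scale = 0.5 is supported")
  if (levels < 1 || winsize < 1 || iterations < 1 || poly_n < 1 || poly_sigma <= 0)
    stop_invalid("flow parameters must be positive")
  structure(list(pyr_scale = 0.5, levels = as.integer(levels),
                 winsize = as.integer(winsize),
                 iterations = as.integer(iterations),
                 poly_n = as.integer(poly_n), poly_sigma = poly_sigma),
            class = "flow_params")
}

#' Estimate dense optical flow between two grayscale frames
#'
#' Farneback polynomial-expansion flow: each pixel neighbourhood of both
#' frames is approximated by a quadratic polynomial under Gaussian
#' weighting and the per-pixel displacement solving the matched expansions
#' is refined iteratively over an image pyramid. Deterministic for fixed
#' inputs and parameters.
#'
#' @param frame_a,frame_b numeric matrices (same shape, single channel).
#' @param params a [flow_params()] list.
#' @return An `(nrow, ncol, 2)` array: `[,,1]` is dx (columns, +x right),
#'   `[,,2]` is dy (rows, +y down), pixels per frame pair, mapping
#'   `frame_a(x) -> frame_b(x + d)`.
#' @export
estimate_flow <- function(frame_a, frame_b, params = flow_params()) {
  if (!is.matrix(frame_a) || !is.matrix(frame_b))
    stop_invalid("frames must be single-channel matrices")
  if (!identical(dim(frame_a), dim(frame_b)))
    stop_invalid("frames must share the same shape")
  if (!inherits(params, "flow_params")) params <- do.call(flow_params, params)
  flow <- .farneback_flow(frame_a, frame_b, params$levels, params$winsize,
                          params$iterations, params$poly_n, params$poly_sigma)
  dimnames(flow) <- list(NULL, NULL, c("dx", "dy"))
  flow
}

# frame-0 footprint pixel lists per superpixel (1-based rows/cols)
.grid_footprints <- function(grid) {
  idx <- which(grid$labels > 0L)
  lab <- grid$labels[idx]
  H <- nrow(grid$labels)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  list(rows = split(rr, factor(lab, levels = seq_len(grid$n))),
       cols = split(cc, factor(lab, levels = seq_len(grid$n))))
}

#' Propagate superpixel tracks through a sequence of flow fields
#'
#' Each superpixel's position is updated by the mean flow over its current
#' footprint: the frame-0 label mask translated by the integer cumulative
#' displacement and clipped to the frame (lost area is not recovered). By
#' default displacements are rounded to the nearest integer. A superpixel
#' whose footprint has fully left the frame holds its last position for
#' all later frames. In `"dense"` mode, new superpixels are spawned each
#' frame at the centers of vacated grid cells (see
#' [spawn_dense_superpixels()]).
#'
#' @param flows list of `(H, W, 2)` flow arrays, one per frame pair.
#' @param grid a [make_superpixel_grid()] partition.
#' @param mode `"fixed"` (constant superpixel count) or `"dense"`.
#' @param round round each displacement update to the nearest integer
#'   (default `TRUE`).
#' @return A track array: `(n_superpixels, n_frames, 2)` of `(x, y)` pixel
#'   coordinates with attributes `origin` (`"fixed"` or `"dense-spawned"`
#'   per superpixel) and `spawn_frame` (1 for fixed superpixels).
#' @export
propagate_tracks <- function(flows, grid, mode = c("fixed", "dense"),
                             round = TRUE) {
  mode <- match.arg(mode)
  if (length(flows) < 1) stop_invalid("empty flow sequence")
  fp <- .grid_footprints(grid)
  n <- grid$n
  T_ <- length(flows) + 1L
  pos <- array(NA_real_, c(n, T_, 2))
  pos[, 1, ] <- grid$centroids
  origin <- rep("fixed", n)
  spawn_frame <- rep(1L, n)
  start_pos <- grid$centroids          # footprint anchor per superpixel
  base_sp <- seq_len(n)                # which grid cell supplies the mask
  frozen <- rep(FALSE, n)
  for (t in seq_along(flows)) {
    cur <- matrix(pos[, t, ], ncol = 2)
    off <- round(cur - start_pos)
    mf <- .footprint_mean_flow(flows[[t]],
                               fp$rows[base_sp], fp$cols[base_sp],
                               matrix(as.integer(off), ncol = 2))
    step <- mf[, 1:2, drop = FALSE]
    if (round) step <- round(step)
    newly_lost <- !frozen & mf[, 3] == 0
    frozen <- frozen | newly_lost
    step[frozen, ] <- 0
    pos[, t + 1L, ] <- cur + step
    if (mode == "dense") {
      spawned <- .vacant_cells(matrix(pos[, t + 1L, ], ncol = 2), grid)
      if (length(spawned)) {
        m <- length(spawned)
        add <- array(NA_real_, c(m, T_, 2))
        for (k in seq_len(m)) {
          add[k, , 1] <- grid$centroids[spawned[k], 1]
          add[k, , 2] <- grid$centroids[spawned[k], 2]
        }
        pos2 <- array(NA_real_, c(n + m, T_, 2))
        pos2[seq_len(n), , ] <- pos
        pos2[n + seq_len(m), , ] <- add
        pos <- pos2
        origin <- c(origin, rep("dense-spawned", m))
        spawn_frame <- c(spawn_frame, rep(t + 1L, m))
        start_pos <- rbind(start_pos, grid$centroids[spawned, , drop = FALSE])
        base_sp <- c(base_sp, spawned)
        frozen <- c(frozen, rep(FALSE, m))
        n <- n + m
      }
    }
  }
  attr(pos, "origin") <- origin
  attr(pos, "spawn_frame") <- spawn_frame
  pos
}

# grid cells whose area contains no current superpixel centroid
.vacant_cells <- function(positions, grid) {
  H <- grid$height; W <- grid$width
  x <- round(positions[, 1]); y <- round(positions[, 2])
  inb <- x >= 1 & x <= W & y >= 1 & y <= H
  occupied <- unique(grid$labels[cbind(y[inb], x[inb])])
  setdiff(seq_len(grid$n), occupied)
}

#' Spawn dense-trajectory superpixels in vacated grid cells
#'
#' Grid cells whose area no longer contains any current superpixel centroid
#' at the given frame receive a fresh superpixel seeded at the cell center.
#' Spawned tracks carry their spawn frame and are back-filled with the
#' spawn position for earlier frames, so all tracks share the full frame
#' range.
#'
#' @param tracks a track array from [propagate_tracks()].
#' @param grid the [make_superpixel_grid()] partition.
#' @param frame 1-based frame index at which to test occupancy.
#' @return The augmented track array (superpixel count never decreases).
#' @export
spawn_dense_superpixels <- function(tracks, grid, frame) {
  if (frame < 1 || frame > dim(tracks)[2]) stop_invalid("frame out of range")
  cur <- matrix(tracks[, frame, ], ncol = 2)
  spawned <- .vacant_cells(cur, grid)
  if (!length(spawned)) return(tracks)
  n <- dim(tracks)[1]; T_ <- dim(tracks)[2]; m <- length(spawned)
  out <- array(NA_real_, c(n + m, T_, 2))
  out[seq_len(n), , ] <- tracks
  for (k in seq_len(m)) {
    out[n + k, , 1] <- grid$centroids[spawned[k], 1]
    out[n + k, , 2] <- grid$centroids[spawned[k], 2]
  }
  attr(out, "origin") <- c(attr(tracks, "origin") %||% rep("fixed", n),
                           rep("dense-spawned", m))
  attr(out, "spawn_frame") <- c(attr(tracks, "spawn_frame") %||% rep(1L, n),
                                rep(as.integer(frame), m))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Track all channels of a video with superpixel optical flow
#'
#' Convenience wrapper running [make_superpixel_grid()], [estimate_flow()]
#' on consecutive frame pairs and [propagate_tracks()] independently for
#' each requested channel.
#'
#' @param video a `(time, row, col, channel)` array (a `video_stack`).
#' @param n_superpixels target superpixel count (1000 reproduces the
#'   original study setting on full-size frames).
#' @param channels channel indices to track (default: all).
#' @param params [flow_params()].
#' @param mode,round passed to [propagate_tracks()].
#' @return A list with `tracks` (one track array per channel), `grid`, and
#'   `params`.
#' @export
track_video <- function(video, n_superpixels = 1000, channels = NULL,
                        params = flow_params(), mode = "fixed", round = TRUE) {
  d <- dim(video)
  if (length(d) != 4) stop_invalid("video must be a (time, row, col, channel) array")
  if (d[1] < 2) stop_invalid("video needs at least 2 frames")
  if (is.null(channels)) channels <- seq_len(d[4])
  grid <- make_superpixel_grid(d[2], d[3], n_superpixels)
  tracks <- lapply(channels, function(ch) {
    flows <- lapply(seq_len(d[1] - 1), function(t)
      estimate_flow(matrix(video[t, , , ch], d[2], d[3]),
                    matrix(video[t + 1, , , ch], d[2], d[3]), params))
    propagate_tracks(flows, grid, mode = mode, round = round)
  })
  names(tracks) <- paste0("channel", channels)
  list(tracks = tracks, grid = grid, params = params)
}
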