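# Ground-truthed synthetic inputs: point-process tracks with known MSD
# regimes, rendered two-channel sheet videos with scripted outcomes, and
# saliency-map fixtures exercising the boundary-formation semantics.

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate 2-D Brownian (Gaussian random walk) tracks
#'
#' Independent i.i.d. Gaussian steps of scale `sigma` per coordinate; the
#' diffusive reference for MSD fitting (`alpha = 1`).
#'
#' @param n number of tracks.
#' @param n_frames track length in frames.
#' @param sigma per-step standard deviation, pixels (0 gives static
#'   tracks).
#' @param seed RNG seed.
#' @param span side of the square in which start positions are drawn.
#' @return `(n, n_frames, 2)` track array.
#' @export
simulate_brownian_tracks <- function(n, n_frames, sigma = 1, seed = 0,
                                     span = 512) {
  with_seed(seed, {
    start <- cbind(runif(n, 1, span), runif(n, 1, span))
    steps <- array(rnorm(n * (n_frames - 1) * 2, sd = sigma),
                   c(n, n_frames - 1, 2))
    pos <- array(0, c(n, n_frames, 2))
    pos[, 1, ] <- start
    for (t in 2:n_frames) pos[, t, ] <- pos[, t - 1, ] + steps[, t - 1, ]
    pos
  })
}

#' Simulate ballistic (constant-heading, constant-speed) tracks
#'
#' Each track keeps a fixed random heading and moves `speed` pixels per
#' frame; the ballistic reference for MSD fitting (`alpha = 2`) with
#' `RMSD(t) = speed * t` exactly.
#'
#' @inheritParams simulate_brownian_tracks
#' @param speed pixels per frame.
#' @return `(n, n_frames, 2)` track array.
#' @export
simulate_ballistic_tracks <- function(n, n_frames, speed = 1, seed = 0,
                                      span = 512) {
  with_seed(seed, {
    start <- cbind(runif(n, 1, span), runif(n, 1, span))
    theta <- runif(n, 0, 2 * pi)
    pos <- array(0, c(n, n_frames, 2))
    for (t in seq_len(n_frames)) {
      pos[, t, 1] <- start[, 1] + speed * (t - 1) * cos(theta)
      pos[, t, 2] <- start[, 2] + speed * (t - 1) * sin(theta)
    }
    pos
  })
}

#' Specification of a synthetic two-sheet closure video
#'
#' Describes two textured epithelial sheets migrating toward each other
#' across a central gap, with scripted post-contact behaviour:
#' `"coalesce"` (sheets briefly interpenetrate, then all motion stops),
#' `"stable_boundary"` (fronts arrest at the contact line while the rear
#' keeps compressing toward it with decaying speed, forming a persistent
#' boundary) or `"push_through"` (the red sheet keeps advancing,
#' displacing the green sheet).
#'
#' @param scenario one of `"coalesce"`, `"stable_boundary"`,
#'   `"push_through"`.
#' @param height,width frame size, pixels.
#' @param gap initial gap width between the fronts, pixels (must be
#'   smaller than `width`).
#' @param speed_red,speed_green front speeds, pixels/frame (> 0).
#' @param grain texture blob scale, pixels.
#' @param noise_sd per-frame additive Gaussian intensity noise (images are
#'   on `[0, 1]`).
#' @param n_frames video length; default twice the approach time plus 10
#'   frames of post-contact behaviour.
#' @param seed texture/noise seed.
#' @return A `scenario_spec` list.
#' @export
scenario_spec <- function(scenario = c("stable_boundary", "coalesce",
                                       "push_through"),
                          height = 96, width = 192, gap = 64,
                          speed_red = 2, speed_green = 2, grain = 8,
                          noise_sd = 0.01, n_frames = NULL, seed = 0) {
  scenario <- match.arg(scenario)
  if (gap >= width) stop_invalid("gap must be smaller than the frame width")
  if (speed_red <= 0 || speed_green <= 0) stop_invalid("speeds must be > 0")
  approach <- ceiling(gap / (speed_red + speed_green))
  if (is.null(n_frames)) n_frames <- 2 * approach + 10
  structure(list(scenario = scenario, height = height, width = width,
                 gap = gap, speed_red = speed_red, speed_green = speed_green,
                 grain = grain, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "scenario_spec")
}

# blob texture: thresholded low-pass noise so optical flow has structure
.blob_texture <- function(h, w, grain) {
  noise <- matrix(runif(h * w), h, w)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(noise),
                                          sigma = grain / 2))
  blobs <- sm > median(sm)
  0.45 + 0.45 * blobs + 0.1 * matrix(runif(h * w), h, w)
}

# sample texture columns at fractional source positions (linear interp)
.sample_tex <- function(tex, src) {
  src <- pmin(pmax(src, 1), ncol(tex))
  lo <- floor(src)
  hi <- pmin(lo + 1, ncol(tex))
  wgt <- src - lo
  tex[, lo, drop = FALSE] * rep(1 - wgt, each = nrow(tex)) +
    tex[, hi, drop = FALSE] * rep(wgt, each = nrow(tex))
}

# Source-column map of a semi-infinite sheet advancing rightward from the
# left edge (texture feeds in from the edge). Returns source columns for
# image columns 1..front (others NA).
#  approach:  rigid translation, front = f0 + v*dt capped at the contact
#             column.
#  stable:    front arrested; rear influx decays (time scale tau) and the
#             absorbed material piles into a 3x-compressed boundary layer.
#  push:      rigid translation continues; the front keeps advancing.
#  compress:  no further influx; the visible sheet between the (moving)
#             front and the anchored rear is compressed linearly.
#  coalesce:  rigid translation for a few more frames (interpenetration),
#             then rest.
.sheet_source_map <- function(width, t, tc, v, f0, cx, off0, scenario,
                              tau = 5, kappa = 3, grain = 8,
                              front_cap = width - 2) {
  shift_tc <- cx - f0
  if (t <= tc) {
    shift <- min(v * (t - 1), shift_tc)
    front <- f0 + shift
    s <- seq_len(floor(front)) + off0 - shift
    return(list(src = s, front = front))
  }
  dt <- t - tc
  if (scenario == "stable") {
    influx <- v * tau * (1 - exp(-dt / tau))
    layer <- influx / (kappa - 1)
    front <- cx
    x <- seq_len(floor(front))
    s <- x + off0 - shift_tc - influx
    inlayer <- x > front - layer
    s[inlayer] <- (front + off0 - shift_tc) - kappa * (front - x[inlayer])
    list(src = s, front = front)
  } else if (scenario == "push") {
    shift <- shift_tc + v * dt
    front <- min(cx + v * dt, front_cap)
    s <- seq_len(floor(front)) + off0 - shift
    list(src = s, front = front)
  } else if (scenario == "compress") {
    # front pushed back by the opposing sheet at speed v_push (carried in
    # attr): no further influx; the frozen source range is squeezed
    # linearly between the anchored rear and the retreating front
    v_push <- attr(scenario, "v_push")
    front <- max(cx - v_push * dt, grain + 1)
    x <- seq_len(floor(front))
    s_lo <- 1 + off0 - shift_tc
    s_hi <- cx + off0 - shift_tc
    s <- s_lo + (x - 1) * (s_hi - s_lo) / max(front - 1, 1)
    list(src = s, front = front)
  } else {  # coalesce
    pen <- pmin(v * dt, grain)
    shift <- shift_tc + pen
    front <- cx + pen
    s <- seq_len(floor(front)) + off0 - shift
    list(src = s, front = front)
  }
}

#' Render a two-channel synthetic sheet-closure video with ground truth
#'
#' Two granular-texture sheets (one per channel) advance toward each other
#' with a linear displacement ramp (anchored at the frame edges, fastest
#' at the fronts), meet, and then follow the scripted scenario. No
#' mechanics are simulated: kinematics are prescribed monotone column maps
#' of the frame-0 texture.
#'
#' @param spec a [scenario_spec()].
#' @return List with `video` (`(T, H, W, 2)` array on `[0, 1]`; channel 1
#'   red, channel 2 green) and `truth` (class `sheet_truth`): closure
#'   frame (1-based; the approach takes `gap / (speed_red + speed_green)`
#'   frame steps), per-frame interface column `boundary_x`, and per-frame
#'   front positions `front_red`, `front_green`.
#' @export
render_two_sheet_video <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width; T_ <- spec$n_frames
    vr <- spec$speed_red; vg <- spec$speed_green
    f0r <- floor((W - spec$gap) / 2)    # initial red front column
    f0g <- W - f0r + 1                  # initial green front column (gap between)
    steps_to_close <- (f0g - 1 - f0r) / (vr + vg)
    tc <- 1 + ceiling(steps_to_close)   # 1-based contact frame
    cx <- f0r + (f0g - 1 - f0r) * vr / (vr + vg)  # contact column
    cxg <- W + 1 - (cx + 1)             # contact column in mirrored green coords
    off0 <- ceiling(max(vr, vg) * T_) + spec$grain
    tex_r <- .blob_texture(H, W + off0, spec$grain)
    tex_g <- .blob_texture(H, W + off0, spec$grain)
    # faint static background texture anchors the flow where no sheet is
    bg_r <- 0.03 + 0.04 * .blob_texture(H, W, spec$grain)
    bg_g <- 0.03 + 0.04 * .blob_texture(H, W, spec$grain)
    sc_red <- switch(spec$scenario, stable_boundary = "stable",
                     push_through = "push", coalesce = "coalesce")
    sc_green <- switch(spec$scenario, stable_boundary = "stable",
                       push_through = "compress", coalesce = "coalesce")
    if (sc_green == "compress") attr(sc_green, "v_push") <- vr
    video <- array(0, c(T_, H, W, 2))
    front_r <- front_g <- numeric(T_)
    for (t in seq_len(T_)) {
      mr <- .sheet_source_map(W, t, tc, vr, f0r, cx, off0, sc_red,
                              grain = spec$grain)
      mg <- .sheet_source_map(W, t, tc, vg, W + 1 - f0g, cxg, off0, sc_green,
                              grain = spec$grain)
      ch_r <- bg_r
      ch_r[, seq_along(mr$src)] <- pmax(.sample_tex(tex_r, mr$src),
                                        bg_r[, seq_along(mr$src)])
      ch_g <- bg_g
      gcols <- W + 1 - seq_along(mg$src)  # mirrored back to image coords
      ch_g[, gcols] <- pmax(.sample_tex(tex_g, mg$src), bg_g[, gcols])
      if (spec$noise_sd > 0) {
        ch_r <- ch_r + matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
        ch_g <- ch_g + matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
      }
      video[t, , , 1] <- pmin(pmax(ch_r, 0), 1)
      video[t, , , 2] <- pmin(pmax(ch_g, 0), 1)
      front_r[t] <- mr$front
      front_g[t] <- W + 1 - mg$front
    }
    truth <- structure(list(closure_frame = tc,
                            boundary_x = (front_r + front_g) / 2,
                            front_red = front_r, front_green = front_g,
                            height = H, width = W, scenario = spec$scenario),
                       class = "sheet_truth")
    list(video = video, truth = truth)
  })
}

#' Ground-truth sheet masks of a synthetic video
#'
#' @param truth the `sheet_truth` from [render_two_sheet_video()].
#' @param frame 1-based frame index.
#' @return List of logical `height x width` masks, `red` and `green`.
#' @export
truth_masks <- function(truth, frame) {
  W <- truth$width
  cols <- seq_len(W)
  list(red = matrix(rep(cols <= truth$front_red[frame], each = truth$height),
                    truth$height, W),
       green = matrix(rep(cols >= truth$front_green[frame], each = truth$height),
                      truth$height, W))
}

#' Saliency-map fixtures with known boundary-formation scores
#'
#' Archetypal motion saliency maps: a spatially `"constant"` map (uniform
#' motion, index 0), a single high-valued `"line"` on zero background
#' (index 1), a single `"point"` spot, and `"multi_spot"` (two separated
#' spots, which score below a single line of equal mass).
#'
#' @param kind map archetype.
#' @param size `c(height, width)` in pixels.
#' @param low,high the two intensity levels.
#' @return A `saliency_map` matrix.
#' @export
make_saliency_fixture <- function(kind = c("constant", "line", "point",
                                           "multi_spot"),
                                  size = c(64, 64), low = 0, high = 10) {
  kind <- match.arg(kind)
  H <- size[1]; W <- size[2]
  map <- matrix(low + high * 0.0, H, W)
  if (kind == "constant") {
    map[] <- high
  } else if (kind == "line") {
    cols <- seq(floor(W / 2) - max(1, floor(W / 32)),
                floor(W / 2) + max(1, floor(W / 32)))
    map[] <- low
    map[, cols] <- high
  } else if (kind == "point") {
    r <- max(2, floor(min(H, W) / 16))
    map[] <- low
    map[seq(floor(H / 2) - r, floor(H / 2) + r),
        seq(floor(W / 2) - r, floor(W / 2) + r)] <- high
  } else {
    # two spots sharing the mass of the single line: half peak height each
    # (split motion hotspots halve the neighbour counts)
    r <- max(2, floor(min(H, W) / 16))
    map[] <- low
    map[seq(floor(H / 4) - r, floor(H / 4) + r),
        seq(floor(W / 4) - r, floor(W / 4) + r)] <- low + (high - low) / 2
    map[seq(floor(3 * H / 4) - r, floor(3 * H / 4) + r),
        seq(floor(3 * W / 4) - r, floor(3 * W / 4) + r)] <- low + (high - low) / 2
  }
  structure(map, class = c("saliency_map", "matrix", "array"))
}
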