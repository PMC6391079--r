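# Shared fixtures and independent brute-force oracles used across tests.

# Rigid-translation tracks over a regular lattice of points.
rigid_tracks <- function(nx = 8, ny = 8, n_frames = 20, v = c(3, -2),
                         spacing = 10) {
  pts <- as.matrix(expand.grid(x = spacing * seq_len(nx),
                               y = spacing * seq_len(ny)))
  n <- nrow(pts)
  pos <- array(0, c(n, n_frames, 2))
  for (t in seq_len(n_frames)) {
    pos[, t, 1] <- pts[, 1] + v[1] * (t - 1)
    pos[, t, 2] <- pts[, 2] + v[2] * (t - 1)
  }
  pos
}

# Brute-force track propagation: explicit mask translation + averaging.
oracle_propagate <- function(flows, grid, round_steps = TRUE) {
  H <- grid$height; W <- grid$width; n <- grid$n
  T_ <- length(flows) + 1
  pos <- array(NA_real_, c(n, T_, 2))
  pos[, 1, ] <- grid$centroids
  frozen <- rep(FALSE, n)
  masks <- lapply(seq_len(n), function(i)
    which(grid$labels == i, arr.ind = TRUE))
  for (t in seq_along(flows)) {
    for (i in seq_len(n)) {
      if (frozen[i]) { pos[i, t + 1, ] <- pos[i, t, ]; next }
      off <- round(pos[i, t, ] - pos[i, 1, ])
      rr <- masks[[i]][, 1] + off[2]
      cc <- masks[[i]][, 2] + off[1]
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      if (!any(ok)) { frozen[i] <- TRUE; pos[i, t + 1, ] <- pos[i, t, ]; next }
      step <- c(mean(flows[[t]][cbind(rr[ok], cc[ok], 1)]),
                mean(flows[[t]][cbind(rr[ok], cc[ok], 2)]))
      if (round_steps) step <- round(step)
      pos[i, t + 1, ] <- pos[i, t, ] + step
    }
  }
  pos
}

# Brute-force O(n^2) adjacency within a radius (inclusive).
oracle_radius_adjacency <- function(positions, radius) {
  n <- nrow(positions)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j &&
        sqrt(sum((positions[i, ] - positions[j, ])^2)) <= radius)
      adj[i, j] <- TRUE
  }
  adj
}

mesh_to_adjacency <- function(mesh) {
  n <- mesh$n
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) adj[i, mesh$neighbours[[i]]] <- TRUE
  adj
}

# Brute-force double-loop mesh strain curve.
oracle_strain_curve <- function(tracks, mesh) {
  n <- dim(tracks)[1]; T_ <- dim(tracks)[2]
  eps <- matrix(0, n, T_)
  for (i in seq_len(n)) {
    js <- mesh$neighbours[[i]]
    if (!length(js)) next
    for (t in seq_len(T_)) {
      acc <- 0
      for (j in js) {
        d0 <- sqrt(sum((tracks[i, 1, ] - tracks[j, 1, ])^2))
        dt <- sqrt(sum((tracks[i, t, ] - tracks[j, t, ])^2))
        acc <- acc + abs(dt - d0)
      }
      eps[i, t] <- acc / length(js)
    }
  }
  deg <- lengths(mesh$neighbours)
  colMeans(eps[deg > 0, , drop = FALSE])
}

# Smoothly varying synthetic flow fields for oracle-equivalence tests.
smooth_flow_sequence <- function(H, W, n_flows, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_flows), function(t) {
    f <- array(0, c(H, W, 2))
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    f[, , 1] <- 1.5 * sin(2 * pi * rr / H + t / 3) +
      0.8 * cos(2 * pi * cc / W)
    f[, , 2] <- 1.2 * cos(2 * pi * cc / W - t / 4) +
      0.5 * sin(2 * pi * rr / H)
    f
  })
}

# Planted two-group strain dynamics: two lattices farther apart than the
# mesh radius (so local strain curves stay group-pure); one group is
# still, the other expands about its own centroid.
planted_strain_fixture <- function(seed, n_frames = 25, rate = 0.08,
                                   noise = 0.05) {
  set.seed(seed)
  lat <- as.matrix(expand.grid(x = 10 * (1:10), y = 10 * (1:10)))
  pos <- rbind(lat, cbind(lat[, 1] + 150, lat[, 2]))
  n <- nrow(pos)
  strainers <- (nrow(lat) + 1):n
  ctr <- colMeans(pos[strainers, ])
  tr <- array(0, c(n, n_frames, 2))
  tr[, 1, ] <- pos
  for (t in 2:n_frames) {
    tr[, t, ] <- tr[, t - 1, ]
    tr[strainers, t, 1] <- tr[strainers, t, 1] + rate * (pos[strainers, 1] - ctr[1])
    tr[strainers, t, 2] <- tr[strainers, t, 2] + rate * (pos[strainers, 2] - ctr[2])
    tr[, t, ] <- tr[, t, ] + matrix(rnorm(2 * n, 0, noise), n, 2)
  }
  list(tracks = tr, truth = as.integer(seq_len(n) %in% strainers),
       avg_width = 10)
}

# Textured frame pair with a known integer circular shift.
shifted_pair <- function(H = 120, W = 160, shift = c(3, 0), seed = 1) {
  set.seed(seed)
  tex <- matrix(runif(H * W), H, W)
  tex <- EBImage::imageData(EBImage::gblur(EBImage::Image(tex), 2))
  shifted <- tex
  if (shift[1] != 0) {
    k <- shift[1] %% W
    shifted <- cbind(shifted[, (W - k + 1):W], shifted[, 1:(W - k)])
  }
  if (shift[2] != 0) {
    k <- shift[2] %% H
    shifted <- rbind(shifted[(H - k + 1):H, ], shifted[1:(H - k), ])
  }
  list(a = tex, b = shifted)
}
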