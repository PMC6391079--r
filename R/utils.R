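# classed error helpers so callers can distinguish bad arguments from
# degenerate (but well-formed) inputs and file-format problems

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("motionmesh_invalid_argument",
                                     "motionmesh_error", "error", "condition")))
}

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("motionmesh_degenerate_input",
                                     "motionmesh_error", "error", "condition")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("motionmesh_format_error",
                                     "motionmesh_error", "error", "condition")))
}

# deterministic half-up rounding (base round() is half-to-even); tracks use
# base round for displacements, this is for grid geometry
round_half_up <- function(x) floor(x + 0.5)

# Euclidean distance matrix between rows of two n x 2 matrices
pdist2 <- function(a, b = a) {
  da <- outer(a[, 1], b[, 1], "-")
  db <- outer(a[, 2], b[, 2], "-")
  sqrt(da^2 + db^2)
}

# velocities V(t) = r(t+1) - r(t): (n, T-1, 2) from (n, T, 2)
track_velocities <- function(positions) {
  T_ <- dim(positions)[2]
  if (T_ < 2) stop_invalid("need at least 2 frames to form velocities")
  positions[, 2:T_, , drop = FALSE] - positions[, 1:(T_ - 1), , drop = FALSE]
}

is_track_array <- function(x) is.array(x) && length(dim(x)) == 3 && dim(x)[3] == 2
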