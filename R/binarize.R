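#' Binarization parameters
#'
#' The triplet (zeta, visual field, delta) that turns a trajectory into
#' per-individual ON/OFF states:
#' * `zeta` — interaction radius in mm; an individual is distance-ON when
#'   some other individual is strictly closer than `zeta`.
#' * `visual_field` — total visual field in rad, up to 2*pi. The half-angle
#'   `eta = visual_field / 2` is compared with the angle between the focal
#'   heading and the direction to a neighbour (strict `<`), so anything less
#'   than 2*pi leaves a rear blind spot, and 2*pi is always ON.
#' * `delta` — turning threshold in rad per step, compared non-strictly
#'   (`>=`) with the angle between consecutive headings; 0 is always ON.
#'
#' `visual_vector` selects the vector convention for the visual-field test:
#' `"to_neighbour"` (default) uses x_j - x_i, the direction from the focal
#' individual to the neighbour, which makes a reduced visual field a rear
#' blind spot; `"as_printed"` uses the opposite sign, x_i - x_j.
#'
#' @param zeta Distance threshold, mm (> 0).
#' @param visual_field Visual field, rad in (0, 2*pi].
#' @param delta Turning-rate threshold, rad per step (>= 0). Thresholds
#'   quoted in rad/s convert by multiplying by `dt`.
#' @param dt Time step of the (resampled) trajectory, seconds.
#' @param visual_vector Visual-field vector convention, see Details.
#' @return A list of class `binarization_params`.
#' @export
binarization_params <- function(zeta, visual_field = 2 * pi, delta = 0, dt = 0.05,
                                visual_vector = c("to_neighbour", "as_printed")) {
  visual_vector <- match.arg(visual_vector)
  if (!is.numeric(zeta) || zeta <= 0) abort("`zeta` must be > 0 (mm)")
  if (visual_field <= 0 || visual_field > 2 * pi + 1e-9) {
    abort("`visual_field` must lie in (0, 2*pi] rad")
  }
  if (delta < 0) abort("`delta` must be >= 0 (rad per step)")
  if (dt <= 0) abort("`dt` must be > 0 (s)")
  structure(list(zeta = zeta, visual_field = visual_field,
                 eta = visual_field / 2, delta = delta, dt = dt,
                 visual_vector = visual_vector),
            class = "binarization_params")
}

#' Distance states at one step
#'
#' An individual is ON iff some other individual is strictly within `zeta`
#' mm. The interaction is symmetric.
#'
#' @param positions An N x 2 matrix of coordinates (mm) at one step.
#' @param zeta Distance threshold in mm.
#' @return Integer vector of N bits.
#' @export
distance_state <- function(positions, zeta) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) abort("distance state needs at least 2 individuals")
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  as.integer(apply(d < zeta, 1, any))
}

#' Visual-field states at one step
#'
#' An individual is ON iff some other individual lies strictly within the
#' half-angle `eta` of its heading. With the default `"to_neighbour"`
#' convention the tested vector is x_j - x_i. Individuals with an undefined
#' (NA) heading are returned OFF and counted in the `n_undefined_heading`
#' attribute. `eta >= pi` (full 2*pi visual field) is always ON.
#'
#' @param positions N x 2 coordinate matrix (mm).
#' @param headings N x 2 unit-heading matrix (rows may be NA).
#' @param eta Half-angle threshold in rad, in `[0, pi]`.
#' @param visual_vector `"to_neighbour"` or `"as_printed"`.
#' @return Integer vector of N bits.
#' @export
visual_state <- function(positions, headings, eta,
                         visual_vector = c("to_neighbour", "as_printed")) {
  visual_vector <- match.arg(visual_vector)
  positions <- as.matrix(positions)
  headings <- as.matrix(headings)
  n <- nrow(positions)
  if (n < 2) abort("visual state needs at least 2 individuals")
  out <- integer(n)
  n_undef <- 0L
  full <- eta >= pi - 1e-12
  for (i in seq_len(n)) {
    if (is.na(headings[i, 1]) || is.na(headings[i, 2])) {
      n_undef <- n_undef + 1L
      out[i] <- 0L
      next
    }
    if (full) { out[i] <- 1L; next }
    j <- setdiff(seq_len(n), i)
    vx <- positions[j, 1] - positions[i, 1]
    vy <- positions[j, 2] - positions[i, 2]
    if (visual_vector == "as_printed") { vx <- -vx; vy <- -vy }
    ang <- vec_angle(headings[i, 1], headings[i, 2], vx, vy)
    out[i] <- as.integer(any(ang < eta, na.rm = TRUE))
  }
  structure(out, n_undefined_heading = n_undef)
}

#' Turning-rate states at one step
#'
#' ON iff the angle between the current and previous heading is at least
#' `delta` (non-strict), so `delta = 0` is always ON.
#'
#' @param heading_t,heading_prev N x 2 unit-heading matrices.
#' @param delta Threshold in rad per step.
#' @return Integer vector of N bits.
#' @export
turning_state <- function(heading_t, heading_prev, delta) {
  heading_t <- as.matrix(heading_t)
  heading_prev <- as.matrix(heading_prev)
  ang <- vec_angle(heading_t[, 1], heading_t[, 2], heading_prev[, 1], heading_prev[, 2])
  # small tolerance keeps the non-strict boundary robust to acos rounding
  as.integer(!is.na(ang) & ang >= delta - 1e-12)
}

#' Binarize a trajectory into a collective ON/OFF state series
#'
#' Each individual's state at each step is the conjunction (AND) of its
#' distance, visual-field and turning-rate states. Turning needs two
#' consecutive headings and headings need one displacement, so states start
#' at the trajectory's third frame.
#'
#' @param traj A `school_traj` tibble, already resampled to `params$dt`.
#' @param params A [binarization_params()] object.
#' @return A tibble of class `state_series` with columns `t` (frame index)
#'   and `s1 ... sN`; attributes `params` and `n`.
#' @export
binarize <- function(traj, params) {
  stopifnot(inherits(params, "binarization_params"))
  fr <- attr(traj, "frame_rate")
  if (abs(1 / fr - params$dt) > 1e-8) {
    abort(sprintf("trajectory step (%g s) does not match params$dt (%g s); resample first",
                  1 / fr, params$dt))
  }
  n <- attr(traj, "n")
  ids <- attr(traj, "ids")
  frames <- sort(unique(traj$frame))
  if (length(frames) < 3) abort("need at least 3 frames to binarize (turning rate)")
  hd <- derive_headings(traj)

  pos_arr <- array(NA_real_, c(length(frames), n, 2))
  for (k in seq_along(ids)) {
    d <- dplyr::arrange(dplyr::filter(traj, .data$id == ids[k]), .data$frame)
    pos_arr[, k, 1] <- d$x
    pos_arr[, k, 2] <- d$y
  }
  hd_arr <- array(NA_real_, c(length(frames), n, 2))
  for (k in seq_along(ids)) {
    d <- dplyr::arrange(dplyr::filter(hd, .data$id == ids[k]), .data$frame)
    idx <- match(d$frame, frames)
    hd_arr[idx, k, 1] <- d$hx
    hd_arr[idx, k, 2] <- d$hy
  }

  steps <- 3:length(frames)  # headings defined from 2, turning from 3
  states <- matrix(0L, length(steps), n)
  for (r in seq_along(steps)) {
    tix <- steps[r]
    pos <- pos_arr[tix, , , drop = TRUE]
    h_t <- hd_arr[tix, , , drop = TRUE]
    h_p <- hd_arr[tix - 1, , , drop = TRUE]
    if (n == 1) abort("binarization needs at least 2 individuals")
    dim(pos) <- c(n, 2); dim(h_t) <- c(n, 2); dim(h_p) <- c(n, 2)
    db <- distance_state(pos, params$zeta)
    vb <- visual_state(pos, h_t, params$eta, params$visual_vector)
    tb <- turning_state(h_t, h_p, params$delta)
    states[r, ] <- db & vb & tb
  }
  out <- tibble::as_tibble(as.data.frame(states))
  names(out) <- paste0("s", seq_len(n))
  out <- dplyr::bind_cols(tibble::tibble(t = frames[steps]), out)
  structure(out, params = params, n = n,
            class = c("state_series", class(tibble::tibble())))
}

#' Assemble a state series from a binary matrix
#'
#' Mostly for simulated or hand-built fixtures: wraps a T x N 0/1 matrix in
#' the `state_series` container used by the estimation and information
#' functions.
#'
#' @param states A T x N matrix (or data frame) of 0/1 states.
#' @param params Optional [binarization_params()] to attach.
#' @return A `state_series` tibble.
#' @export
as_state_series <- function(states, params = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) abort("states must be 0/1")
  if (nrow(states) < 2) abort("state series must have at least 2 steps")
  n <- ncol(states)
  out <- tibble::as_tibble(as.data.frame(matrix(as.integer(states), nrow(states), n)))
  names(out) <- paste0("s", seq_len(n))
  out <- dplyr::bind_cols(tibble::tibble(t = seq_len(nrow(states))), out)
  structure(out, params = params, n = n,
            class = c("state_series", class(tibble::tibble())))
}

#' Extract the T x N state matrix from a state series
#' @param series A `state_series` tibble.
#' @return Integer matrix with one column per individual.
#' @export
state_matrix <- function(series) {
  n <- attr(series, "n")
  as.matrix(series[, paste0("s", seq_len(n))])
}

#' Write / read a state series as CSV with a YAML parameter sidecar
#'
#' @param series A `state_series` tibble.
#' @param path CSV path; the sidecar is written to `<path>.yml`.
#' @return `path`, invisibly (`read_state_series` returns the series).
#' @export
write_state_series <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path)
  p <- attr(series, "params")
  if (!is.null(p)) {
    yaml::write_yaml(unclass(p), paste0(path, ".yml"))
  }
  invisible(path)
}

#' @rdname write_state_series
#' @export
read_state_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  params <- NULL
  side <- paste0(path, ".yml")
  if (file.exists(side)) {
    params <- do.call(binarization_params,
                      yaml::read_yaml(side)[c("zeta", "visual_field", "delta", "dt",
                                              "visual_vector")])
  }
  out <- as_state_series(df[, grep("^s[0-9]+$", names(df)), drop = FALSE], params)
  out$t <- df$t
  out
}
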