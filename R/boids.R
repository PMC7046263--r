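#' Boids model parameters
#'
#' Zonal flocking model with repulsion (radius `R`), alignment (radius `O`)
#' and attraction (shell `O..A`) rules, each scaled by the coupling
#' strength `C`, in a continuous 3000 x 2500 mm arena with reflective
#' walls. Defaults reproduce the simulation settings used to emulate small
#' fish schools: R = 10 mm (one body length), O = 120 mm (the observed
#' 80-140 mm neighbour distances), A = Inf, and per-group-size speeds and
#' heading-noise standard deviations:
#'
#' | n | v (mm/step) | noise sd (rad) |
#' |---|-------------|----------------|
#' | 2 | 11.1        | 0.20           |
#' | 3 | 12.4        | 0.17           |
#' | 4 | 8.47        | 0.21           |
#' | 5 | 10.2        | 0.23           |
#'
#' Speeds are displacements per time step: real-fish velocities of
#' 150-340 mm/s at dt = 0.05 s give 7-17 mm per step, matching these
#' magnitudes.
#'
#' @param n Number of agents (2-5 have tabulated defaults; other sizes
#'   need explicit `v` and `noise_sd`).
#' @param R,O,A Zone radii in mm, 0 < R <= O <= A.
#' @param v Speed, mm per step.
#' @param coupling Coupling strength C >= 0 applied to all three rules.
#' @param noise_sd Standard deviation of the Gaussian heading noise, rad.
#' @param dt Time step, s.
#' @param arena Arena width and height, mm.
#' @param boundary `"reflect"` (default) or `"wrap"`.
#' @return A list of class `boids_params`.
#' @export
boids_params <- function(n, R = 10, O = 120, A = Inf, v = NULL,
                         coupling = 1, noise_sd = NULL, dt = 0.05,
                         arena = c(3000, 2500),
                         boundary = c("reflect", "wrap")) {
  boundary <- match.arg(boundary)
  v_tab <- c(`2` = 11.1, `3` = 12.4, `4` = 8.47, `5` = 10.2)
  e_tab <- c(`2` = 0.20, `3` = 0.17, `4` = 0.21, `5` = 0.23)
  if (is.null(v)) {
    if (!as.character(n) %in% names(v_tab)) abort("no default speed for this n; supply `v`")
    v <- unname(v_tab[as.character(n)])
  }
  if (is.null(noise_sd)) {
    if (!as.character(n) %in% names(e_tab)) abort("no default noise for this n; supply `noise_sd`")
    noise_sd <- unname(e_tab[as.character(n)])
  }
  if (!(R > 0 && R <= O && O <= A)) abort("need 0 < R <= O <= A")
  if (v <= 0) abort("`v` must be > 0")
  if (coupling < 0) abort("`coupling` must be >= 0")
  structure(list(n = as.integer(n), R = R, O = O, A = A, v = v,
                 coupling = coupling, noise_sd = noise_sd, dt = dt,
                 arena = arena, boundary = boundary),
            class = "boids_params")
}

#' Simulate Boids trajectories
#'
#' Synchronous updates: for each agent the repulsion vector (away from
#' neighbours within `R`), the alignment vector (mean heading of agents
#' within `O`, including the agent itself, which provides inertia) and the
#' attraction vector (towards neighbours in the `O..A` shell) are each
#' scaled by the coupling strength, summed, and normalised to a heading;
#' Gaussian noise of sd `noise_sd` is added to the heading angle, and the
#' position advances by `v` along the unit heading. A zero rule sum keeps
#' the previous heading (so coupling 0 with zero noise gives straight
#' lines until a wall). Walls reflect both position and heading.
#' Coincident agents get a random repulsion direction (counted in the
#' `n_coincident` attribute).
#'
#' @param params A [boids_params()] object.
#' @param steps Number of time steps (>= 2).
#' @param seed Optional RNG seed.
#' @param init Optional list with numeric vectors `x`, `y` and `angle`
#'   (heading, rad) of length n, overriding the random initial conditions
#'   (a loose group at the arena centre with random headings).
#' @return A `school_traj` tibble with `frame_rate = 1/dt`.
#' @export
simulate_boids <- function(params, steps, seed = NULL, init = NULL) {
  stopifnot(inherits(params, "boids_params"))
  if (steps < 2) abort("`steps` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  n <- params$n
  W <- params$arena[1]; H <- params$arena[2]
  cc <- params$coupling

  if (is.null(init)) {
    # start as a loose group near the arena centre
    x <- W / 2 + runif(n, -150, 150)
    y <- H / 2 + runif(n, -150, 150)
    ang <- runif(n, 0, 2 * pi)
  } else {
    stopifnot(length(init$x) == n, length(init$y) == n, length(init$angle) == n)
    x <- as.double(init$x); y <- as.double(init$y); ang <- as.double(init$angle)
  }
  hx <- cos(ang); hy <- sin(ang)
  n_coincident <- 0L

  xs <- matrix(NA_real_, steps, n)
  ys <- matrix(NA_real_, steps, n)
  xs[1, ] <- x; ys[1, ] <- y

  for (t in 2:steps) {
    dxm <- outer(x, x, function(a, b) b - a)  # dxm[i,j] = x_j - x_i
    dym <- outer(y, y, function(a, b) b - a)
    d <- sqrt(dxm^2 + dym^2)
    diag(d) <- Inf
    nhx <- numeric(n); nhy <- numeric(n)
    for (i in seq_len(n)) {
      rx <- 0; ry <- 0
      rep_j <- which(d[i, ] <= params$R)
      if (length(rep_j)) {
        for (j in rep_j) {
          if (d[i, j] < 1e-9) {
            a <- runif(1, 0, 2 * pi)
            rx <- rx - cos(a); ry <- ry - sin(a)
            n_coincident <- n_coincident + 1L
          } else {
            rx <- rx - dxm[i, j] / d[i, j]
            ry <- ry - dym[i, j] / d[i, j]
          }
        }
      }
      ali_j <- which(d[i, ] <= params$O)
      ax <- hx[i]; ay <- hy[i]  # alignment sum includes self
      if (length(ali_j)) { ax <- ax + sum(hx[ali_j]); ay <- ay + sum(hy[ali_j]) }
      att_j <- which(d[i, ] >= params$O & d[i, ] <= params$A)
      tx <- 0; ty <- 0
      if (length(att_j)) {
        tx <- sum(dxm[i, att_j] / d[i, att_j])
        ty <- sum(dym[i, att_j] / d[i, att_j])
      }
      sx <- cc * (rx + ax + tx)
      sy <- cc * (ry + ay + ty)
      nrm <- sqrt(sx^2 + sy^2)
      if (nrm < 1e-12) { sx <- hx[i]; sy <- hy[i]; nrm <- 1 }
      theta <- atan2(sy, sx) + rnorm(1, 0, params$noise_sd)
      nhx[i] <- cos(theta); nhy[i] <- sin(theta)
    }
    hx <- nhx; hy <- nhy
    x <- x + params$v * hx
    y <- y + params$v * hy
    if (params$boundary == "reflect") {
      rl <- x < 0; x[rl] <- -x[rl]; hx[rl] <- -hx[rl]
      rr <- x > W; x[rr] <- 2 * W - x[rr]; hx[rr] <- -hx[rr]
      rb <- y < 0; y[rb] <- -y[rb]; hy[rb] <- -hy[rb]
      rt <- y > H; y[rt] <- 2 * H - y[rt]; hy[rt] <- -hy[rt]
    } else {
      x <- x %% W; y <- y %% H
    }
    xs[t, ] <- x; ys[t, ] <- y
  }
  df <- tibble::tibble(
    frame = rep(seq_len(steps), each = n),
    id = rep(seq_len(n), steps),
    x = as.vector(t(xs)),
    y = as.vector(t(ys))
  )
  out <- as_trajectory(df, frame_rate = 1 / params$dt)
  attr(out, "n_coincident") <- n_coincident
  attr(out, "boids_params") <- params
  out
}
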