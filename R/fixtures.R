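#' Deterministic fixtures with known ground truth
#'
#' Small hand-built objects used throughout the tests and examples:
#'
#' * `copy_pair` — 2-node deterministic TPM where each node copies the
#'   other's previous state; strongly integrated (Phi > 0), major complex
#'   is the pair.
#' * `independent_pair` — 2-node TPM where each node depends only on its
#'   own past; factorizes across the bipartition, Phi = 0 at every state.
#' * `and_gate_triple` — 3 nodes: nodes 1 and 2 are unbiased coins, node 3
#'   computes AND of their previous states.
#' * `leader_chain` — trajectory of 5 agents in single file moving along
#'   +x with constant spacing; the front agent is the positional leader at
#'   every step, and with a rear blind spot (visual field < 2*pi) it is
#'   also the only OFF individual.
#'
#' @param name Fixture name.
#' @param steps Number of frames for trajectory fixtures.
#' @return A `school_tpm` or `school_traj`, depending on the fixture.
#' @export
make_fixture <- function(name = c("copy_pair", "independent_pair",
                                  "and_gate_triple", "leader_chain"),
                         steps = 100) {
  known <- c("copy_pair", "independent_pair", "and_gate_triple", "leader_chain")
  if (!is.character(name) || !name[1] %in% known) {
    abort(paste0("unknown fixture; available: ", paste(known, collapse = ", ")))
  }
  name <- match.arg(name)
  switch(name,
    copy_pair = as_school_tpm(matrix(c(
      0, 0,   # past 00
      0, 1,   # past 10: node 1 was ON -> node 2 ON
      1, 0,   # past 01
      1, 1),  # past 11
      ncol = 2, byrow = TRUE)),
    independent_pair = as_school_tpm(matrix(c(
      0.9, 0.2,   # each node follows only its own past bit
      0.1, 0.2,
      0.9, 0.8,
      0.1, 0.8),
      ncol = 2, byrow = TRUE)),
    and_gate_triple = {
      states <- all_states(3)
      probs <- cbind(0.5, 0.5, as.numeric(states[, 1] & states[, 2]))
      as_school_tpm(probs)
    },
    leader_chain = {
      n <- 5
      spacing <- 100
      frames <- seq_len(steps)
      # agent 1 at the front (largest x), all moving in +x
      df <- tidyr::expand_grid(frame = frames, id = seq_len(n))
      df$x <- 20 * df$frame + (n - df$id) * spacing
      df$y <- 1250 + 0 * df$frame
      as_trajectory(df, frame_rate = 20)
    })
}

#' Synthetic 5-node leader-structured TPM
#'
#' A stand-in for an empirically estimated 5-node fish-school TPM with a
#' leadership structure (it is generated by this package, not measured
#' from animals): a single-file school with a rear blind spot is
#' simulated, its trajectory binarized, and the TPM estimated from the
#' resulting state series. The front agent sees no neighbour and drives
#' the others, so single-OFF collective states occur often and the
#' estimated process carries a weak link between the leader and the rest.
#'
#' @param steps Simulation length (default 20000).
#' @param seed RNG seed (default 1, for a reproducible object).
#' @param zeta,visual_field Binarization settings (defaults 700 mm and
#'   1.6*pi rad, the high-integration regime).
#' @return A `school_tpm` estimated from the synthetic series.
#' @export
synthetic_leader_tpm <- function(steps = 20000, seed = 1,
                                 zeta = 700, visual_field = 1.6 * pi) {
  traj <- simulate_leader_school(n = 5, steps = steps, seed = seed)
  params <- binarization_params(zeta = zeta, visual_field = visual_field,
                                delta = 0, dt = 0.05)
  estimate_tpm(binarize(traj, params))
}

#' Simulate a leader-follower school
#'
#' Boids-like variant in which agent 1 ignores all others (it performs a
#' noisy persistent walk) while agents 2..n align with and are attracted
#' to every agent, leader included. With a rear blind spot the leader at
#' the front tends to be the single OFF individual.
#'
#' @param n Number of agents.
#' @param steps Number of time steps.
#' @param seed Optional RNG seed.
#' @param v Speed, mm per step.
#' @param noise_sd Heading noise sd, rad (leader); followers get half.
#' @param dt Time step, s.
#' @return A `school_traj` tibble.
#' @export
simulate_leader_school <- function(n = 5, steps = 2000, seed = NULL,
                                   v = 10.2, noise_sd = 0.23, dt = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  W <- 3000; H <- 2500
  x <- W / 2 + runif(n, -100, 100)
  y <- H / 2 + runif(n, -100, 100)
  ang <- runif(n, 0, 2 * pi)
  hx <- cos(ang); hy <- sin(ang)
  xs <- matrix(NA_real_, steps, n); ys <- matrix(NA_real_, steps, n)
  xs[1, ] <- x; ys[1, ] <- y
  for (t in 2:steps) {
    nhx <- hx; nhy <- hy
    for (i in seq_len(n)) {
      if (i == 1) {
        theta <- atan2(hy[1], hx[1]) + rnorm(1, 0, noise_sd)
      } else {
        dx <- x - x[i]; dy <- y - y[i]
        d <- sqrt(dx^2 + dy^2); d[i] <- Inf
        sx <- sum(hx[-i]) + hx[i]
        sy <- sum(hy[-i]) + hy[i]
        far <- which(d > 120)
        if (length(far)) {
          sx <- sx + sum(dx[far] / d[far])
          sy <- sy + sum(dy[far] / d[far])
        }
        near <- which(d <= 10)
        if (length(near)) {
          sx <- sx - sum(dx[near] / pmax(d[near], 1e-9))
          sy <- sy - sum(dy[near] / pmax(d[near], 1e-9))
        }
        theta <- atan2(sy, sx) + rnorm(1, 0, noise_sd / 2)
      }
      nhx[i] <- cos(theta); nhy[i] <- sin(theta)
    }
    hx <- nhx; hy <- nhy
    x <- x + v * hx; y <- y + v * hy
    rl <- x < 0; x[rl] <- -x[rl]; hx[rl] <- -hx[rl]
    rr <- x > W; x[rr] <- 2 * W - x[rr]; hx[rr] <- -hx[rr]
    rb <- y < 0; y[rb] <- -y[rb]; hy[rb] <- -hy[rb]
    rt <- y > H; y[rt] <- 2 * H - y[rt]; hy[rt] <- -hy[rt]
    xs[t, ] <- x; ys[t, ] <- y
  }
  df <- tibble::tibble(frame = rep(seq_len(steps), each = n),
                       id = rep(seq_len(n), steps),
                       x = as.vector(t(xs)), y = as.vector(t(ys)))
  as_trajectory(df, frame_rate = 1 / dt)
}
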