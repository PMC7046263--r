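test_that("distance states use a strict threshold and any-neighbour rule", {
  pos <- rbind(c(0, 0), c(50, 0))
  expect_equal(distance_state(pos, zeta = 100), c(1L, 1L))
  # exactly at the threshold is OFF (strict <)
  pos2 <- rbind(c(0, 0), c(100, 0))
  expect_equal(distance_state(pos2, zeta = 100), c(0L, 0L))
  # 3 collinear fish at 0, 400, 800 with zeta 500: ends reach the middle
  pos3 <- cbind(c(0, 400, 800), 0)
  expect_equal(distance_state(pos3, zeta = 500), c(1L, 1L, 1L))
})

test_that("visual states implement the blind-spot geometry", {
  pos <- rbind(c(0, 0), c(-100, 0))   # neighbour directly behind focal 1
  hd <- rbind(c(1, 0), c(1, 0))
  # full visual field (eta = pi) is always ON
  expect_equal(as.integer(visual_state(pos, hd, eta = pi)), c(1L, 1L))
  # rear neighbour at angle pi with eta = 0.8 pi: blind spot
  expect_equal(as.integer(visual_state(pos, hd, eta = 0.8 * pi))[1], 0L)
  # neighbour at bearing 45 degrees, eta = pi/2: visible
  pos2 <- rbind(c(0, 0), c(100, 100))
  expect_equal(as.integer(visual_state(pos2, hd, eta = pi / 2))[1], 1L)
  # printed-sign variant flips the tested vector
  expect_equal(as.integer(visual_state(pos, hd, eta = 0.8 * pi,
                                       visual_vector = "as_printed"))[1], 1L)
  # undefined heading gives OFF and is counted
  hd_na <- rbind(c(NA, NA), c(1, 0))
  v <- visual_state(pos, hd_na, eta = pi)
  expect_equal(as.integer(v)[1], 0L)
  expect_equal(attr(v, "n_undefined_heading"), 1L)
})

test_that("turning states compare the step angle non-strictly", {
  straight <- rbind(c(1, 0))
  expect_equal(turning_state(straight, straight, delta = 0), 1L)    # 0 >= 0
  expect_equal(turning_state(straight, straight, delta = 0.1), 0L)
  turn30 <- rbind(c(cos(pi / 6), sin(pi / 6)))
  expect_equal(turning_state(turn30, straight, delta = pi / 6), 1L)  # boundary
})

straight_pair <- function(t = 6, sep = 50) {
  df <- expand.grid(id = 1:2, frame = seq_len(t))
  df$x <- df$frame * 10
  df$y <- ifelse(df$id == 1, 0, sep)
  as_trajectory(df, frame_rate = 20)
}

test_that("binarize is the AND of the three conditions", {
  traj <- straight_pair()
  # distance ON (50 < 100), visual ON (2 pi), turning OFF (straight, delta > 0)
  p <- binarization_params(zeta = 100, visual_field = 2 * pi, delta = 0.1, dt = 0.05)
  expect_true(all(state_matrix(binarize(traj, p)) == 0))
  # all three trivially ON
  p2 <- binarization_params(zeta = Inf, visual_field = 2 * pi, delta = 0, dt = 0.05)
  s2 <- binarize(traj, p2)
  expect_true(all(state_matrix(s2) == 1))
  expect_equal(nrow(s2), 4)  # first two frames dropped
})

test_that("a hand-built toy trajectory matches per-step manual evaluation", {
  # two fish, 7 frames: fish 1 runs straight along +x, fish 2 zig-zags and
  # walks away in y
  df <- rbind(
    data.frame(frame = 1:7, id = 1, x = (1:7) * 10, y = 0),
    data.frame(frame = 1:7, id = 2, x = (1:7) * 10,
               y = c(0, 30, 50, 90, 140, 200, 270))
  )
  traj <- as_trajectory(df, frame_rate = 20)
  p <- binarization_params(zeta = 100, visual_field = 1.5 * pi, delta = 0.2,
                           dt = 0.05)
  got <- state_matrix(binarize(traj, p))

  # independent manual evaluation, step by step
  hd <- derive_headings(traj)
  frames <- 3:7
  manual <- matrix(0L, length(frames), 2)
  for (k in seq_along(frames)) {
    fr <- frames[k]
    pos <- as.matrix(df[df$frame == fr, c("x", "y")][order(df$id[df$frame == fr]), ])
    h_t <- as.matrix(dplyr::arrange(dplyr::filter(hd, frame == fr), id)[, c("hx", "hy")])
    h_p <- as.matrix(dplyr::arrange(dplyr::filter(hd, frame == fr - 1), id)[, c("hx", "hy")])
    for (i in 1:2) {
      j <- 3 - i
      D <- as.integer(sqrt(sum((pos[i, ] - pos[j, ])^2)) < p$zeta)
      v <- pos[j, ] - pos[i, ]
      ang <- acos(sum(h_t[i, ] * v) / sqrt(sum(v^2)))
      B <- as.integer(ang < p$eta)
      turn <- acos(min(1, max(-1, sum(h_t[i, ] * h_p[i, ]))))
      Tb <- as.integer(turn >= p$delta)
      manual[k, i] <- D & B & Tb
    }
  }
  expect_equal(got, manual, ignore_attr = TRUE)
})

test_that("states are monotone in zeta and visual field at delta 0", {
  set.seed(5)
  traj <- simulate_boids(boids_params(3), steps = 60, seed = 5)
  base <- state_matrix(binarize(traj, binarization_params(300, 1.4 * pi, 0, 0.05)))
  bigger_z <- state_matrix(binarize(traj, binarization_params(600, 1.4 * pi, 0, 0.05)))
  bigger_v <- state_matrix(binarize(traj, binarization_params(300, 1.8 * pi, 0, 0.05)))
  expect_true(all(bigger_z >= base))
  expect_true(all(bigger_v >= base))
})

test_that("with full visual field and zero turning only distance matters", {
  set.seed(6)
  traj <- simulate_boids(boids_params(3), steps = 60, seed = 6)
  p <- binarization_params(zeta = 150, visual_field = 2 * pi, delta = 0, dt = 0.05)
  s <- binarize(traj, p)
  # recompute from the distance rule alone
  frames <- sort(unique(traj$frame))[3:length(unique(traj$frame))]
  manual <- t(vapply(frames, function(fr) {
    pos <- as.matrix(dplyr::arrange(dplyr::filter(traj, frame == fr), id)[, c("x", "y")])
    distance_state(pos, 150)
  }, integer(3)))
  expect_equal(state_matrix(s), manual, ignore_attr = TRUE)
})

test_that("state series round-trip through CSV with parameter sidecar", {
  set.seed(7)
  s <- as_state_series(matrix(rbinom(20, 1, 0.5), 10, 2),
                       binarization_params(100, 2 * pi, 0, 0.05))
  path <- tempfile(fileext = ".csv")
  write_state_series(s, path)
  s2 <- read_state_series(path)
  expect_equal(state_matrix(s2), state_matrix(s))
  expect_equal(attr(s2, "params")$zeta, 100)
})
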