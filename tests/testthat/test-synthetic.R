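test_that("uncoupled noiseless boids fly straight until a wall", {
  p <- boids_params(3, coupling = 0, noise_sd = 0)
  traj <- simulate_boids(p, steps = 40, seed = 31)
  hd <- derive_headings(traj)
  # headings are piecewise constant; changes only coincide with reflections
  for (i in 1:3) {
    h <- dplyr::filter(hd, id == i)
    turn <- abs(diff(atan2(h$hy, h$hx)))
    d <- dplyr::filter(traj, id == i)
    near_wall <- d$x < 15 | d$x > 2985 | d$y < 15 | d$y > 2485
    expect_true(all(turn[!near_wall[3:(nrow(d) - 1)]] < 1e-9))
  }
})

test_that("repulsion pushes close agents apart", {
  # two agents inside the repulsion radius, heading at each other so the
  # alignment vectors cancel: the update must increase their distance
  p <- boids_params(2, coupling = 5, noise_sd = 0)
  t2 <- simulate_boids(p, steps = 2,
                       init = list(x = c(1500, 1505), y = c(1250, 1250),
                                   angle = c(0, pi)))
  d <- sapply(1:2, function(fr) {
    m <- as.matrix(dplyr::arrange(dplyr::filter(t2, frame == fr), id)[, c("x", "y")])
    sqrt(sum((m[1, ] - m[2, ])^2))
  })
  expect_gt(d[2], d[1])
})

test_that("default parameters produce a cohesive school", {
  traj <- simulate_boids(boids_params(4), steps = 2000, seed = 33)
  late <- dplyr::filter(traj, frame > 500)
  pd <- sapply(split(late, late$frame), function(d) {
    m <- as.matrix(d[order(d$id), c("x", "y")])
    mean(dist(m))
  })
  # stays grouped on the ~100 mm interaction scale, far below the arena size
  expect_gt(mean(pd), 20)
  expect_lt(mean(pd), 300)
})

test_that("generators are seed-deterministic", {
  a <- simulate_boids(boids_params(3), steps = 50, seed = 34)
  b <- simulate_boids(boids_params(3), steps = 50, seed = 34)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_identical(random_tpm(3, seed = 35)$probs, random_tpm(3, seed = 35)$probs)
  m1 <- markov_phi_baseline(2, reps = 3, seed = 36)
  m2 <- markov_phi_baseline(2, reps = 3, seed = 36)
  expect_identical(m1$per_rep, m2$per_rep)
})

test_that("random TPM entries are uniform on (0, 1)", {
  set.seed(37)
  draws <- replicate(100, mean(random_tpm(3)$probs))
  expect_lt(abs(mean(draws) - 0.5), 0.02)
  one <- random_tpm(4, seed = 38)$probs
  expect_true(all(one > 0 & one < 1))
})

test_that("fixtures carry their documented ground truth", {
  expect_error(make_fixture("nonsense"), "copy_pair")
  ind <- make_fixture("independent_pair")
  for (k in 1:4) {
    st <- c(bitwAnd(k - 1, 1), bitwAnd(bitwShiftR(k - 1, 1), 1))
    expect_equal(big_phi(ind, st)$phi, 0)
  }
  expect_equal(major_complex(make_fixture("copy_pair"), c(1L, 1L))$subsystem,
               c(1L, 2L))
  chain <- make_fixture("leader_chain", steps = 30)
  hd <- derive_headings(chain)
  for (fr in unique(hd$frame)) {
    pos <- as.matrix(dplyr::arrange(dplyr::filter(chain, frame == fr), id)[, c("x", "y")])
    hm <- as.matrix(dplyr::arrange(dplyr::filter(hd, frame == fr), id)[, c("hx", "hy")])
    expect_equal(positional_leader(pos, hm), 1L)
  }
  and3 <- make_fixture("and_gate_triple")
  bits <- as.matrix(expand.grid(0:1, 0:1, 0:1))  # little-endian state order
  expect_equal(and3$probs[, 3], as.numeric(bits[, 1] & bits[, 2]))
})

test_that("the leader-school generator produces single-OFF-dominated series", {
  traj <- simulate_leader_school(n = 5, steps = 1500, seed = 39)
  p <- binarization_params(zeta = 700, visual_field = 1.6 * pi, delta = 0,
                           dt = 0.05)
  m <- state_matrix(binarize(traj, p))
  soff <- single_off_index(m)
  # leadership states are common and the leader is usually the OFF one
  expect_gt(mean(soff > 0), 0.05)
  expect_gt(mean(soff[soff > 0] == 1), 0.5)
})
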