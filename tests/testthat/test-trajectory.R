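make_df <- function(n = 2, t = 3, fr = 20) {
  df <- expand.grid(id = seq_len(n), frame = seq_len(t))
  df$x <- df$frame * 10 + df$id
  df$y <- df$frame * 5
  df
}

test_that("loading validates and normalises well-formed data", {
  traj <- as_trajectory(make_df(2, 3), frame_rate = 20)
  expect_s3_class(traj, "school_traj")
  expect_equal(attr(traj, "n"), 2)
  expect_equal(length(unique(traj$frame)), 3)
  expect_equal(names(traj), c("frame", "id", "x", "y"))

  path <- tempfile(fileext = ".csv")
  readr::write_csv(make_df(2, 3), path)
  traj2 <- read_trajectory(path, frame_rate = 20)
  expect_equal(tibble::as_tibble(traj2), tibble::as_tibble(traj))
})

test_that("a non-finite coordinate is rejected, naming frame and id", {
  df <- make_df(2, 3)
  df$y[df$frame == 2 & df$id == 1] <- NaN
  expect_error(as_trajectory(df, frame_rate = 20), "frame 2.*id 1")
})

test_that("ragged and misaligned individuals are rejected", {
  df <- make_df(2, 3)
  expect_error(as_trajectory(df[-1, ], frame_rate = 20), "ragged")
  df2 <- make_df(2, 3)
  df2$frame[df2$id == 2] <- df2$frame[df2$id == 2] + 10
  expect_error(as_trajectory(df2, frame_rate = 20), "same frame sequence")
})

test_that("column dialects map shuffled layouts onto the canonical one", {
  df <- make_df(2, 3)
  shuffled <- data.frame(easting = df$x, t_idx = df$frame,
                         northing = df$y, fish = df$id)
  traj1 <- as_trajectory(df, frame_rate = 20)
  traj2 <- as_trajectory(shuffled, frame_rate = 20,
                         dialect = c(frame = "t_idx", id = "fish",
                                     x = "easting", y = "northing"))
  expect_equal(tibble::as_tibble(traj1), tibble::as_tibble(traj2))
})

test_that("resampling keeps every stride-th frame and composes", {
  traj <- as_trajectory(make_df(2, 100), frame_rate = 120)
  expect_equal(tibble::as_tibble(resample_trajectory(traj, 1 / 120)),
               tibble::as_tibble(traj))
  r6 <- resample_trajectory(traj, 0.05)  # 120 fps, dt 0.05 -> stride 6
  expect_equal(sort(unique(r6$frame)), seq(1, 100, by = 6))
  expect_equal(length(unique(r6$frame)), 17)  # floor((100-1)/6) + 1
  expect_equal(attr(r6, "frame_rate"), 20)
  # resample by 2 then 3 equals a single resample by 6
  r23 <- resample_trajectory(resample_trajectory(traj, 2 / 120), 6 / 120)
  expect_equal(tibble::as_tibble(r23), tibble::as_tibble(resample_trajectory(traj, 6 / 120)))
  expect_error(resample_trajectory(traj, 0.0251), "nearest valid dt")
})

test_that("headings are backward differences with carry-forward for pauses", {
  df <- data.frame(frame = rep(1:5, 2), id = rep(1:2, each = 5),
                   x = c(1:5 * 10, -(1:5) * 10), y = 0)
  traj <- as_trajectory(df, frame_rate = 10)
  hd <- derive_headings(traj)
  h1 <- dplyr::filter(hd, id == 1)
  expect_true(all(abs(h1$hx - 1) < 1e-12 & abs(h1$hy) < 1e-12))
  expect_true(all(abs(h1$speed - 100) < 1e-9))  # 10 mm/frame at 10 Hz

  # circular motion: per-step turning angle equals omega * dt
  omega <- 0.3; fr <- 10
  tt <- seq(0, 5, by = 1 / fr)
  circ <- data.frame(frame = seq_along(tt), id = 1,
                     x = 100 * cos(omega * tt), y = 100 * sin(omega * tt))
  circ <- rbind(circ, transform(circ, id = 2, x = circ$x + 500))
  hc <- dplyr::filter(derive_headings(as_trajectory(circ, frame_rate = fr)), id == 1)
  turn <- acos(pmin(1, head(hc$hx, -1) * tail(hc$hx, -1) +
                      head(hc$hy, -1) * tail(hc$hy, -1)))
  expect_true(all(abs(turn - omega / fr) < 1e-6))

  # one stationary step inside a moving series copies the previous heading
  df2 <- make_df(2, 5)
  df2$x[df2$frame == 3] <- df2$x[df2$frame == 2]
  df2$y[df2$frame == 3] <- df2$y[df2$frame == 2]
  hd2 <- derive_headings(as_trajectory(df2, frame_rate = 20))
  h3 <- dplyr::filter(hd2, frame == 3, id == 1)
  h2 <- dplyr::filter(hd2, frame == 2, id == 1)
  expect_equal(c(h3$hx, h3$hy), c(h2$hx, h2$hy))
  expect_equal(attr(hd2, "n_carried"), 2L)

  expect_error(derive_headings(as_trajectory(
    data.frame(frame = rep(1:3, each = 1), id = 1, x = 5, y = 5),
    frame_rate = 10)), "never moves")
})

test_that("headings are invariant under global translation", {
  set.seed(11)
  df <- make_df(3, 20)
  df$x <- df$x + rnorm(nrow(df))
  df$y <- df$y + rnorm(nrow(df))
  df2 <- transform(df, x = x + 1234, y = y - 987)
  h1 <- derive_headings(as_trajectory(df, frame_rate = 20))
  h2 <- derive_headings(as_trajectory(df2, frame_rate = 20))
  expect_equal(h1$hx, h2$hx, tolerance = 1e-12)
  expect_equal(h1$hy, h2$hy, tolerance = 1e-12)
})
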