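test_that("single-OFF detection needs exactly one OFF bit", {
  expect_equal(single_off_index(c(0, 1, 1, 1, 1)), 1L)
  expect_equal(single_off_index(c(1, 1, 1, 1, 1)), 0L)
  expect_equal(single_off_index(c(0, 0, 1, 1, 1)), 0L)
  expect_equal(single_off_index(rbind(c(1, 0), c(1, 1))), c(2L, 0L))
})

test_that("the positional leader maximises the projection on the group heading", {
  pos <- cbind(c(10, 50, 30), 0)
  hd <- cbind(rep(1, 3), 0)
  expect_equal(positional_leader(pos, hd), 2L)
  # rotation invariance
  th <- 1.1
  rot <- function(m) m %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  expect_equal(positional_leader(rot(pos), rot(hd)), 2L)
  # antiparallel headings cancel: undefined
  expect_true(is.na(positional_leader(cbind(c(0, 10), 0),
                                      rbind(c(1, 0), c(-1, 0)))))
  # ties go to the smallest index
  expect_equal(positional_leader(cbind(c(5, 5), 0), cbind(rep(1, 2), 0)), 1L)
})

test_that("matching rates count single-OFF steps only", {
  recs <- tibble::tibble(
    single_off = c(1L, 0L, 2L, 3L, 0L, 1L, 2L, 0L, 3L, 1L),
    positional_leader = c(1L, 2L, 2L, 1L, 3L, 1L, 2L, 1L, 3L, 2L)
  )
  # 7 single-OFF steps; matches at rows 1,3,6,7,9 -> hand count 5/7
  expect_equal(matching_rate(recs), 100 * 5 / 7)
  expect_equal(matching_rate(tibble::tibble(single_off = c(1L, 2L),
                                            positional_leader = c(1L, 2L))), 100)
  expect_equal(matching_rate(tibble::tibble(single_off = c(1L, 2L),
                                            positional_leader = c(2L, 1L))), 0)
  expect_true(is.na(matching_rate(tibble::tibble(single_off = 0L,
                                                 positional_leader = 1L))))
})

test_that("MIP matching recognises cuts isolating the OFF individual", {
  recs <- tibble::tibble(
    single_off = c(1L, 2L, 3L, 0L),
    mip = c("{1} -/-> {2,3}", "{1,3} -/-> {2}", "{1,2} -/-> {3}", "{1} -/-> {2,3}")
  )
  expect_equal(mip_single_off_match_rate(recs, n = 3), 100)
  recs$mip[2] <- "{1,2} -/-> {3}"  # no longer isolates individual 2
  expect_equal(mip_single_off_match_rate(recs, n = 3), 100 * 2 / 3)
})

test_that("leadership classification follows the cut direction", {
  # flow severed FROM the leader: passive
  expect_equal(classify_leadership(1L, 1L, c(2L, 3L, 4L, 5L)), "passive")
  # flow severed TOWARDS the leader: active
  expect_equal(classify_leadership(1L, c(2L, 3L, 4L, 5L), 1L), "active")
  expect_equal(classify_leadership(1L, c(1L, 2L), c(3L, 4L, 5L)), "none")
  expect_equal(classify_leadership(0L, 1L, c(2L, 3L)), "none")
})

test_that("the single-file school yields perfect matching with a blind spot", {
  traj <- make_fixture("leader_chain", steps = 60)
  # the front fish sees nobody (rear blind spot), everyone else sees ahead
  p <- binarization_params(zeta = 600, visual_field = 1.6 * pi, delta = 0,
                           dt = 1 / attr(traj, "frame_rate"))
  recs <- leadership_records(traj, p)
  expect_true(all(recs$single_off == 1L))
  expect_true(all(recs$positional_leader == 1L))
  expect_equal(matching_rate(recs), 100)
})

test_that("matching rate is invariant under consistent relabelling", {
  recs <- tibble::tibble(
    single_off = c(1L, 2L, 0L, 3L),
    positional_leader = c(1L, 3L, 2L, 3L)
  )
  perm <- c(2L, 3L, 1L)  # relabel i -> perm[i], 0 stays "no single OFF"
  relabel <- function(v) vapply(v, function(i) if (i == 0L) 0L else perm[i],
                                integer(1))
  relab <- tibble::tibble(
    single_off = relabel(recs$single_off),
    positional_leader = relabel(recs$positional_leader)
  )
  expect_equal(matching_rate(recs), matching_rate(relab))
})
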