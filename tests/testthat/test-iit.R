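# The swap pair: each node deterministically copies the other's past state.
swap_tpm <- function() make_fixture("copy_pair")

test_that("earth mover's distance agrees with an LP solved independently", {
  skip_if_not_installed("boot")
  lp_emd <- function(p, q) {
    m <- length(p)
    H <- outer(0:(m - 1), 0:(m - 1),
               function(x, y) oracle_popcount(bitwXor(x, y)))
    nv <- m * m
    A3 <- matrix(0, 2 * m - 1, nv)  # one redundant constraint dropped
    b3 <- c(p, q[-m])
    for (i in 1:m) A3[i, ((i - 1) * m + 1):(i * m)] <- 1
    for (j in 1:(m - 1)) A3[m + j, seq(j, nv, by = m)] <- 1
    unname(boot::simplex(a = as.vector(t(H)), A3 = A3, b3 = b3, maxi = FALSE)$value)
  }
  set.seed(10)
  for (rep in 1:30) {
    m <- sample(c(2, 4, 8, 16), 1)
    p <- runif(m); p <- p / sum(p)
    q <- runif(m); q <- q / sum(q)
    want <- lp_emd(p, q)
    expect_equal(emd(p, q), want, tolerance = 1e-8)
    expect_equal(oracle_emd(p, q), want, tolerance = 1e-8)  # test oracle too
  }
})

test_that("EMD basics: identity, single bit flip, purview mismatch", {
  expect_equal(emd(c(0.25, 0.25, 0.25, 0.25), c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(emd(c(1, 0), c(0, 1)), 1)
  expect_equal(emd(c(0, 0, 0, 1), rep(0.25, 4)), 1)  # mean Hamming to corner
  expect_error(emd(c(1, 0), c(0, 0, 1, 0)), "purview")
})

test_that("repertoires behave on the deterministic swap pair", {
  tpm <- swap_tpm()
  st <- c(1L, 1L)
  # unconstrained repertoires
  expect_equal(as.numeric(cause_repertoire(tpm, st, integer(0), 1L)), c(0.5, 0.5))
  expect_equal(as.numeric(effect_repertoire(tpm, st, integer(0), 2L)), c(0.5, 0.5))
  # copy: mechanism {1} ON pins node 2's future and node 2's past
  expect_equal(as.numeric(effect_repertoire(tpm, st, 1L, 2L)), c(0, 1))
  expect_equal(as.numeric(cause_repertoire(tpm, st, 2L, 1L)), c(0, 1))
  # empty purview is the scalar distribution
  expect_equal(as.numeric(effect_repertoire(tpm, st, 1L, integer(0))), 1)
})

test_that("undefined cause repertoires are flagged", {
  # node 1 can never be ON: P(on) = 0 in every row
  tpm <- matrix(c(0, 0, 0, 0, 0.3, 0.6, 0.2, 0.9), 4, 2)
  r <- cause_repertoire(tpm, c(1L, 0L), 1L, 2L)  # mechanism state impossible
  expect_true(isTRUE(attr(r, "undefined")))
  expect_equal(as.numeric(r), c(0.5, 0.5))
})

test_that("small phi: swap concepts are irreducible, independence is not", {
  tpm <- swap_tpm()
  con <- small_phi(tpm, c(1L, 1L), 1L)
  expect_equal(con$phi, 0.5, tolerance = 1e-10)
  expect_equal(con$cause$purview, 2L)
  expect_equal(con$effect$purview, 2L)
  # the joint mechanism factorises exactly (each node explains one purview
  # node) and is reducible
  expect_null(small_phi(tpm, c(1L, 1L), c(1L, 2L)))
  # independent nodes: single-node self-concepts exist, but a mechanism
  # evaluated over the *other* node alone is fully reducible, and so is the
  # joint mechanism
  ind <- make_fixture("independent_pair")
  con1 <- small_phi(ind, c(1L, 1L), 1L)
  expect_equal(con1$cause$purview, 1L)   # constrains only its own past
  expect_equal(con1$effect$purview, 1L)
  expect_null(small_phi(ind, c(0L, 1L), c(1L, 2L)))
})

test_that("cause-effect structures enumerate exactly the irreducible mechanisms", {
  ces <- cause_effect_structure(swap_tpm(), c(1L, 1L))
  expect_equal(nrow(ces), 2)
  expect_equal(sort(unlist(ces$mechanism)), c(1L, 2L))
  expect_equal(ces$phi, c(0.5, 0.5), tolerance = 1e-10)

  # independent pair: only singleton self-concepts, no joint concept
  ind <- cause_effect_structure(make_fixture("independent_pair"), c(1L, 1L))
  expect_true(all(lengths(ind$mechanism) == 1))

  # a single-node subsystem has at most one mechanism
  one <- cause_effect_structure(swap_tpm(), c(1L, 1L), subsystem = 1L)
  expect_lte(nrow(one), 1)
})

test_that("system cuts noise exactly the severed inputs", {
  tpm <- swap_tpm()
  cut <- apply_cut(tpm, 1L, 2L)
  expect_true(all(cut$probs[, 2] == 0.5))        # node 2 driven by noise
  expect_equal(cut$probs[, 1], tpm$probs[, 1])   # node 1 untouched
  # cutting an absent dependency changes nothing
  ind <- make_fixture("independent_pair")
  expect_equal(apply_cut(ind, 1L, 2L)$probs, ind$probs, tolerance = 1e-12)
  # random 3-node system equals the enumeration oracle
  set.seed(11)
  t3 <- random_tpm(3)
  got <- apply_cut(t3, c(1L, 3L), 2L)$probs
  want <- oracle_apply_cut(t3$probs, c(1, 3), 2)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("cut enumerations have the right size, order and contents", {
  c2 <- cut_one_cuts(2)
  expect_equal(nrow(c2), 4)
  c5 <- cut_one_cuts(5)
  expect_equal(nrow(c5), 10)
  expect_true("{1} -/-> {2,3,4,5}" %in% c5$label)
  expect_true("{2,3,4,5} -/-> {1}" %in% c5$label)
  for (k in seq_len(nrow(c5))) {
    expect_equal(sort(c(c5$from[[k]], c5$to[[k]])), 1:5)
    expect_length(intersect(c5$from[[k]], c5$to[[k]]), 0)
  }
  e3 <- exhaustive_cuts(3)
  expect_equal(nrow(e3), 6)  # 2 (2^(3-1) - 1) ordered bipartitions
  expect_true(all(cut_one_cuts(3)$label %in% e3$label))
  expect_error(cut_one_cuts(1), ">= 2")
})

test_that("ces distance is zero to self and the phi-mass-to-null on emptiness", {
  tpm <- swap_tpm()
  expect_equal(ces_distance(tpm, tpm, c(1L, 1L)), 0)
  # full noise kills every concept: distance = sum of phi * distance-to-null,
  # which for the swap system in state 11 is 2 * 0.5 * (0.5 + 0.5) + 0.5 cause
  # asymmetry = 1 (hand-computed; also the big-phi value of the total cut)
  noise <- as_school_tpm(matrix(0.5, 4, 2))
  expect_equal(ces_distance(tpm, noise, c(1L, 1L)), 1, tolerance = 1e-10)
})

test_that("big phi: zeros for factorized systems, known value for the swap", {
  ind <- make_fixture("independent_pair")
  for (k in 1:4) {
    st <- c(bitwAnd(k - 1, 1), bitwAnd(bitwShiftR(k - 1, 1), 1))
    expect_equal(big_phi(ind, st)$phi, 0)
  }
  r <- big_phi(swap_tpm(), c(1L, 1L), cuts = "exhaustive")
  expect_equal(r$phi, 1, tolerance = 1e-10)
  expect_equal(r$n_concepts, 2)
})

test_that("cut-one upper-bounds the exhaustive MIP search", {
  set.seed(12)
  for (rep in 1:10) {
    probs <- matrix(runif(24), 8, 3)
    st <- sample(0:1, 3, replace = TRUE)
    expect_gte(big_phi(probs, st, cuts = "one")$phi,
               big_phi(probs, st, cuts = "exhaustive")$phi - 1e-10)
  }
})

test_that("unreachable states are reported with phi zero", {
  # node 1 is never ON, so any state with bit 1 set is unreachable
  tpm <- matrix(c(0, 0, 0, 0, 0.3, 0.6, 0.2, 0.9), 4, 2)
  r <- big_phi(tpm, c(1L, 1L))
  expect_true(r$unreachable)
  expect_equal(r$phi, 0)
  expect_false(big_phi(tpm, c(0L, 1L))$unreachable)
})

test_that("the major complex finds the interacting pair", {
  mc <- major_complex(swap_tpm(), c(1L, 1L))
  expect_equal(mc$subsystem, c(1L, 2L))
  expect_equal(mc$result$phi, 1, tolerance = 1e-10)

  ind <- major_complex(make_fixture("independent_pair"), c(1L, 1L))
  expect_equal(ind$result$phi, 0)

  # swap pair plus an independent third node: the complex is within {1,2}
  set.seed(13)
  probs <- cbind(rbind(swap_tpm()$probs, swap_tpm()$probs),  # nodes 1,2 ignore 3
                 0.5)
  # perturb slightly away from determinism to keep repertoires defined
  probs <- probs * 0.98 + 0.01
  mc3 <- major_complex(probs, c(1L, 1L, 1L))
  expect_true(all(mc3$subsystem %in% c(1L, 2L)))
})

test_that("phi summaries aggregate per-state values under both weightings", {
  ind <- make_fixture("independent_pair")
  s <- phi_over_series(tpm = ind, weighting = "by_state")
  expect_equal(s$mean_phi, 0)
  expect_equal(s$sd_phi, 0)
  expect_equal(s$max_phi, 0)

  # 2-node toy: by_state mean equals the plain average of the 4 values
  set.seed(14)
  tpm <- random_tpm(2)
  phis <- vapply(1:4, function(k) {
    st <- c(bitwAnd(k - 1, 1), bitwAnd(bitwShiftR(k - 1, 1), 1))
    big_phi(tpm, st)$phi
  }, numeric(1))
  s2 <- phi_over_series(tpm = tpm, weighting = "by_state")
  expect_equal(s2$mean_phi, mean(phis), tolerance = 1e-12)
  expect_equal(s2$sd_phi, sqrt(mean((phis - mean(phis))^2)), tolerance = 1e-12)

  # by_time weighting follows occupancy
  set.seed(15)
  series <- as_state_series(matrix(rbinom(400, 1, 0.4), ncol = 2))
  est <- estimate_tpm(series)
  st <- phi_over_series(series, weighting = "by_time")
  w <- est$occupancy / sum(est$occupancy)
  phis_t <- st$per_state$phi
  expect_equal(st$mean_phi, sum(w * phis_t), tolerance = 1e-12)
})

test_that("tidiers expose results as tibbles", {
  r <- big_phi(swap_tpm(), c(1L, 1L))
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$phi, 1, tolerance = 1e-10)
  expect_equal(td$state, "11")
  g <- glance(phi_over_series(tpm = make_fixture("independent_pair")))
  expect_equal(g$mean_phi, 0)
  tt <- tidy(swap_tpm())
  expect_equal(nrow(tt), 8)
})
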