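# Independent brute-force IIT 3.0 oracle.
#
# Everything here is computed by explicit enumeration over full state
# spaces, with node sets as sorted integer vectors, and an EMD solved by a
# hand-written successive-shortest-path transport routine that is itself
# cross-validated against an LP (boot::simplex) in the tests. No code is
# shared with the package implementation.

oracle_states <- function(n) {
  if (n == 0) return(matrix(0L, 1, 0))  # the single empty assignment
  as.matrix(expand.grid(rep(list(0:1), n)))  # row k: little-endian bits of k-1
}

oracle_row <- function(bits) 1L + as.integer(sum(bits * 2^(seq_along(bits) - 1L)))

oracle_subsets <- function(v, nonempty = FALSE) {
  out <- list(integer(0))
  for (x in v) out <- c(out, lapply(out, function(s) c(s, x)))
  out <- out[order(vapply(out, function(s) sum(2^(s - 1)), numeric(1)))]
  if (nonempty) out[-1] else out
}

# --- transport / EMD --------------------------------------------------------

oracle_transport <- function(a, b, C) {
  na_ <- length(a); nb_ <- length(b)
  f <- matrix(0, na_, nb_)
  total <- 0
  repeat {
    ra <- a - rowSums(f); rb <- b - colSums(f)
    srcs <- which(ra > 1e-12); snks <- which(rb > 1e-12)
    if (!length(srcs) || !length(snks)) break
    nn <- na_ + nb_
    dist <- rep(Inf, nn); parent <- rep(NA_integer_, nn)
    dist[srcs] <- 0
    repeat {
      changed <- FALSE
      for (i in seq_len(na_)) {
        if (!is.finite(dist[i])) next
        nd <- dist[i] + C[i, ]
        upd <- which(nd < dist[na_ + seq_len(nb_)] - 1e-15)
        if (length(upd)) {
          dist[na_ + upd] <- nd[upd]; parent[na_ + upd] <- i; changed <- TRUE
        }
      }
      for (j in seq_len(nb_)) {
        if (!is.finite(dist[na_ + j])) next
        has <- which(f[, j] > 1e-12)
        if (length(has)) {
          nd <- dist[na_ + j] - C[has, j]
          upd <- which(nd < dist[has] - 1e-15)
          if (length(upd)) {
            dist[has[upd]] <- nd[upd]; parent[has[upd]] <- na_ + j; changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    reach <- snks[is.finite(dist[na_ + snks])]
    if (!length(reach)) break
    jbest <- reach[which.min(dist[na_ + reach])]
    path <- integer(0); node <- na_ + jbest
    while (!is.na(parent[node])) { path <- c(node, path); node <- parent[node] }
    path <- c(node, path)
    bott <- min(ra[path[1]], rb[jbest])
    if (length(path) > 2) {
      for (k in seq(2, length(path) - 1)) {
        u <- path[k]; v <- path[k + 1]
        if (u > na_ && v <= na_) bott <- min(bott, f[v, u - na_])
      }
    }
    for (k in seq_len(length(path) - 1)) {
      u <- path[k]; v <- path[k + 1]
      if (u <= na_ && v > na_) f[u, v - na_] <- f[u, v - na_] + bott
      else f[v, u - na_] <- f[v, u - na_] - bott
    }
    total <- total + bott * dist[na_ + jbest]
  }
  total
}

oracle_popcount <- function(x) {
  vapply(x, function(z) sum(bitwAnd(bitwShiftR(z, 0:30), 1L)), integer(1))
}

oracle_emd <- function(p, q) {
  m <- length(p)
  d <- p - q
  sup <- which(d > 1e-12); dem <- which(d < -1e-12)
  if (!length(sup) || !length(dem)) return(0)
  H <- outer(sup - 1L, dem - 1L,
             function(x, y) oracle_popcount(bitwXor(x, y)))
  oracle_transport(d[sup], -d[dem], H)
}

# --- repertoires ------------------------------------------------------------

oracle_system <- function(probs, state) {
  list(probs = probs, n = ncol(probs), state = as.integer(state),
       cache = new.env(parent = emptyenv()))
}

# Effect repertoires factorise over purview nodes (each purview node is
# constrained independently by the mechanism; correlations induced by
# shared non-mechanism inputs do not count as constraint).
oracle_effect_rep <- function(sys, M, Z) {
  key <- paste("e", paste(M, collapse = "."), paste(Z, collapse = "."))
  if (!is.null(sys$cache[[key]])) return(sys$cache[[key]])
  n <- sys$n
  if (!length(Z)) return(1)
  S <- oracle_states(n)
  rows <- if (length(M)) {
    which(apply(S, 1, function(r) all(r[M] == sys$state[M])))
  } else seq_len(2^n)
  marg <- vapply(Z, function(j) mean(sys$probs[rows, j]), numeric(1))
  Zs <- oracle_states(length(Z))
  out <- vapply(seq_len(nrow(Zs)), function(zi) {
    prod(ifelse(Zs[zi, ] == 1, marg, 1 - marg))
  }, numeric(1))
  sys$cache[[key]] <- out
  out
}

oracle_cause_rep <- function(sys, M, Z) {
  key <- paste("c", paste(M, collapse = "."), paste(Z, collapse = "."))
  if (!is.null(sys$cache[[key]])) return(sys$cache[[key]])
  n <- sys$n
  if (!length(Z)) return(list(dist = 1, undefined = FALSE))
  Zs <- oracle_states(length(Z))
  Wn <- setdiff(seq_len(n), Z)
  Ws <- oracle_states(length(Wn))
  lik <- rep(1, nrow(Zs))
  for (i in M) {
    li <- numeric(nrow(Zs))
    for (zi in seq_len(nrow(Zs))) {
      s <- 0
      for (wi in seq_len(nrow(Ws))) {
        bits <- integer(n)
        bits[Z] <- Zs[zi, ]
        if (length(Wn)) bits[Wn] <- Ws[wi, ]
        p <- sys$probs[oracle_row(bits), i]
        s <- s + if (sys$state[i] == 1) p else 1 - p
      }
      li[zi] <- s / nrow(Ws)
    }
    lik <- lik * li
  }
  out <- if (sum(lik) <= 0) {
    list(dist = rep(1 / nrow(Zs), nrow(Zs)), undefined = TRUE)
  } else {
    list(dist = lik / sum(lik), undefined = FALSE)
  }
  sys$cache[[key]] <- out
  out
}

oracle_rep <- function(sys, M, Z, dir) {
  if (dir == "effect") list(dist = oracle_effect_rep(sys, M, Z), undefined = FALSE)
  else oracle_cause_rep(sys, M, Z)
}

# --- mechanism phi ----------------------------------------------------------

# All bipartitions ((M1,Z1),(M2,Z2)) of a mechanism/purview pair: unordered
# splits of M crossed with directed splits of Z, both parts non-empty as
# mechanism-purview pairs.
oracle_partitions <- function(M, Z) {
  m_splits <- Filter(function(s) !(M[1] %in% s), oracle_subsets(M))
  z_splits <- oracle_subsets(Z)
  out <- list()
  for (M1 in m_splits) for (Z1 in z_splits) {
    M2 <- setdiff(M, M1); Z2 <- setdiff(Z, Z1)
    if (!length(M1) && !length(Z1)) next
    out[[length(out) + 1]] <- list(M1 = M1, Z1 = Z1, M2 = M2, Z2 = Z2)
  }
  out
}

oracle_part_product <- function(sys, part, Z, dir) {
  Zs <- oracle_states(length(Z))
  f1 <- if (length(part$Z1)) oracle_rep(sys, part$M1, part$Z1, dir)$dist else NULL
  f2 <- if (length(part$Z2)) oracle_rep(sys, part$M2, part$Z2, dir)$dist else NULL
  q <- rep(1, nrow(Zs))
  for (zi in seq_len(nrow(Zs))) {
    if (!is.null(f1)) q[zi] <- q[zi] * f1[oracle_row(Zs[zi, match(part$Z1, Z)])]
    if (!is.null(f2)) q[zi] <- q[zi] * f2[oracle_row(Zs[zi, match(part$Z2, Z)])]
  }
  q
}

oracle_mice <- function(sys, M, dir) {
  n <- sys$n
  best <- list(phi = -1, purview = integer(0), rep = NULL)
  for (Z in oracle_subsets(seq_len(n), nonempty = TRUE)) {
    r <- oracle_rep(sys, M, Z, dir)
    if (r$undefined) {
      phiZ <- 0
    } else {
      phiZ <- Inf
      for (part in oracle_partitions(M, Z)) {
        q <- oracle_part_product(sys, part, Z, dir)
        phiZ <- min(phiZ, oracle_emd(r$dist, q))
      }
    }
    if (phiZ > best$phi + 1e-10 ||
        (abs(phiZ - best$phi) <= 1e-10 && length(Z) > length(best$purview))) {
      best <- list(phi = phiZ, purview = Z, rep = r$dist)
    }
  }
  best
}

oracle_concept <- function(sys, M) {
  cc <- oracle_mice(sys, M, "cause")
  if (cc$phi <= 1e-10) return(NULL)
  ee <- oracle_mice(sys, M, "effect")
  if (ee$phi <= 1e-10) return(NULL)
  list(mech = M, phi = min(cc$phi, ee$phi), cause = cc, effect = ee)
}

oracle_ces <- function(sys) {
  out <- list()
  for (M in oracle_subsets(seq_len(sys$n), nonempty = TRUE)) {
    c_ <- oracle_concept(sys, M)
    if (!is.null(c_)) out[[length(out) + 1]] <- c_
  }
  out
}

# --- system level -----------------------------------------------------------

oracle_apply_cut <- function(probs, from, to) {
  n <- ncol(probs)
  S <- oracle_states(n)
  out <- probs
  for (j in to) {
    for (s in seq_len(2^n)) {
      rows <- which(apply(S, 1, function(r) {
        keep <- setdiff(seq_len(n), from)
        all(r[keep] == S[s, keep])
      }))
      out[s, j] <- mean(probs[rows, j])
    }
  }
  out
}

oracle_expand_concept <- function(sys, con) {
  n <- sys$n
  S <- oracle_states(n)
  Zc <- con$cause$purview
  exc <- vapply(seq_len(2^n), function(s) {
    con$cause$rep[oracle_row(S[s, Zc])] / 2^(n - length(Zc))
  }, numeric(1))
  # effect: full product distribution over all nodes
  marg <- numeric(n)
  Ze <- con$effect$purview
  repZ <- con$effect$rep
  Zs <- oracle_states(length(Ze))
  for (j in seq_len(n)) {
    if (j %in% Ze) {
      marg[j] <- sum(repZ[Zs[, match(j, Ze)] == 1])
    } else {
      marg[j] <- oracle_effect_rep(sys, integer(0), j)[2]
    }
  }
  exe <- vapply(seq_len(2^n), function(s) {
    prod(ifelse(S[s, ] == 1, marg, 1 - marg))
  }, numeric(1))
  list(cause = exc, effect = exe)
}

oracle_null_concept <- function(sys) {
  n <- sys$n
  list(mech = integer(0), phi = 0,
       cause = list(purview = seq_len(n), rep = rep(1 / 2^n, 2^n)),
       effect = list(purview = seq_len(n),
                     rep = oracle_effect_rep(sys, integer(0), seq_len(n))))
}

# The cut system's concepts are expanded within the CUT system (its own
# unconstrained effect marginals); the null concept is the intact one.
oracle_ces_distance2 <- function(sysA, sysB, A, B) {
  exA <- lapply(A, function(c_) oracle_expand_concept(sysA, c_))
  exB <- lapply(B, function(c_) oracle_expand_concept(sysB, c_))
  exN <- oracle_expand_concept(sysA, oracle_null_concept(sysA))
  gd <- function(x, y) oracle_emd(x$cause, y$cause) + oracle_emd(x$effect, y$effect)
  phiA <- vapply(A, function(c_) c_$phi, numeric(1))
  phiB <- vapply(B, function(c_) c_$phi, numeric(1))
  if (sum(phiA) <= 1e-12 && sum(phiB) <= 1e-12) return(0)
  a <- c(phiA, sum(phiB))
  b <- c(phiB, sum(phiA))
  pts_a <- c(exA, list(exN))
  pts_b <- c(exB, list(exN))
  C <- matrix(0, length(a), length(b))
  for (i in seq_along(a)) for (j in seq_along(b)) C[i, j] <- gd(pts_a[[i]], pts_b[[j]])
  oracle_transport(a, b, C)
}

oracle_big_phi <- function(probs, state, cuts = c("exhaustive", "one")) {
  cuts <- match.arg(cuts)
  n <- ncol(probs)
  sys <- oracle_system(probs, state)
  A <- oracle_ces(sys)
  if (!length(A)) return(list(phi = 0))
  all_n <- seq_len(n)
  froms <- if (cuts == "one") {
    c(lapply(all_n, identity), lapply(all_n, function(i) setdiff(all_n, i)))
  } else {
    Filter(function(s) length(s) >= 1 && length(s) < n,
           oracle_subsets(all_n))
  }
  best <- Inf
  for (from in froms) {
    to <- setdiff(all_n, from)
    sysc <- oracle_system(oracle_apply_cut(probs, from, to), state)
    B <- oracle_ces(sysc)
    d <- oracle_ces_distance2(sys, sysc, A, B)
    if (d < best) best <- d
    if (best <= 1e-12) break
  }
  list(phi = best, ces = A)
}
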