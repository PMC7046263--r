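#' Cause and effect repertoires
#'
#' The effect repertoire of a mechanism M (in the current state) over a
#' purview Z is the distribution of Z's next state obtained by clamping M to
#' its state and marginalising all other inputs with the maximum-entropy
#' (uniform) distribution; it factorises over purview nodes. The cause
#' repertoire is the Bayesian inversion with a uniform prior over past
#' purview states; mechanism nodes are treated as independent virtual
#' elements whose likelihoods are multiplied before normalising.
#'
#' An empty mechanism gives the unconstrained repertoire (uniform for the
#' cause side, the product of uniform-input node marginals for the effect
#' side). An empty purview gives the scalar distribution (a single 1).
#'
#' @param tpm A `school_tpm` (or bare 2^N x N probability matrix).
#' @param state Binary vector of length N, current collective state.
#' @param mechanism Integer vector of node indices (may be empty).
#' @param purview Integer vector of node indices (may be empty).
#' @return A numeric vector over purview states (little-endian within the
#'   purview), named by state label. Cause repertoires that are undefined
#'   (the mechanism state is unreachable from every purview state) carry
#'   attribute `undefined = TRUE` and are returned uniform.
#' @export
effect_repertoire <- function(tpm, state, mechanism, purview) {
  tpm <- tpm_probs(tpm)
  if (!length(purview)) return(structure(1, names = ""))
  v <- cpp_effect_repertoire(tpm, as.integer(state),
                             as.integer(mechanism), as.integer(purview))
  name_repertoire(v, length(purview))
}

#' @rdname effect_repertoire
#' @export
cause_repertoire <- function(tpm, state, mechanism, purview) {
  tpm <- tpm_probs(tpm)
  if (!length(purview)) return(structure(1, names = ""))
  r <- cpp_cause_repertoire(tpm, as.integer(state),
                            as.integer(mechanism), as.integer(purview))
  out <- name_repertoire(r$distribution, length(purview))
  if (r$undefined) attr(out, "undefined") <- TRUE
  out
}

name_repertoire <- function(v, k) {
  if (k == 0) return(structure(v, names = ""))
  labs <- apply(all_states(k), 1, state_label)
  stats::setNames(as.numeric(v), labs)
}

tpm_probs <- function(tpm) {
  if (inherits(tpm, "school_tpm")) tpm$probs else as.matrix(tpm)
}

#' Earth mover's distance between repertoires
#'
#' Exact minimum-cost transport between two distributions over the states
#' of k binary nodes, with the Hamming distance between states as ground
#' metric.
#'
#' @param p,q Numeric vectors of equal power-of-two length, each summing
#'   to the same total mass.
#' @return Non-negative scalar distance.
#' @examples
#' emd(c(1, 0), c(0, 1))  # one unit of mass over Hamming distance 1
#' @export
emd <- function(p, q) {
  if (length(p) != length(q)) abort("repertoires must share the same purview")
  cpp_emd_hamming(as.numeric(p), as.numeric(q))
}

#' Mechanism-level integrated information (a concept)
#'
#' For every purview, the cause (effect) repertoire is compared with its
#' minimum-information partition over all mechanism/purview bipartitions
#' (including cuts against the empty set); small phi for the purview is the
#' EMD between the unpartitioned and MIP-partitioned repertoire, and the
#' maximally irreducible cause/effect maximises it over purviews (ties go
#' to the larger purview). The concept's phi is the minimum of the two
#' maxima; mechanisms with phi = 0 specify no concept and return `NULL`.
#'
#' @inheritParams effect_repertoire
#' @param mechanism Non-empty integer vector of node indices.
#' @return A list of class `concept` (mechanism, phi, cause and effect
#'   sides with purview, phi and repertoire), or `NULL` when phi = 0.
#' @export
small_phi <- function(tpm, state, mechanism) {
  tpm <- tpm_probs(tpm)
  r <- cpp_concept(tpm, as.integer(state), as.integer(mechanism))
  if (r$phi <= 0) return(NULL)
  structure(r, class = "concept")
}

#' @export
print.concept <- function(x, ...) {
  cat(sprintf("<concept> mechanism {%s}  phi = %.6f\n",
              paste(x$mechanism, collapse = ","), x$phi))
  cat(sprintf("  cause : purview {%s} phi = %.6f\n",
              paste(x$cause$purview, collapse = ","), x$cause$phi))
  cat(sprintf("  effect: purview {%s} phi = %.6f\n",
              paste(x$effect$purview, collapse = ","), x$effect$phi))
  invisible(x)
}

#' Cause-effect structure of a subsystem in a state
#'
#' All concepts (mechanisms with small phi > 0) of the subsystem.
#'
#' @inheritParams effect_repertoire
#' @param subsystem Integer vector of node indices; default all nodes.
#' @return A tibble of class `ces` with one row per concept: `mechanism`
#'   (list column), `phi`, `cause_purview`, `cause_phi`, `effect_purview`,
#'   `effect_phi`.
#' @export
cause_effect_structure <- function(tpm, state, subsystem = NULL) {
  tpm <- tpm_probs(tpm)
  n <- ncol(tpm)
  if (!is.null(subsystem) && !setequal(subsystem, seq_len(n))) {
    cnd <- condense_tpm(tpm, state, subsystem)
    tpm <- cnd$tpm; state <- cnd$state
  }
  cl <- cpp_ces(tpm, as.integer(state))
  out <- tibble::tibble(
    mechanism = purrr::map(cl, "mechanism"),
    phi = purrr::map_dbl(cl, "phi"),
    cause_purview = purrr::map(cl, "cause_purview"),
    cause_phi = purrr::map_dbl(cl, "cause_phi"),
    effect_purview = purrr::map(cl, "effect_purview"),
    effect_phi = purrr::map_dbl(cl, "effect_phi")
  )
  if (!is.null(subsystem)) {
    sub <- sort(subsystem)
    relabel <- function(ix) sub[ix]
    out$mechanism <- purrr::map(out$mechanism, relabel)
    out$cause_purview <- purrr::map(out$cause_purview, relabel)
    out$effect_purview <- purrr::map(out$effect_purview, relabel)
  }
  structure(out, class = c("ces", class(out)))
}

#' Sever directed connections between two parts of the system
#'
#' Replaces the inputs from `from` into `to` with independent
#' maximum-entropy noise: each target node's conditional probabilities are
#' averaged uniformly over the severed input bits. Connections within each
#' part, and from `to` back into `from`, are left intact.
#'
#' @inheritParams effect_repertoire
#' @param from,to Disjoint integer vectors of node indices.
#' @return A `school_tpm` (occupancy cleared).
#' @export
apply_cut <- function(tpm, from, to) {
  tpm <- tpm_probs(tpm)
  if (length(intersect(from, to))) abort("cut parts must be disjoint")
  as_school_tpm(cpp_apply_cut(tpm, as.integer(from), as.integer(to)))
}

#' System-level cut sets
#'
#' `cut_one_cuts()` returns the 2N unidirectional cuts that isolate one
#' node in either direction (the cut-one approximation to the MIP search);
#' `exhaustive_cuts()` returns all 2 (2^(N-1) - 1) ordered non-trivial
#' bipartitions.
#'
#' @param n Number of nodes (>= 2).
#' @return A tibble with list columns `from` and `to` and a `label` column
#'   in the `{1} -/-> {2,3}` notation.
#' @export
cut_one_cuts <- function(n) {
  if (n < 2) abort("`n` must be >= 2")
  cuts_tibble(n, "one")
}

#' @rdname cut_one_cuts
#' @export
exhaustive_cuts <- function(n) {
  if (n < 2) abort("`n` must be >= 2")
  cuts_tibble(n, "all")
}

cuts_tibble <- function(n, strategy) {
  all_n <- seq_len(n)
  if (strategy == "one") {
    froms <- c(lapply(all_n, function(i) i),
               lapply(all_n, function(i) setdiff(all_n, i)))
  } else {
    masks <- seq_len(2^n - 2)
    subs <- lapply(masks, function(m) which(index_state(m + 1L, n) == 1L))
    ord <- order(lengths(subs), masks)
    froms <- subs[ord]
  }
  tos <- lapply(froms, function(f) setdiff(all_n, f))
  tibble::tibble(from = froms, to = tos,
                 label = purrr::map2_chr(froms, tos, format_cut))
}

#' Distance between the intact and a perturbed cause-effect structure
#'
#' Extended earth mover's distance in concept space: small-phi mass is
#' transported between the concepts of the two structures (or created /
#' destroyed at the null concept of the intact system), with ground cost
#' the sum of cause- and effect-repertoire EMDs over the full subsystem.
#'
#' @param tpm_a Intact `school_tpm` (or matrix).
#' @param tpm_b Perturbed (e.g. cut) TPM over the same nodes.
#' @inheritParams effect_repertoire
#' @return Non-negative scalar.
#' @export
ces_distance <- function(tpm_a, tpm_b, state) {
  cpp_ces_distance(tpm_probs(tpm_a), tpm_probs(tpm_b), as.integer(state))
}

#' System-level integrated information (big Phi)
#'
#' Big Phi for a subsystem in a state is the minimum, over unidirectional
#' system cuts, of the distance between the intact cause-effect structure
#' and the structure after the cut; the minimising cut is the system's
#' minimum information partition (MIP). `cuts = "one"` restricts the search
#' to the 2N single-node cuts (the default approximation, an upper bound on
#' the exhaustive value); `cuts = "exhaustive"` searches every ordered
#' bipartition. States that the TPM cannot reach are reported with
#' `phi = 0` and `unreachable = TRUE` (their cause repertoires are
#' undefined). Ties between cuts resolve to the earliest cut in canonical
#' order (from-part size, then node order), recorded in the result.
#'
#' @inheritParams effect_repertoire
#' @param subsystem Integer vector of node indices; default all nodes.
#'   Background nodes are frozen at their state.
#' @param cuts `"one"` (cut-one approximation) or `"exhaustive"`.
#' @return A list of class `phi_result`: `phi`, `state`, `subsystem`,
#'   `mip` (list with `from`, `to`, `label`), `n_concepts`,
#'   `sum_small_phi`, `unreachable`, and a tibble `cut_distances`.
#' @examples
#' tpm <- make_fixture("copy_pair")
#' big_phi(tpm, c(1, 1))
#' @export
big_phi <- function(tpm, state, subsystem = NULL, cuts = c("one", "exhaustive")) {
  cuts <- match.arg(cuts)
  tpm <- tpm_probs(tpm)
  n_full <- ncol(tpm)
  state <- as.integer(state)
  sub <- if (is.null(subsystem)) seq_len(n_full) else sort(unique(as.integer(subsystem)))
  if (length(sub) < 2) abort("subsystem must have at least 2 nodes")
  if (!setequal(sub, seq_len(n_full))) {
    cnd <- condense_tpm(tpm, state, sub)
    r <- cpp_big_phi(cnd$tpm, cnd$state, strategy = if (cuts == "one") "one" else "all")
    relabel <- function(ix) sub[ix]
  } else {
    r <- cpp_big_phi(tpm, state, strategy = if (cuts == "one") "one" else "all")
    relabel <- identity
  }
  ct <- cuts_tibble(length(sub), if (cuts == "one") "one" else "all")
  ct$from <- purrr::map(ct$from, relabel)
  ct$to <- purrr::map(ct$to, relabel)
  ct$label <- purrr::map2_chr(ct$from, ct$to, format_cut)
  ct$distance <- if (length(r$cut_distances)) as.numeric(r$cut_distances) else
    rep(NA_real_, nrow(ct))
  mip_from <- relabel(r$mip_from)
  mip_to <- relabel(r$mip_to)
  structure(list(
    phi = r$phi,
    state = state,
    subsystem = sub,
    mip = list(from = mip_from, to = mip_to,
               label = if (length(mip_from)) format_cut(mip_from, mip_to) else NA_character_),
    n_concepts = r$n_concepts,
    sum_small_phi = r$sum_small_phi,
    unreachable = r$unreachable,
    cut_distances = ct,
    cut_strategy = cuts
  ), class = "phi_result")
}

# Restrict a full-system TPM to a subsystem, freezing background nodes at
# their current state: keep the rows whose background bits match, drop the
# background columns.
condense_tpm <- function(tpm, state, subsystem) {
  n <- ncol(tpm)
  sub <- sort(subsystem)
  bg <- setdiff(seq_len(n), sub)
  k <- length(sub)
  rows <- integer(2^k)
  for (r in seq_len(2^k)) {
    bits <- integer(n)
    bits[sub] <- index_state(r, k)
    bits[bg] <- state[bg]
    rows[r] <- state_index(bits)
  }
  list(tpm = tpm[rows, sub, drop = FALSE], state = state[sub])
}

#' @export
print.phi_result <- function(x, ...) {
  cat(sprintf("<phi_result> state %s  subsystem {%s}\n",
              state_label(x$state), paste(x$subsystem, collapse = ",")))
  cat(sprintf("  Phi = %.6f  (%s cuts)  MIP: %s\n", x$phi,
              x$cut_strategy, x$mip$label))
  cat(sprintf("  %d concepts, sum small phi = %.6f%s\n", x$n_concepts,
              x$sum_small_phi, if (x$unreachable) "  [state unreachable]" else ""))
  invisible(x)
}

#' Major complex: the subsystem maximising big Phi
#'
#' Evaluates every candidate subsystem of size >= 2 (singletons have
#' Phi = 0 by convention) and returns the one with maximal Phi; ties go to
#' the larger subsystem, then to node order.
#'
#' @inheritParams big_phi
#' @return A list with `subsystem` and the corresponding `phi_result`,
#'   plus a tibble `candidates` of all evaluated subsystems.
#' @export
major_complex <- function(tpm, state, cuts = c("one", "exhaustive")) {
  cuts <- match.arg(cuts)
  tpm <- tpm_probs(tpm)
  n <- ncol(tpm)
  if (n > 8) abort("major complex search is limited to 8 nodes")
  subs <- unlist(lapply(2:n, function(k) {
    asplit(combn(n, k), 2)
  }), recursive = FALSE)
  results <- lapply(subs, function(s) big_phi(tpm, state, subsystem = as.integer(s), cuts = cuts))
  phis <- vapply(results, function(r) r$phi, numeric(1))
  sizes <- lengths(subs)
  best <- order(-phis, -sizes)[1]
  cand <- tibble::tibble(
    subsystem = purrr::map_chr(subs, ~ paste(.x, collapse = ",")),
    size = sizes, phi = phis
  )
  list(subsystem = as.integer(subs[[best]]), result = results[[best]],
       candidates = cand)
}

#' Big Phi over every collective state of a series
#'
#' Computes Phi once per collective state of the TPM (estimated from the
#' series unless supplied) and aggregates. `by_state` weights all 2^N
#' states equally; `by_time` weights states by their occupancy in the
#' series, i.e. averages the Phi time series.
#'
#' @param series A `state_series`; may be NULL when `tpm` is given
#'   (then `by_time` is unavailable unless the TPM carries occupancy).
#' @param tpm Optional `school_tpm`; estimated from `series` when NULL.
#' @param weighting `"by_state"` or `"by_time"`.
#' @inheritParams big_phi
#' @return A list of class `phi_summary`: `per_state` tibble (state,
#'   occupancy, phi, mip, unreachable), `mean_phi`, `sd_phi`, `max_phi`,
#'   `min_phi`, `weighting`, `n`.
#' @export
phi_over_series <- function(series = NULL, tpm = NULL,
                            weighting = c("by_state", "by_time"),
                            cuts = c("one", "exhaustive")) {
  weighting <- match.arg(weighting)
  cuts <- match.arg(cuts)
  if (is.null(tpm)) {
    if (is.null(series)) abort("supply a series or a TPM")
    tpm <- estimate_tpm(series)
  }
  stopifnot(inherits(tpm, "school_tpm"))
  n <- tpm$n
  ns <- 2^n
  res <- lapply(seq_len(ns), function(k) {
    big_phi(tpm$probs, index_state(k, n), cuts = cuts)
  })
  per_state <- tibble::tibble(
    state = vapply(seq_len(ns), function(k) state_label(index_state(k, n)), character(1)),
    occupancy = tpm$occupancy,
    phi = vapply(res, function(r) r$phi, numeric(1)),
    mip = vapply(res, function(r) r$mip$label, character(1)),
    unreachable = vapply(res, function(r) r$unreachable, logical(1))
  )
  w <- if (weighting == "by_time") as.numeric(per_state$occupancy) else rep(1, ns)
  if (sum(w) == 0) {
    abort("by_time weighting needs occupancy counts (estimate the TPM from a series)")
  }
  w <- w / sum(w)
  mu <- sum(w * per_state$phi)
  keep <- w > 0
  structure(list(
    per_state = per_state,
    mean_phi = mu,
    sd_phi = sqrt(sum(w * (per_state$phi - mu)^2)),
    max_phi = max(per_state$phi[keep]),
    min_phi = min(per_state$phi[keep]),
    weighting = weighting,
    cut_strategy = cuts,
    n = n
  ), class = "phi_summary")
}

#' @export
print.phi_summary <- function(x, ...) {
  cat(sprintf("<phi_summary> %d nodes, %s weighting (%s cuts)\n",
              x$n, x$weighting, x$cut_strategy))
  cat(sprintf("  <Phi> = %.4f  sd = %.4f  max = %.4f  min = %.4f\n",
              x$mean_phi, x$sd_phi, x$max_phi, x$min_phi))
  invisible(x)
}
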