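#' State-by-node transition probability matrices
#'
#' A `school_tpm` stores the conditional probability that each node
#' (individual) is ON at the next step given the past collective state:
#' a 2^N x N matrix whose row order is little-endian in the node bits
#' (row 1 = all OFF, row 2 = node 1 ON, ...). Nodes are conditionally
#' independent given the past state, which is the canonical input form for
#' the IIT computations. `occupancy` records how often each past state was
#' visited by the estimating series (zero for TPMs built directly).
#'
#' @param probs A 2^N x N matrix of ON-probabilities.
#' @param occupancy Optional integer vector of per-state visit counts.
#' @return An object of class `school_tpm`.
#' @export
as_school_tpm <- function(probs, occupancy = NULL) {
  probs <- as.matrix(probs)
  n <- ncol(probs)
  assert_prob_matrix(probs, n)
  if (is.null(occupancy)) occupancy <- integer(2^n)
  stopifnot(length(occupancy) == 2^n)
  structure(list(probs = unname(probs), n = n,
                 occupancy = as.integer(occupancy),
                 state_indexing = "little_endian"),
            class = "school_tpm")
}

#' Estimate the transition probability matrix of a binary state series
#'
#' Maximum-likelihood estimate: entry (s, i) is the fraction of transitions
#' out of past collective state s in which node i was ON at the next step.
#' Past states never visited carry no information and are filled with the
#' maximum-entropy value 0.5 (the IIT computations need a fully specified
#' TPM); optional Laplace smoothing `alpha` shrinks all entries towards 0.5.
#'
#' @param series A `state_series` tibble (see [binarize()]).
#' @param alpha Laplace smoothing pseudo-count (default 0, plain ML).
#' @return A `school_tpm` with per-state `occupancy` counts.
#' @examples
#' s <- as_state_series(matrix(c(0,0, 1,1, 0,0, 1,1), ncol = 2, byrow = TRUE))
#' estimate_tpm(s)
#' @export
estimate_tpm <- function(series, alpha = 0) {
  m <- state_matrix(series)
  n <- ncol(m)
  t_len <- nrow(m)
  if (t_len < 2) abort("need at least 2 steps to estimate a TPM")
  idx <- as.integer(m %*% 2^(seq_len(n) - 1)) + 1L
  past <- idx[-t_len]
  ns <- 2^n
  visits <- tabulate(past, nbins = ns)
  on_counts <- matrix(0, ns, n)
  nxt <- m[-1, , drop = FALSE]
  for (i in seq_len(n)) {
    on_counts[, i] <- tabulate(past[nxt[, i] == 1L], nbins = ns)
  }
  probs <- (on_counts + alpha) / (visits + 2 * alpha)
  probs[visits + 2 * alpha == 0, ] <- 0.5
  as_school_tpm(probs, occupancy = visits)
}

#' Expand a state-by-node TPM to state-by-state form
#'
#' Row s, column s' is P(X_t = s' | X_{t-1} = s), using conditional
#' independence of the nodes given the past state. Rows sum to 1.
#'
#' @param tpm A `school_tpm`.
#' @return A 2^N x 2^N matrix, little-endian state order on both axes.
#' @export
state_by_state <- function(tpm) {
  stopifnot(inherits(tpm, "school_tpm"))
  n <- tpm$n
  ns <- 2^n
  states <- all_states(n)
  out <- matrix(1, ns, ns)
  for (i in seq_len(n)) {
    p_on <- tpm$probs[, i]
    out <- out * ifelse(matrix(states[, i], ns, ns, byrow = TRUE),
                        matrix(p_on, ns, ns),
                        matrix(1 - p_on, ns, ns))
  }
  out
}

#' Generate a random state-by-node TPM
#'
#' Every conditional ON-probability is drawn independently from
#' Uniform(0, 1) — the random time-homogeneous Markov chains used as the
#' size baseline for integrated information.
#'
#' @param n Number of nodes (>= 2).
#' @param seed Optional seed; when NULL the current RNG stream is used.
#' @return A `school_tpm`.
#' @export
random_tpm <- function(n, seed = NULL) {
  if (n < 2) abort("`n` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  as_school_tpm(matrix(runif(2^n * n), 2^n, n))
}

#' Marginalise out inputs excluded by a connectivity matrix
#'
#' For each node j, inputs i with `adjacency[i, j] == 0` are replaced by
#' independent maximum-entropy noise (the node's conditional is averaged
#' uniformly over those inputs). With a zero diagonal this removes
#' self-loops, supporting analyses on networks without self history.
#'
#' @param tpm A `school_tpm`.
#' @param adjacency N x N 0/1 matrix, entry (i, j) = 1 when node i feeds
#'   node j. Defaults to all ones (complete graph with self-loops).
#' @return A `school_tpm`.
#' @export
apply_connectivity <- function(tpm, adjacency) {
  stopifnot(inherits(tpm, "school_tpm"))
  n <- tpm$n
  adjacency <- as.matrix(adjacency)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n,
            all(adjacency %in% c(0, 1)))
  probs <- tpm$probs
  for (j in seq_len(n)) {
    cut_in <- which(adjacency[, j] == 0)
    if (!length(cut_in)) next
    probs[, j] <- cpp_apply_cut(probs, cut_in, j)[, j]
  }
  as_school_tpm(probs, tpm$occupancy)
}

#' Drop self-loops from a TPM
#'
#' Shorthand for [apply_connectivity()] with a complete graph minus the
#' diagonal.
#'
#' @param tpm A `school_tpm`.
#' @return A `school_tpm`.
#' @export
drop_self_loops <- function(tpm) {
  adj <- matrix(1, tpm$n, tpm$n)
  diag(adj) <- 0
  apply_connectivity(tpm, adj)
}

#' Write / read a TPM
#'
#' CSV holds the bare 2^N x N probability matrix (header `p1..pN`); JSON
#' additionally records `n`, `state_indexing` and occupancy.
#'
#' @param tpm A `school_tpm`.
#' @param path Output path; format chosen by extension (.csv or .json).
#' @return `path` invisibly; `read_tpm` returns the `school_tpm`.
#' @export
write_tpm <- function(tpm, path) {
  stopifnot(inherits(tpm, "school_tpm"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(n = tpm$n, state_indexing = tpm$state_indexing,
                              probs = tpm$probs, occupancy = tpm$occupancy),
                         path, digits = NA, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(tpm$probs)
    names(df) <- paste0("p", seq_len(tpm$n))
    readr::write_csv(df, path)
  }
  invisible(path)
}

#' @rdname write_tpm
#' @export
read_tpm <- function(path) {
  if (grepl("\\.json$", path)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(j$state_indexing, "little_endian")) {
      abort("only little_endian state indexing is supported")
    }
    as_school_tpm(j$probs, j$occupancy)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    as_school_tpm(as.matrix(df))
  }
}

#' @export
print.school_tpm <- function(x, ...) {
  cat(sprintf("<school_tpm> %d nodes, %d past states (little-endian)\n", x$n, 2^x$n))
  if (any(x$occupancy > 0)) {
    cat(sprintf("  estimated from %d transitions; %d/%d states unvisited (filled 0.5)\n",
                sum(x$occupancy), sum(x$occupancy == 0), 2^x$n))
  }
  print(round(x$probs, 4))
  invisible(x)
}

#' @describeIn as_school_tpm Tidy a TPM into a long tibble (state label,
#'   node, ON-probability, occupancy).
#' @param x A `school_tpm`.
#' @param ... Unused.
#' @export
tidy.school_tpm <- function(x, ...) {
  n <- x$n
  labels <- apply(all_states(n), 1, state_label)
  tibble::tibble(
    state = rep(labels, n),
    node = rep(seq_len(n), each = 2^n),
    p_on = as.vector(x$probs),
    occupancy = rep(x$occupancy, n)
  )
}
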