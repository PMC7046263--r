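#' Mutual information between successive collective states
#'
#' Plug-in (maximum likelihood) estimate of I(X(t); X(t - lag)) over the
#' collective state alphabet, in bits: H(X(t)) - H(X(t) | X(t - lag)).
#'
#' @param series A `state_series` tibble.
#' @param lag_steps Lag in steps (default 1).
#' @return Mutual information in bits (non-negative).
#' @export
mutual_information <- function(series, lag_steps = 1) {
  m <- state_matrix(series)
  n <- ncol(m)
  idx <- as.integer(m %*% 2^(seq_len(n) - 1)) + 1L
  t_len <- length(idx)
  if (t_len <= lag_steps) abort("series shorter than the lag")
  past <- idx[seq_len(t_len - lag_steps)]
  pres <- idx[seq_len(t_len - lag_steps) + lag_steps]
  plugin_mi(cbind(past, pres))
}

# MI from a 2-column matrix of symbol pairs, base 2.
plugin_mi <- function(xy) {
  jt <- table(xy[, 1], xy[, 2]) / nrow(xy)
  px <- rowSums(jt); py <- colSums(jt)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ent(px) + ent(py) - ent(as.vector(jt))
}

#' Summed pairwise transfer entropy
#'
#' Sum over ordered pairs (i, j), i != j, of the transfer entropy
#' T(i -> j) = H(x_j(t) | x_j(t-1)) - H(x_j(t) | x_i(t-1), x_j(t-1)),
#' plug-in estimates with one step of history, in bits.
#'
#' @inheritParams mutual_information
#' @return Summed transfer entropy in bits.
#' @export
transfer_entropy_sum <- function(series, lag_steps = 1) {
  m <- state_matrix(series)
  n <- ncol(m)
  if (n < 2) abort("transfer entropy needs at least 2 individuals")
  t_len <- nrow(m)
  if (t_len <= lag_steps) abort("series shorter than the lag")
  sel_past <- seq_len(t_len - lag_steps)
  sel_pres <- sel_past + lag_steps
  total <- 0
  for (j in seq_len(n)) {
    xj <- m[sel_pres, j]
    xj_p <- m[sel_past, j]
    h_self <- cond_entropy(xj, xj_p)
    for (i in seq_len(n)) {
      if (i == j) next
      xi_p <- m[sel_past, i]
      total <- total + (h_self - cond_entropy(xj, xj_p + 2L * xi_p))
    }
  }
  total
}

# H(target | cond), plug-in, base 2; cond is an integer code.
cond_entropy <- function(target, cond) {
  jt <- table(cond, target) / length(target)
  pc <- rowSums(jt)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  ent(as.vector(jt)) - ent(pc)
}
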