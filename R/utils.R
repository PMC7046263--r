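# Internal helpers shared across modules.

# States are bit vectors (node 1, node 2, ...); the scalar index is
# little-endian: index = 1 + sum_i s_i * 2^(i-1), so node 1 is the least
# significant bit. All matrices indexed by collective state use this order.

state_index <- function(bits) {
  1L + as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

index_state <- function(k, n) {
  as.integer(bitwAnd(bitwShiftR(k - 1L, seq_len(n) - 1L), 1L))
}

state_label <- function(bits) paste(bits, collapse = "")

all_states <- function(n) {
  t(vapply(seq_len(2^n), index_state, integer(n), n = n))
}

format_cut <- function(from, to) {
  paste0("{", paste(from, collapse = ","), "} -/-> {", paste(to, collapse = ","), "}")
}

assert_prob_matrix <- function(x, n, what = "TPM") {
  if (!is.matrix(x) || nrow(x) != 2^n || ncol(x) != n) {
    abort(sprintf("%s must be a 2^n x n matrix (got %d x %d for n = %d)",
                  what, NROW(x), NCOL(x), n))
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s entries must be probabilities in [0, 1]", what))
  }
  invisible(x)
}

# Angle between two 2-d vectors, in [0, pi]. Undefined (NA) if either is zero.
vec_angle <- function(ax, ay, bx, by) {
  na <- sqrt(ax^2 + ay^2)
  nb <- sqrt(bx^2 + by^2)
  dot <- (ax * bx + ay * by) / (na * nb)
  out <- acos(pmin(pmax(dot, -1), 1))
  out[na == 0 | nb == 0] <- NA_real_
  out
}
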