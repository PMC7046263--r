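# broom-style tidiers for the package's result objects.

#' Tidy a big-Phi result
#'
#' @param x A `phi_result` from [big_phi()].
#' @param ... Unused.
#' @return One-row tibble: state, subsystem, phi, mip, n_concepts,
#'   sum_small_phi, unreachable.
#' @export
tidy.phi_result <- function(x, ...) {
  tibble::tibble(
    state = state_label(x$state),
    subsystem = paste(x$subsystem, collapse = ","),
    phi = x$phi,
    mip = x$mip$label,
    n_concepts = x$n_concepts,
    sum_small_phi = x$sum_small_phi,
    unreachable = x$unreachable
  )
}

#' @rdname tidy.phi_result
#' @export
glance.phi_result <- function(x, ...) {
  tibble::tibble(phi = x$phi, n_concepts = x$n_concepts,
                 cut_strategy = x$cut_strategy)
}

#' Tidy a per-state Phi summary
#'
#' @param x A `phi_summary` from [phi_over_series()].
#' @param ... Unused.
#' @return `tidy()` returns the per-state table; `glance()` the
#'   aggregates.
#' @export
tidy.phi_summary <- function(x, ...) x$per_state

#' @rdname tidy.phi_summary
#' @export
glance.phi_summary <- function(x, ...) {
  tibble::tibble(mean_phi = x$mean_phi, sd_phi = x$sd_phi,
                 max_phi = x$max_phi, min_phi = x$min_phi,
                 weighting = x$weighting, n = x$n)
}

#' Tidy a Markov-chain baseline
#'
#' @param x A `markov_baseline` from [markov_phi_baseline()].
#' @param ... Unused.
#' @return `tidy()` returns the per-repetition summaries; `glance()` one
#'   row of cross-repetition aggregates.
#' @export
tidy.markov_baseline <- function(x, ...) x$per_rep

#' @rdname tidy.markov_baseline
#' @export
glance.markov_baseline <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(n = x$n, reps = x$reps)
  for (k in seq_len(nrow(s))) {
    out[[s$statistic[k]]] <- s$mean[k]
    out[[paste0(s$statistic[k], "_sd")]] <- s$sd[k]
  }
  out
}
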