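#' Random Markov-chain baseline for integrated information
#'
#' Generates `reps` random state-by-node TPMs (entries Uniform(0, 1)),
#' computes big Phi at every one of the 2^n collective states of each, and
#' summarises: per repetition the mean, (population) standard deviation,
#' max and min of Phi across states; across repetitions the mean and sd of
#' each summary. The cross-rep mean of the per-TPM sd is the sigma(Phi(n))
#' size baseline.
#'
#' @param n Number of nodes (2..5 are practical).
#' @param reps Number of random TPMs (default 100).
#' @param seed Optional RNG seed.
#' @param cuts MIP search strategy (default the cut-one approximation).
#' @return A list of class `markov_baseline` with `per_rep` (tibble: rep,
#'   mean_phi, sd_phi, max_phi, min_phi) and `summary` (tibble: statistic,
#'   mean, sd across reps), plus `n`, `reps`.
#' @examples
#' \donttest{
#' markov_phi_baseline(2, reps = 5, seed = 1)
#' }
#' @export
markov_phi_baseline <- function(n, reps = 100, seed = NULL,
                                cuts = c("one", "exhaustive")) {
  cuts <- match.arg(cuts)
  if (n < 2) abort("`n` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  strategy <- if (cuts == "one") "one" else "all"
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    tpm <- random_tpm(n)
    phis <- cpp_phi_all_states(tpm$probs, strategy)
    mu <- mean(phis)
    per[[r]] <- tibble::tibble(
      rep = r,
      mean_phi = mu,
      sd_phi = sqrt(mean((phis - mu)^2)),
      max_phi = max(phis),
      min_phi = min(phis)
    )
  }
  per_rep <- dplyr::bind_rows(per)
  summary <- tibble::tibble(
    statistic = c("mean_phi", "sd_phi", "max_phi", "min_phi"),
    mean = vapply(per_rep[, -1], mean, numeric(1)),
    sd = vapply(per_rep[, -1], stats::sd, numeric(1))
  )
  structure(list(per_rep = per_rep, summary = summary, n = n, reps = reps,
                 cut_strategy = cuts),
            class = "markov_baseline")
}

#' @export
print.markov_baseline <- function(x, ...) {
  cat(sprintf("<markov_baseline> n = %d, %d random TPMs (%s cuts)\n",
              x$n, x$reps, x$cut_strategy))
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-8s = %.4f +/- %.4f\n", s$statistic[k], s$mean[k], s$sd[k]))
  }
  invisible(x)
}
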