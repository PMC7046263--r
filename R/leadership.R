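#' Index of the single OFF individual
#'
#' Returns the index of the unique OFF individual when the collective state
#' has exactly one 0 bit, and 0 otherwise.
#'
#' @param state Binary vector (one collective state) or T x N matrix.
#' @return Integer (or integer vector for a matrix input) in 0..N.
#' @examples
#' single_off_index(c(0, 1, 1, 1, 1))  # 1
#' single_off_index(c(1, 1, 1, 1, 1))  # 0
#' @export
single_off_index <- function(state) {
  if (is.matrix(state)) return(apply(state, 1, single_off_index))
  off <- which(state == 0)
  if (length(off) == 1) off else 0L
}

#' Positional leader at one step
#'
#' The average group direction is the normalised mean of the unit headings;
#' the leader is the individual whose position projects furthest onto it.
#' Ties go to the smallest index. When the headings cancel (zero mean
#' vector) the leader is undefined and NA is returned.
#'
#' @param positions N x 2 coordinate matrix (mm).
#' @param headings N x 2 unit-heading matrix.
#' @return Integer index, or NA when the group direction is undefined.
#' @export
positional_leader <- function(positions, headings) {
  positions <- as.matrix(positions)
  headings <- as.matrix(headings)
  if (anyNA(headings)) return(NA_integer_)
  gx <- mean(headings[, 1]); gy <- mean(headings[, 2])
  nrm <- sqrt(gx^2 + gy^2)
  if (nrm < 1e-12) return(NA_integer_)
  proj <- positions[, 1] * (gx / nrm) + positions[, 2] * (gy / nrm)
  which.max(proj)  # which.max takes the first (smallest index) on ties
}

#' Classify IIT leadership from the MIP cut direction
#'
#' When the system MIP isolates the single OFF individual, the direction of
#' the severed edges distinguishes passive leadership (`{off} -/-> rest`:
#' the weak link is the flow severed from the leader, most information
#' flows from the other members) from active leadership
#' (`rest -/-> {off}`: most information flows from the leader). Any other
#' cut is `"none"`.
#'
#' @param single_off Index of the single OFF individual (0 if none).
#' @param mip_from,mip_to Node index vectors of the MIP cut.
#' @return `"passive"`, `"active"` or `"none"`.
#' @export
classify_leadership <- function(single_off, mip_from, mip_to) {
  if (single_off < 1) return("none")
  if (identical(as.integer(mip_from), as.integer(single_off))) return("passive")
  if (identical(as.integer(mip_to), as.integer(single_off))) return("active")
  "none"
}

#' Per-step leadership records
#'
#' Joins, for every step of a binarized trajectory: the collective state,
#' its big Phi and MIP (computed once per state from the estimated TPM),
#' the single-OFF index, the positional leader, and the leadership
#' classification.
#'
#' @param traj A `school_traj`, resampled to `params$dt`.
#' @param params [binarization_params()].
#' @param tpm Optional `school_tpm`; estimated from the binarized series
#'   when NULL.
#' @param cuts MIP search strategy, `"one"` or `"exhaustive"`.
#' @return A tibble of class `leadership_records` with columns `t`,
#'   `state`, `phi`, `single_off`, `positional_leader`, `mip`,
#'   `classification`; attribute `n_undefined_direction` counts steps
#'   excluded for an undefined group direction.
#' @export
leadership_records <- function(traj, params, tpm = NULL,
                               cuts = c("one", "exhaustive")) {
  cuts <- match.arg(cuts)
  series <- binarize(traj, params)
  n <- attr(series, "n")
  if (is.null(tpm)) tpm <- estimate_tpm(series)
  res <- lapply(seq_len(2^n), function(k) {
    big_phi(tpm$probs, index_state(k, n), cuts = cuts)
  })
  phis <- vapply(res, function(r) r$phi, numeric(1))
  mips <- lapply(res, function(r) r$mip)

  hd <- derive_headings(traj)
  ids <- attr(traj, "ids")
  frames <- sort(unique(traj$frame))
  traj_o <- dplyr::arrange(traj, .data$id, .data$frame)
  px <- matrix(traj_o$x, length(frames), n)
  py <- matrix(traj_o$y, length(frames), n)
  hd_o <- dplyr::arrange(hd, .data$id, .data$frame)
  hx <- matrix(NA_real_, length(frames), n)
  hy <- matrix(NA_real_, length(frames), n)
  hx[match(hd_o$frame, frames) + (match(hd_o$id, ids) - 1L) * length(frames)] <- hd_o$hx
  hy[match(hd_o$frame, frames) + (match(hd_o$id, ids) - 1L) * length(frames)] <- hd_o$hy

  m <- state_matrix(series)
  t_steps <- nrow(series)
  n_undef <- 0L
  state_chr <- character(t_steps)
  phi_col <- numeric(t_steps)
  soff_col <- integer(t_steps)
  leader_col <- integer(t_steps)
  mip_col <- character(t_steps)
  class_col <- character(t_steps)
  for (r in seq_len(t_steps)) {
    fr_ix <- match(series$t[r], frames)
    bits <- m[r, ]
    k <- state_index(bits)
    leader <- positional_leader(cbind(px[fr_ix, ], py[fr_ix, ]),
                                cbind(hx[fr_ix, ], hy[fr_ix, ]))
    if (is.na(leader)) n_undef <- n_undef + 1L
    soff <- single_off_index(bits)
    mip <- mips[[k]]
    state_chr[r] <- state_label(bits)
    phi_col[r] <- phis[k]
    soff_col[r] <- as.integer(soff)
    leader_col[r] <- as.integer(leader)
    mip_col[r] <- mip$label
    class_col[r] <- if (soff >= 1 && length(mip$from)) {
      classify_leadership(soff, mip$from, mip$to)
    } else "none"
  }
  out <- tibble::tibble(t = series$t, state = state_chr, phi = phi_col,
                        single_off = soff_col, positional_leader = leader_col,
                        mip = mip_col, classification = class_col)
  structure(out, n_undefined_direction = n_undef, n = n,
            class = c("leadership_records", class(out)))
}

#' Matching rate between single-OFF individuals and positional leaders
#'
#' Percentage of single-OFF steps in which the OFF individual is also the
#' positional leader. Steps with an undefined group direction are excluded
#' from numerator and denominator.
#'
#' @param records A `leadership_records` tibble (or any tibble with
#'   `single_off` and `positional_leader` columns).
#' @return Percentage in `[0, 100]`, or NA when no single-OFF step exists.
#' @export
matching_rate <- function(records) {
  ok <- records$single_off >= 1 & !is.na(records$positional_leader)
  if (!any(ok)) return(NA_real_)
  100 * mean(records$single_off[ok] == records$positional_leader[ok])
}

#' Matching rate between single-OFF individuals and the MIP cut
#'
#' Among single-OFF steps, the percentage whose system MIP isolates the OFF
#' individual (in either direction, `{off} -/-> rest` or
#' `rest -/-> {off}`).
#'
#' @param records A `leadership_records` tibble (needs `single_off`,
#'   `mip` and the number of individuals as attribute `n` or via `n`).
#' @param n Number of individuals; taken from the records attribute when
#'   missing.
#' @return Percentage in `[0, 100]`, or NA when no single-OFF step exists.
#' @export
mip_single_off_match_rate <- function(records, n = NULL) {
  n <- n %||% attr(records, "n")
  if (is.null(n)) abort("supply `n` (number of individuals)")
  ok <- records$single_off >= 1
  if (!any(ok)) return(NA_real_)
  iso <- vapply(which(ok), function(r) {
    off <- records$single_off[r]
    rest <- setdiff(seq_len(n), off)
    records$mip[r] %in% c(format_cut(off, rest), format_cut(rest, off))
  }, logical(1))
  100 * mean(iso)
}
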