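#' Build a validated multi-agent trajectory
#'
#' A trajectory is a tidy table with one row per individual per frame and
#' columns `frame`, `id`, `x`, `y` (coordinates in mm, origin at a corner of
#' the arena). All individuals must be observed on the same contiguous frame
#' index sequence, of length at least 2, with finite coordinates.
#'
#' @param df A data frame with (at least) frame, id and coordinate columns.
#' @param frame_rate Sampling rate in Hz (frames per second).
#' @param dialect Named character vector mapping the canonical column names
#'   `frame`, `id`, `x`, `y` to the columns of `df`, for files using other
#'   headers.
#' @return A tibble of class `school_traj` with columns `frame`, `id`, `x`,
#'   `y`, individuals sorted by id within frame, and attributes `frame_rate`,
#'   `n` (number of individuals) and `ids`.
#' @examples
#' df <- data.frame(frame = rep(1:3, each = 2), id = rep(1:2, 3),
#'                  x = rnorm(6), y = rnorm(6))
#' traj <- as_trajectory(df, frame_rate = 20)
#' @export
as_trajectory <- function(df, frame_rate,
                          dialect = c(frame = "frame", id = "id", x = "x", y = "y")) {
  stopifnot(is.data.frame(df))
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0) {
    abort("`frame_rate` must be a single positive number (Hz)")
  }
  need <- c("frame", "id", "x", "y")
  dialect <- c(dialect)
  missing_map <- setdiff(need, names(dialect))
  if (length(missing_map)) {
    abort(paste0("dialect must map columns: ", paste(missing_map, collapse = ", ")))
  }
  bad <- setdiff(unname(dialect[need]), names(df))
  if (length(bad)) {
    abort(paste0("columns not found in data: ", paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(
    frame = as.integer(df[[dialect[["frame"]]]]),
    id = df[[dialect[["id"]]]],
    x = as.double(df[[dialect[["x"]]]]),
    y = as.double(df[[dialect[["y"]]]])
  )
  nf <- !is.finite(out$x) | !is.finite(out$y)
  if (any(nf)) {
    k <- which(nf)[1]
    abort(sprintf("non-finite coordinate at frame %d, id %s",
                  out$frame[k], as.character(out$id[k])))
  }
  ids <- sort(unique(out$id))
  if (length(ids) < 1) abort("trajectory has no individuals")
  lens <- table(out$id)
  if (length(unique(as.integer(lens))) != 1) {
    abort(paste0("ragged trajectory: individuals have differing numbers of frames (",
                 paste(sprintf("%s:%d", names(lens), as.integer(lens)), collapse = ", "), ")"))
  }
  frames <- sort(unique(out$frame))
  per_id_frames <- tapply(out$frame, out$id, function(f) identical(sort(f), frames))
  if (!all(unlist(per_id_frames))) {
    abort("all individuals must be observed on the same frame sequence")
  }
  if (length(frames) < 2) abort("trajectory must span at least 2 frames")
  if (any(diff(frames) != diff(frames)[1])) {
    abort("frame indices must be evenly spaced")
  }
  out <- dplyr::arrange(out, .data$frame, .data$id)
  structure(out,
            frame_rate = as.double(frame_rate),
            n = length(ids), ids = ids,
            class = c("school_traj", class(tibble::tibble())))
}

#' Read a trajectory CSV
#'
#' Expects one row per individual per frame; the canonical header is
#' `frame,id,x,y`, other layouts are handled through `dialect`.
#'
#' @inheritParams as_trajectory
#' @param path Path to a CSV file.
#' @return A `school_traj` tibble, see [as_trajectory()].
#' @export
read_trajectory <- function(path, frame_rate,
                            dialect = c(frame = "frame", id = "id", x = "x", y = "y")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trajectory(df, frame_rate = frame_rate, dialect = dialect)
}

#' Resample a trajectory to a coarser time step
#'
#' Keeps every stride-th frame, where the stride is `dt * frame_rate`; `dt`
#' must therefore be an integer multiple of the original frame interval
#' (e.g. 120 fps and dt = 0.05 s give stride 6).
#'
#' @param traj A `school_traj` tibble.
#' @param dt Target time step in seconds.
#' @return A `school_traj` tibble with updated `frame_rate = 1/dt`.
#' @export
resample_trajectory <- function(traj, dt) {
  fr <- attr(traj, "frame_rate")
  stride <- dt * fr
  if (abs(stride - round(stride)) > 1e-8 || round(stride) < 1) {
    lo <- max(1, floor(stride)); hi <- ceiling(stride)
    abort(sprintf(
      "dt = %g s is not an integer multiple of the frame interval (1/%g s); nearest valid dt: %g or %g s",
      dt, fr, lo / fr, hi / fr))
  }
  stride <- as.integer(round(stride))
  frames <- sort(unique(traj$frame))
  keep <- frames[seq(1, length(frames), by = stride)]
  out <- dplyr::filter(traj, .data$frame %in% keep)
  as_trajectory(out, frame_rate = fr / stride)
}

#' Derive per-step headings and speeds
#'
#' Headings are backward finite differences: the heading at frame t is the
#' unit vector of x(t) - x(t-1), so they are defined from the second frame
#' on. A step with zero displacement carries the previous heading forward;
#' leading zero-displacement steps (no previous heading) are returned as NA
#' and counted in the `n_undefined` attribute, carried steps in `n_carried`.
#'
#' @param traj A `school_traj` tibble.
#' @return A tibble with columns `frame`, `id`, `hx`, `hy` (unit heading)
#'   and `speed` (mm/s), one row per individual per frame from the second
#'   frame on; attributes `n_carried` and `n_undefined`.
#' @export
derive_headings <- function(traj) {
  fr <- attr(traj, "frame_rate")
  dt <- 1 / fr
  ids <- attr(traj, "ids")
  n_carried <- 0L
  n_undef <- 0L
  res <- lapply(ids, function(i) {
    d <- dplyr::filter(traj, .data$id == i)
    d <- dplyr::arrange(d, .data$frame)
    dx <- diff(d$x); dy <- diff(d$y)
    len <- sqrt(dx^2 + dy^2)
    if (all(len == 0)) {
      abort(sprintf("individual %s never moves; headings undefined", as.character(i)))
    }
    hx <- dx / len; hy <- dy / len
    for (k in seq_along(len)) {
      if (len[k] == 0) {
        if (k == 1 || is.na(hx[k - 1])) {
          hx[k] <- NA_real_; hy[k] <- NA_real_
          n_undef <<- n_undef + 1L
        } else {
          hx[k] <- hx[k - 1]; hy[k] <- hy[k - 1]
          n_carried <<- n_carried + 1L
        }
      }
    }
    tibble::tibble(frame = d$frame[-1], id = i, hx = hx, hy = hy, speed = len / dt)
  })
  out <- dplyr::arrange(dplyr::bind_rows(res), .data$frame, .data$id)
  structure(out, n_carried = n_carried, n_undefined = n_undef,
            frame_rate = fr, n = length(ids), ids = ids)
}

#' @export
print.school_traj <- function(x, ...) {
  cat(sprintf("<school_traj> %d individuals, %d frames at %g Hz\n",
              attr(x, "n"), length(unique(x$frame)), attr(x, "frame_rate")))
  NextMethod()
}
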