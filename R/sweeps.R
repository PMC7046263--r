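#' Parameter-grid sweep of an information measure
#'
#' For every combination of distance threshold and visual field the
#' trajectory is binarized, a TPM estimated, and the requested measure
#' computed: `"phi"` (mean big Phi over collective states), `"mi"`
#' (mutual information) or `"te"` (summed transfer entropy). Cells whose
#' computation fails are returned as NA with `failed = TRUE` and the sweep
#' continues.
#'
#' @param traj A `school_traj`, already at the sweep's time step.
#' @param zeta Numeric vector of distance thresholds, mm (default the
#'   100..1000 mm grid).
#' @param visual_field Numeric vector of visual fields, rad (default
#'   1.0*pi .. 2.0*pi in steps of 0.2*pi plus 1.9*pi).
#' @param measure `"phi"`, `"mi"` or `"te"`.
#' @param delta Turning threshold, rad per step (default 0).
#' @param cuts,weighting Passed to [phi_over_series()] for `measure =
#'   "phi"`.
#' @return A tibble of class `phi_heatmap` with columns `zeta`,
#'   `visual_field`, `value`, `failed`; attributes `measure`, `n`, `dt`,
#'   `delta`, `weighting`.
#' @export
sweep_measure <- function(traj, zeta = seq(100, 1000, by = 100),
                          visual_field = sort(c(seq(1.0, 2.0, by = 0.2), 1.9)) * pi,
                          measure = c("phi", "mi", "te"), delta = 0,
                          cuts = c("one", "exhaustive"),
                          weighting = c("by_state", "by_time")) {
  measure <- match.arg(measure)
  cuts <- match.arg(cuts)
  weighting <- match.arg(weighting)
  if (!length(zeta) || !length(visual_field)) abort("empty parameter grid")
  dt <- 1 / attr(traj, "frame_rate")
  grid <- tidyr::expand_grid(visual_field = visual_field, zeta = zeta)
  vals <- purrr::pmap(grid, function(visual_field, zeta) {
    tryCatch({
      params <- binarization_params(zeta = zeta, visual_field = visual_field,
                                    delta = delta, dt = dt)
      series <- binarize(traj, params)
      v <- switch(measure,
        phi = phi_over_series(series, weighting = weighting, cuts = cuts)$mean_phi,
        mi = mutual_information(series),
        te = transfer_entropy_sum(series))
      list(value = v, failed = FALSE)
    }, error = function(e) list(value = NA_real_, failed = TRUE))
  })
  out <- dplyr::bind_cols(grid,
                          value = purrr::map_dbl(vals, "value"),
                          failed = purrr::map_lgl(vals, "failed"))
  structure(out, measure = measure, n = attr(traj, "n"), dt = dt,
            delta = delta, weighting = weighting,
            class = c("phi_heatmap", class(out)))
}

#' Heat map as a matrix
#'
#' @param hm A `phi_heatmap` tibble.
#' @return Numeric matrix, visual-field values (rad) as rows, distance
#'   values (mm) as columns.
#' @export
heatmap_matrix <- function(hm) {
  wide <- tidyr::pivot_wider(dplyr::select(hm, "visual_field", "zeta", "value"),
                             names_from = "zeta", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- format(wide$visual_field)
  m
}

#' Distance between two heat maps
#'
#' Root-mean-square ("normalised Frobenius", default) or mean-absolute
#' element-wise difference: both return |c| for maps differing by a
#' constant c. Grids must match.
#'
#' @param a,b `phi_heatmap` tibbles (or plain matrices) on identical
#'   grids.
#' @param method `"frobenius"` (RMS of differences) or `"mean_abs"`.
#' @return Non-negative scalar.
#' @export
matrix_distance <- function(a, b, method = c("frobenius", "mean_abs")) {
  method <- match.arg(method)
  ma <- if (is.matrix(a)) a else heatmap_matrix(a)
  mb <- if (is.matrix(b)) b else heatmap_matrix(b)
  if (!all(dim(ma) == dim(mb))) abort("heat maps are on different grids")
  d <- ma - mb
  if (method == "frobenius") sqrt(mean(d^2)) else mean(abs(d))
}

#' Baseline-adjusted matrix distance between adjacent group sizes
#'
#' For each adjacent pair of group sizes, the mean matrix distance between
#' all cross-group pairs of heat maps, minus the baseline: the mean of all
#' within-group pairwise distances pooled over every group. Negative
#' values (inter smaller than intra) are legitimate. Groups with a single
#' sample contribute no baseline pairs (a warning is raised).
#'
#' @param groups Named list mapping group size to a list of heat maps
#'   (each a `phi_heatmap` or a matrix on a common grid).
#' @param method Passed to [matrix_distance()].
#' @return A tibble with columns `pair`, `inter_md`, `baseline`,
#'   `adjusted_md`.
#' @export
baseline_adjusted_md <- function(groups, method = c("frobenius", "mean_abs")) {
  method <- match.arg(method)
  sizes <- sort(as.integer(names(groups)))
  mats <- lapply(groups, function(g) lapply(g, function(x) {
    if (is.matrix(x)) x else heatmap_matrix(x)
  }))
  intra <- c()
  for (nm in names(mats)) {
    g <- mats[[nm]]
    if (length(g) < 2) {
      warn(sprintf("group %s has a single sample; excluded from the baseline", nm))
      next
    }
    pr <- combn(length(g), 2)
    intra <- c(intra, apply(pr, 2, function(ij) {
      matrix_distance(g[[ij[1]]], g[[ij[2]]], method)
    }))
  }
  if (!length(intra)) abort("no group has >= 2 samples; baseline undefined")
  baseline <- mean(intra)
  rows <- lapply(seq_len(length(sizes) - 1), function(k) {
    a <- mats[[as.character(sizes[k])]]
    b <- mats[[as.character(sizes[k + 1])]]
    inter <- outer(seq_along(a), seq_along(b),
                   Vectorize(function(i, j) matrix_distance(a[[i]], b[[j]], method)))
    tibble::tibble(pair = sprintf("%d-%d", sizes[k], sizes[k + 1]),
                   inter_md = mean(inter),
                   baseline = baseline,
                   adjusted_md = mean(inter) - baseline)
  })
  dplyr::bind_rows(rows)
}

#' Two-sample comparison tests
#'
#' Thin wrapper over the standard tests used for group comparisons:
#' Welch's t-test, the Wilcoxon signed-rank test (paired) and the
#' Mann-Whitney U test (unpaired rank sum), all two-sided.
#'
#' @param x,y Numeric samples (equal length required for
#'   `wilcoxon_signed`).
#' @param test Which test to run.
#' @return A tibble with `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(x, y, test = c("welch_t", "wilcoxon_signed", "mann_whitney_u")) {
  test <- match.arg(test)
  r <- switch(test,
    welch_t = stats::t.test(x, y, var.equal = FALSE),
    wilcoxon_signed = {
      if (length(x) != length(y)) abort("wilcoxon_signed needs paired samples of equal length")
      stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
    },
    mann_whitney_u = stats::wilcox.test(x, y, paired = FALSE, exact = FALSE))
  tibble::tibble(test = test,
                 statistic = unname(r$statistic),
                 p_value = r$p.value)
}
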