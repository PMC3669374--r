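#' Per-sample equilibrium radius of gyration
#'
#' Time average of \eqn{R_g} over the post-burn-in records of one trajectory.
#'
#' @param traj A `trajectory_record`.
#' @return Scalar mean \eqn{R_g}.
#' @export
equilibrium_rg <- function(traj) {
  r <- traj$records
  keep <- !r$burn_in
  if (!any(keep)) keep <- rep(TRUE, nrow(r))
  mean(r$rg[keep])
}

#' Ensemble sweep of the radius of gyration over a temperature grid
#'
#' For each temperature an independent ensemble is run and the post-burn-in
#' time-averaged \eqn{R_g} of each sample is aggregated into mean and standard
#' error. A failing temperature is reported with a warning and skipped; the
#' remaining grid is still returned.
#'
#' @inheritParams run_ensemble
#' @param temperatures Strictly increasing grid of reduced temperatures
#'   (at least 3).
#' @param ... Passed to [simulate_chain()] (e.g. `box_size`, `boundary`).
#' @return Object of class `sweep_table`: data frame `temperature`, `rg_mean`,
#'   `rg_sem`, `n_samples`, with attributes `label` (from the matrix) and
#'   `failures`.
#' @export
temperature_sweep <- function(sequence, matrix, temperatures, config,
                              n_samples, master_seed, ...) {
  if (length(temperatures) < 3L) stop("need at least 3 temperatures")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperatures must be strictly increasing")
  rows <- list()
  failures <- character()
  for (k in seq_along(temperatures)) {
    tt <- temperatures[k]
    res <- tryCatch({
      cfg <- config
      cfg$temperature <- tt
      ens <- run_ensemble(sequence, matrix, cfg, n_samples,
                          master_seed + 104729 * (k - 1L), ...)
      rg <- vapply(ens, equilibrium_rg, numeric(1L))
      data.frame(temperature = tt, rg_mean = mean(rg),
                 rg_sem = stats::sd(rg) / sqrt(length(rg)),
                 n_samples = length(rg))
    }, error = function(e) {
      warning("temperature ", tt, " failed: ", conditionMessage(e),
              call. = FALSE)
      failures <<- c(failures, sprintf("T=%g: %s", tt, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  structure(out, label = attr(matrix, "label"), failures = failures,
            class = c("sweep_table", "data.frame"))
}

#' Characteristic temperature of the non-monotonic response
#'
#' Temperature of the interior maximum of `rg_mean`, refined by a local
#' quadratic through the peak point and its two neighbours (so the estimate is
#' not pinned to the grid). Discrete ties break toward lower temperature.
#'
#' @param table A `sweep_table` (columns `temperature`, `rg_mean`).
#' @return \eqn{T_c} (scalar).
#' @export
locate_Tc <- function(table) {
  tt <- table$temperature
  y <- table$rg_mean
  k <- which.max(y)                      # first maximum = lower-T tie break
  if (k == 1L || k == length(y))
    stop("no interior peak: rg_mean is maximal at the grid edge")
  t3 <- tt[(k - 1L):(k + 1L)]
  y3 <- y[(k - 1L):(k + 1L)]
  fit <- stats::lm(y3 ~ t3 + I(t3^2))
  a <- stats::coef(fit)
  tc <- if (is.na(a[3L]) || a[3L] >= 0) t3[2L] else -a[2L] / (2 * a[3L])
  # keep the refinement inside the bracketing interval
  min(max(tc, t3[1L]), t3[3L])
}

interp_crossing <- function(t1, y1, t2, y2, thr) {
  t1 + (thr - y1) * (t2 - t1) / (y2 - y1)
}

#' Non-monotonic response window
#'
#' Operationalizes the temperature range \eqn{\Delta T} over which the
#' rise-then-decay of \eqn{\langle R_g\rangle(T)} occurs as threshold
#' crossings: the low edge is where the curve last rises through
#' `baseline_low + threshold * (peak - baseline_low)` below \eqn{T_c}, the
#' high edge where it first falls through the analogous level above
#' \eqn{T_c}; baselines are the mean of the two lowest-/highest-temperature
#' grid points and crossings are linearly interpolated.
#'
#' @param table A `sweep_table`.
#' @param threshold Rise fraction defining the edges; default 0.25.
#' @return Object of class `response_summary`: list with `T_c`, `window_low`,
#'   `window_high`, `rg_peak`, `rg_low_T_baseline`, `rg_high_T_plateau`,
#'   `label`.
#' @export
response_window <- function(table, threshold = 0.25) {
  tc <- locate_Tc(table)
  tt <- table$temperature
  y <- table$rg_mean
  k <- which.max(y)
  peak <- y[k]
  base_lo <- mean(y[1:2])
  base_hi <- mean(y[(length(y) - 1L):length(y)])
  thr_lo <- base_lo + threshold * (peak - base_lo)
  thr_hi <- base_hi + threshold * (peak - base_hi)

  window_low <- tt[1L]
  for (m in seq(k - 1L, 1L)) {          # walk down from the peak
    if (y[m] < thr_lo) {
      window_low <- interp_crossing(tt[m], y[m], tt[m + 1L], y[m + 1L], thr_lo)
      break
    }
  }
  window_high <- tt[length(tt)]
  for (m in seq(k + 1L, length(tt))) {  # walk up from the peak
    if (y[m] < thr_hi) {
      window_high <- interp_crossing(tt[m - 1L], y[m - 1L], tt[m], y[m], thr_hi)
      break
    }
  }
  structure(list(T_c = tc, window_low = window_low, window_high = window_high,
                 rg_peak = peak, rg_low_T_baseline = base_lo,
                 rg_high_T_plateau = base_hi,
                 grid_spacing = stats::median(diff(tt)),
                 label = attr(table, "label")),
            class = "response_summary")
}

#' @export
print.response_summary <- function(x, ...) {
  cat(sprintf("response_summary%s: T_c = %.4g, window = [%.4g, %.4g]\n",
              if (nzchar(x$label %||% "")) paste0(" (", x$label, ")") else "",
              x$T_c, x$window_low, x$window_high))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Effective dimension from the structure-factor power law
#'
#' Least-squares slope of \eqn{\log S} versus \eqn{\log q} over a window of
#' `fit_width_decades` decades centred on \eqn{q^* = 2\pi/R_g} (wavelengths
#' comparable to the chain size); since \eqn{S(q) \propto q^{-1/\nu} =
#' q^{-D_e}} there, the effective dimension is minus the slope. About 2 for a
#' random coil, 3 for a compact globule, 1 for a rod.
#'
#' @param sq An `sq_table` from [structure_factor()].
#' @param rg Radius of gyration setting the window centre.
#' @param fit_width_decades Window width in decades of q; default 0.5.
#' @return List: `D_e`, `se` (slope standard error), `n_points`,
#'   `q_window`.
#' @export
fit_effective_dimension <- function(sq, rg, fit_width_decades = 0.5) {
  qstar <- 2 * pi / rg
  lo <- qstar / 10^(fit_width_decades / 2)
  hi <- qstar * 10^(fit_width_decades / 2)
  sel <- sq$q >= lo & sq$q <= hi & sq$s > 0
  if (sum(sel) < 4L)
    stop("insufficient data: only ", sum(sel), " S(q) points in [",
         signif(lo, 3), ", ", signif(hi, 3), "]")
  fit <- stats::lm(log(s) ~ log(q), data = sq[sel, ])
  # exact power laws fit perfectly; the zero-residual warning is meaningless
  sm <- suppressWarnings(summary(fit))$coefficients
  list(D_e = -unname(stats::coef(fit)[2L]), se = unname(sm["log(q)", "Std. Error"]),
       n_points = sum(sel), q_window = c(lo, hi))
}

#' Compare characteristic temperatures across potentials
#'
#' Sorts response summaries by \eqn{T_c} and reports pairwise differences with
#' a propagated uncertainty of half a grid spacing per estimate.
#'
#' @param summaries List of `response_summary` objects (at least 2).
#' @return List with `ranking` (data frame `label`, `T_c`, sorted ascending)
#'   and `pairs` (data frame of pairwise differences, `uncertainty`, and a
#'   `tied` flag for differences within resolution).
#' @export
compare_potentials <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 summaries")
  lab <- vapply(summaries, function(s) s$label %||% "", character(1L))
  lab[!nzchar(lab)] <- paste0("potential_", which(!nzchar(lab)))
  tc <- vapply(summaries, function(s) s$T_c, numeric(1L))
  gs <- vapply(summaries, function(s) s$grid_spacing %||% NA_real_, numeric(1L))
  ord <- order(tc, lab)
  ranking <- data.frame(label = lab[ord], T_c = tc[ord])
  cmb <- utils::combn(seq_along(ord), 2L)
  pairs <- data.frame(
    lower = ranking$label[cmb[1L, ]], higher = ranking$label[cmb[2L, ]],
    delta_Tc = ranking$T_c[cmb[2L, ]] - ranking$T_c[cmb[1L, ]])
  u <- sqrt((gs[ord][cmb[1L, ]] / 2)^2 + (gs[ord][cmb[2L, ]] / 2)^2)
  pairs$uncertainty <- u
  pairs$tied <- !is.na(u) & abs(pairs$delta_Tc) <= u
  list(ranking = ranking, pairs = pairs)
}

#' Export a sweep table as CSV
#'
#' @param table A `sweep_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
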