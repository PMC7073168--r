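#' Clip a melt dataset to the active melt region
#'
#' Retains the reads whose temperature lies in the closed interval
#' \code{[lower, upper]}; the printed region limits are compared with a
#' 1e-9 degC tolerance so grid points sitting exactly on a limit are never
#' dropped by floating-point edge effects.
#'
#' @param ds A [melt_dataset].
#' @param lower,upper Active melt-region limits (degC).
#' @return The clipped [melt_dataset] (at least 5 reads, else an error).
#' @export
clip_melt_region <- function(ds, lower, upper) {
  stopifnot(inherits(ds, "melt_dataset"), lower < upper)
  tol <- 1e-9
  keep <- ds$temperatures >= lower - tol & ds$temperatures <= upper + tol
  if (sum(keep) < 5L)
    stop("melt region [", lower, ", ", upper, "] of marker '",
         ds$marker_id, "' retains ", sum(keep),
         " reads; need at least 5", call. = FALSE)
  melt_dataset(ds$temperatures[keep],
               ds$fluorescence[keep, , drop = FALSE],
               sample_ids = ds$sample_ids, marker_id = ds$marker_id)
}

#' Per-curve min-max normalization
#'
#' Rescales each sample's curve to \code{(F - min) / (max - min)} within
#' the (already clipped) region, so every curve attains 0 and 1. This is
#' the scheme of the PCA calling pipeline, which takes only the two
#' melt-region limits as input. Constant (failed-well) curves are excluded
#' with a warning rather than aborting the plate; their ids are recorded in
#' the \code{"excluded_samples"} attribute.
#'
#' @param ds A [melt_dataset], typically from [clip_melt_region()].
#' @return A normalized [melt_dataset].
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "melt_dataset"))
  f <- ds$fluorescence
  lo <- apply(f, 2, min); hi <- apply(f, 2, max)
  flat <- hi - lo <= .Machine$double.eps * pmax(abs(hi), 1)
  if (all(flat))
    stop("all curves are constant over the melt region", call. = FALSE)
  if (any(flat))
    warning("excluding constant curve(s): ",
            paste(ds$sample_ids[flat], collapse = ", "), call. = FALSE)
  keep <- which(!flat)
  norm <- sweep(f[, keep, drop = FALSE], 2, lo[keep], "-")
  norm <- sweep(norm, 2, (hi - lo)[keep], "/")
  out <- melt_dataset(ds$temperatures, norm,
                      sample_ids = ds$sample_ids[keep],
                      marker_id = ds$marker_id)
  attr(out, "excluded_samples") <- ds$sample_ids[flat]
  out
}

#' Two-baseline melt-curve normalization
#'
#' The classic HRM-software scheme: per curve, a least-squares line is
#' fitted to the pre-melt window (upper baseline, fully double-stranded)
#' and another to the post-melt window (lower baseline, fully melted);
#' the curve is rescaled to \code{(F - L(T)) / (U(T) - L(T))} and clipped
#' to \code{[-0.05, 1.05]}, so the pre-melt plateau maps near 1 and the
#' post-melt plateau near 0. Samples whose fitted baselines cross inside
#' the active region are flagged in the \code{"baseline_warn"} attribute.
#'
#' @param ds A [melt_dataset] still covering the baseline windows (i.e.
#'   not yet clipped to the active region).
#' @param cfg Marker configuration (a row of [load_marker_fixtures()] as
#'   returned by [marker_config()]), providing \code{premelt_lo/hi},
#'   \code{postmelt_lo/hi} and the active-region limits.
#' @return A normalized [melt_dataset] on the full input grid.
#' @export
baseline_normalize <- function(ds, cfg) {
  stopifnot(inherits(ds, "melt_dataset"))
  tg <- ds$temperatures
  tol <- 1e-9
  pre <- which(tg >= cfg$premelt_lo - tol & tg <= cfg$premelt_hi + tol)
  post <- which(tg >= cfg$postmelt_lo - tol & tg <= cfg$postmelt_hi + tol)
  if (length(pre) < 2L || length(post) < 2L)
    stop("pre- and post-melt windows must each contain at least 2 reads ",
         "(marker '", cfg$marker_id, "')", call. = FALSE)
  fit_lines <- function(idx) {
    x <- cbind(1, tg[idx])
    b <- solve(crossprod(x), crossprod(x, ds$fluorescence[idx, , drop = FALSE]))
    cbind(1, tg) %*% b    # predictions on the full grid, reads x samples
  }
  upper <- fit_lines(pre)
  lower <- fit_lines(post)
  norm <- pmin(pmax((ds$fluorescence - lower) / (upper - lower), -0.05), 1.05)
  active <- tg >= cfg$lower_limit - tol & tg <= cfg$upper_limit + tol
  warn <- apply(upper[active, , drop = FALSE] <=
                  lower[active, , drop = FALSE], 2, any)
  if (any(warn))
    warning("fitted baselines cross inside the active region for: ",
            paste(ds$sample_ids[warn], collapse = ", "), call. = FALSE)
  out <- melt_dataset(tg, norm, sample_ids = ds$sample_ids,
                      marker_id = ds$marker_id)
  attr(out, "baseline_warn") <- stats::setNames(warn, ds$sample_ids)
  out
}

#' Difference plot data
#'
#' Subtracts a reference sample's normalized curve from every curve,
#' emphasizing shape differences between variants.
#'
#' @param ds_norm A normalized [melt_dataset].
#' @param reference Sample id of the reference curve.
#' @return A [melt_dataset] of difference curves (the reference maps to
#'   the zero curve).
#' @export
difference_plot <- function(ds_norm, reference) {
  stopifnot(inherits(ds_norm, "melt_dataset"))
  i <- match(reference, ds_norm$sample_ids)
  if (is.na(i))
    stop("reference sample '", reference, "' not on the plate",
         call. = FALSE)
  melt_dataset(ds_norm$temperatures,
               ds_norm$fluorescence - ds_norm$fluorescence[, i],
               sample_ids = ds_norm$sample_ids,
               marker_id = ds_norm$marker_id)
}

#' Melting temperature from the derivative curve
#'
#' Tm called as the temperature of steepest fluorescence loss: the maximum
#' of \code{-dF/dT} by central finite differences, ties broken toward the
#' lower temperature. A curve with no descending segment has no melting
#' transition and raises an error.
#'
#' @param temperatures Strictly increasing numeric grid (>= 3 reads).
#' @param curve Fluorescence values on the grid.
#' @return Tm in degC (a grid temperature).
#' @export
derivative_tm <- function(temperatures, curve) {
  n <- length(temperatures)
  if (n < 3L || length(curve) != n)
    stop("need at least 3 reads and matching curve length", call. = FALSE)
  i <- 2:(n - 1)
  neg_slope <- -(curve[i + 1] - curve[i - 1]) /
    (temperatures[i + 1] - temperatures[i - 1])
  if (all(neg_slope <= 0))
    stop("curve never descends; no melting transition to locate",
         call. = FALSE)
  temperatures[i][which.max(neg_slope)]
}

#' Plot melt or difference curves
#'
#' Base-graphics rendering of a plate's curves, one line per sample.
#'
#' @param ds A [melt_dataset].
#' @param main Plot title; defaults to the marker id.
#' @param ylab Y-axis label.
#' @return \code{ds}, invisibly.
#' @export
plot_melt_curves <- function(ds, main = NULL, ylab = "fluorescence") {
  stopifnot(inherits(ds, "melt_dataset"))
  graphics::matplot(ds$temperatures, ds$fluorescence, type = "l", lty = 1,
                    col = grDevices::hcl.colors(ncol(ds$fluorescence),
                                                "Dark 3"),
                    xlab = "temperature (°C)", ylab = ylab,
                    main = main %||% ds$marker_id)
  invisible(ds)
}
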