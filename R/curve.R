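#' Tabulate a GIET distance-to-ratio calibration curve
#'
#' Samples [lifetimeRatio()] on a dense grid and wraps it in a strictly
#' monotone, shape-preserving interpolant (monotone piecewise cubic,
#' `splinefun(method = "monoH.FC")`). Monotonicity of the sampled ratios
#' is verified at build time; a violation indicates a quadrature failure
#' and aborts.
#'
#' @param fluor A [fluorophore()].
#' @param stack An [opticalStack()]; default [defaultStackFor()].
#' @param d_min,d_max Distance range in nm; must satisfy
#'   `monolayer thickness <= d_min < d_max <= 50`.
#' @param step Grid step in nm, at most 0.1.
#' @return An object of class `"gietCurve"` with fields `d`, `ratio`,
#'   `fluor`, `stack`, `monolayer` (nm) and the interpolant.
#' @export
gietCurve <- function(fluor, stack = defaultStackFor(fluor),
                      d_min = NULL, d_max = 30, step = 0.05) {
  stopifnot(inherits(fluor, "fluorophore"), inherits(stack, "opticalStack"))
  t_ml <- monolayerThickness(stack)
  if (is.null(d_min)) d_min <- t_ml
  if (d_min < t_ml) stop("'d_min' must be at least the monolayer thickness (",
                         t_ml, " nm)")
  if (d_max > 50) stop("'d_max' must be at most 50 nm")
  if (d_min >= d_max) stop("'d_min' must be smaller than 'd_max'")
  if (step > 0.1) stop("'step' must be at most 0.1 nm")
  d <- seq(d_min, d_max, by = step)
  if (d[length(d)] < d_max) d <- c(d, d_max)
  ratio <- lifetimeRatio(fluor, stack, d)
  if (any(diff(ratio) <= 0))
    stop("sampled ratios are not strictly increasing; quadrature failure ",
         "near d = ", signif(d[which(diff(ratio) <= 0)[1L]], 4), " nm")
  if (any(ratio <= 0 | ratio > 1))
    stop("sampled ratios outside (0, 1]")
  newGietCurve(d, ratio, fluor = fluor, stack = stack, monolayer = t_ml)
}

newGietCurve <- function(d, ratio, fluor = NULL, stack = NULL,
                         monolayer = 2.5) {
  structure(list(
    d = d, ratio = ratio, fluor = fluor, stack = stack,
    monolayer = monolayer,
    fun = stats::splinefun(d, ratio, method = "monoH.FC"),
    inv_range = range(ratio)
  ), class = "gietCurve")
}

#' @export
print.gietCurve <- function(x, ...) {
  who <- if (!is.null(x$fluor)) x$fluor$name else "tabulated"
  cat(sprintf(
    "<gietCurve> %s: d in [%.2f, %.2f] nm (%d samples), ratio in [%.4f, %.4f]\n",
    who, min(x$d), max(x$d), length(x$d), x$inv_range[1], x$inv_range[2]))
  invisible(x)
}

#' Evaluate a GIET curve at arbitrary distances
#'
#' @param object A `"gietCurve"`.
#' @param d Distances in nm within the curve's range.
#' @param ... Unused.
#' @return Interpolated lifetime/intensity ratios.
#' @export
predict.gietCurve <- function(object, d, ...) {
  if (any(d < min(object$d) - 1e-9 | d > max(object$d) + 1e-9))
    stop("'d' outside the curve range [", min(object$d), ", ",
         max(object$d), "] nm")
  object$fun(d)
}

#' Invert a measured ratio to an axial distance
#'
#' Solves `curve(d) = ratio` by root bisection on the strictly monotone
#' interpolant. The uncertainty interval comes from inverting
#' `ratio -/+ ratio_sd`, clipped to the curve range (the asymmetric
#' bracket convention of the original calibration), and the height above
#' the monolayer is `h = d - monolayer thickness`.
#'
#' @param curve A `"gietCurve"`.
#' @param ratio Measured `tau_G/tau_0` or `I_G/I_0`.
#' @param ratio_sd Standard deviation of the ratio (>= 0).
#' @param tol Distance tolerance of the bisection in nm.
#' @return A `"distanceEstimate"`: list with `d`, `h`, `d_low`, `d_high`,
#'   `h_low`, `h_high`, `ratio`, `ratio_sd`.
#' @export
invertRatio <- function(curve, ratio, ratio_sd = 0, tol = 1e-4) {
  stopifnot(inherits(curve, "gietCurve"))
  if (length(ratio) != 1L || ratio_sd < 0)
    stop("'ratio' must be a scalar and 'ratio_sd' non-negative")
  lo <- curve$inv_range[1]; hi <- curve$inv_range[2]
  if (ratio < lo || ratio > hi)
    stop(sprintf(
      "ratio %.4g outside the attainable interval [%.4g, %.4g] of this curve",
      ratio, lo, hi))
  solve1 <- function(r) {
    if (r <= lo) return(min(curve$d))
    if (r >= hi) return(max(curve$d))
    stats::uniroot(function(x) curve$fun(x) - r,
                   lower = min(curve$d), upper = max(curve$d),
                   tol = tol)$root
  }
  d <- solve1(ratio)
  d_lo <- solve1(max(ratio - ratio_sd, lo))
  d_hi <- solve1(min(ratio + ratio_sd, hi))
  t_ml <- curve$monolayer
  structure(list(d = d, h = d - t_ml,
                 d_low = d_lo, d_high = d_hi,
                 h_low = d_lo - t_ml, h_high = d_hi - t_ml,
                 ratio = ratio, ratio_sd = ratio_sd),
            class = "distanceEstimate")
}

#' @export
print.distanceEstimate <- function(x, ...) {
  cat(sprintf(
    "<distanceEstimate> ratio %.3f +/- %.3f -> d = %.2f nm (%.2f-%.2f), h = %.2f nm (%.2f-%.2f)\n",
    x$ratio, x$ratio_sd, x$d, x$d_low, x$d_high, x$h, x$h_low, x$h_high))
  invisible(x)
}

#' Export a GIET curve as delimited text
#'
#' Two tab-separated columns `d_nm` and `ratio`, UTF-8, '.' decimal.
#'
#' @param curve A `"gietCurve"`.
#' @param path Output file path.
#' @export
writeGietCurve <- function(curve, path) {
  stopifnot(inherits(curve, "gietCurve"))
  utils::write.table(
    data.frame(d_nm = curve$d, ratio = curve$ratio),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GIET curve from delimited text
#'
#' Reads the two-column (`d_nm`, `ratio`) format written by
#' [writeGietCurve()] and rebuilds the monotone interpolant. The
#' fluorophore/stack provenance is not stored in the text format.
#'
#' @param path File path.
#' @param monolayer Monolayer thickness in nm used for the `h = d - t`
#'   convention (default 2.5).
#' @return A `"gietCurve"`.
#' @export
readGietCurve <- function(path, monolayer = 2.5) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("d_nm", "ratio") %in% names(tab)))
    stop("curve file must have columns 'd_nm' and 'ratio'")
  if (any(diff(tab$d_nm) <= 0) || any(diff(tab$ratio) <= 0))
    stop("curve samples must be strictly increasing in d and ratio")
  newGietCurve(tab$d_nm, tab$ratio, monolayer = monolayer)
}
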