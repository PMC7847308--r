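#' Mass-normalized intensity ratio
#'
#' Normalizes the raw graphene/reference intensity ratio by the ratio of
#' immobilized-mass signals measured label-free on the two substrates:
#' `I_G/I_0 = (m0/mG) * (IG_raw/I0_raw)`.
#'
#' @param m0,mG Mass signals (ng/mm^2) on the reference substrate and on
#'   graphene.
#' @param I0_raw,IG_raw Raw fluorescence intensities on the same scale.
#' @return The mass-normalized ratio `I_G/I_0`.
#' @export
normalizeIntensity <- function(m0, mG, I0_raw, IG_raw) {
  vals <- c(m0 = m0, mG = mG, I0_raw = I0_raw, IG_raw = IG_raw)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all of m0, mG, I0_raw, IG_raw must be positive and finite")
  (m0 / mG) * (IG_raw / I0_raw)
}

#' Background-corrected FRAP normalization
#'
#' `(I_inside - I_bg) / (I_outside - I_bg)` per time point; the series of
#' these values over time is the recovery curve.
#'
#' @param I_inside Intensity inside the bleached region (a.u.).
#' @param I_outside Intensity of the unbleached reference region (a.u.).
#' @param I_bg Background intensity (a.u.).
#' @return Normalized recovery value(s).
#' @export
frapNormalize <- function(I_inside, I_outside, I_bg) {
  den <- I_outside - I_bg
  if (any(!is.finite(den)) || any(den <= 0))
    stop("degenerate FRAP record: I_outside must exceed I_bg")
  (I_inside - I_bg) / den
}

#' Vertical dye distance of a tilted membrane-anchored nanoruler
#'
#' `d = l_dna * sin(alpha) + l_ml`: the contour length of the label
#' position projected by the tilt angle, plus the monolayer thickness.
#'
#' @param l_dna Contour length from the anchor to the label in nm (0 for
#'   a lipid-conjugated dye).
#' @param alpha Tilt angle between ruler and surface in degrees, (0, 90].
#' @param l_ml Monolayer thickness in nm (default 2.5).
#' @return Vertical distance(s) d in nm.
#' @export
rulerDistance <- function(l_dna, alpha, l_ml = 2.5) {
  if (any(l_dna < 0)) stop("'l_dna' must be non-negative")
  if (any(alpha <= 0 | alpha > 90)) stop("'alpha' must lie in (0, 90] degrees")
  l_dna * sin(alpha * pi / 180) + l_ml
}

#' Axial separation of two label positions on the same ruler
#'
#' @param l_dna_a,l_dna_b Contour lengths in nm.
#' @param alpha Tilt angle in degrees.
#' @return `|l_dna_a - l_dna_b| * sin(alpha)` in nm.
#' @export
labelSeparation <- function(l_dna_a, l_dna_b, alpha) {
  if (any(alpha <= 0 | alpha > 90)) stop("'alpha' must lie in (0, 90] degrees")
  abs(l_dna_a - l_dna_b) * sin(alpha * pi / 180)
}

#' Global tilt-angle fit of nanoruler ratios against a GIET curve
#'
#' Finds the single tilt angle shared by all rulers that minimizes the sum
#' of squared differences between measured ratios and the curve evaluated
#' at `l_dna * sin(alpha) + l_ml`, by bounded scalar minimization on
#' (0, 90] degrees. Uncertainty is a seeded bootstrap over measurements.
#'
#' @param measurements Data frame with columns `l_dna_nm` and `ratio`;
#'   optional `ratio_sd` (used when `weighted = TRUE`), `label_end`,
#'   `mode`.
#' @param curve A [gietCurve()] covering the implied distance range.
#' @param l_ml Monolayer thickness in nm.
#' @param weighted Weight residuals by `1/ratio_sd^2`.
#' @param n_boot Bootstrap replicates (>= 200 recommended); 0 disables.
#' @param seed Integer seed for the bootstrap.
#' @return A `"tiltFit"`: `alpha` (deg), `se` (deg), `rss`, `n`,
#'   `at_bound` flag, bootstrap draws.
#' @export
fitTiltAngle <- function(measurements, curve, l_ml = 2.5, weighted = FALSE,
                         n_boot = 200, seed = NULL) {
  stopifnot(inherits(curve, "gietCurve"))
  req <- c("l_dna_nm", "ratio")
  if (!is.data.frame(measurements) || !all(req %in% names(measurements)))
    stop("'measurements' must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (length(unique(measurements$l_dna_nm)) < 3L)
    stop("tilt angle unidentifiable: need at least 3 distinct l_dna values")
  w <- if (weighted) {
    if (!"ratio_sd" %in% names(measurements) ||
        any(measurements$ratio_sd <= 0))
      stop("weighted fit requires positive 'ratio_sd'")
    1 / measurements$ratio_sd^2
  } else rep(1, nrow(measurements))

  d_lo <- min(curve$d); d_hi <- max(curve$d)
  objective <- function(alpha, dat, wt) {
    d <- rulerDistance(dat$l_dna_nm, alpha, l_ml)
    d <- pmin(pmax(d, d_lo), d_hi)
    sum(wt * (dat$ratio - curve$fun(d))^2)
  }
  fit1 <- function(dat, wt) {
    stats::optimize(objective, c(0.01, 90), dat = dat, wt = wt,
                    tol = 1e-6)$minimum
  }
  alpha <- fit1(measurements, w)
  at_bound <- alpha < 0.5 || alpha > 89.5
  if (at_bound)
    warning("fitted tilt angle is at the boundary of (0, 90] degrees")

  boot <- numeric(0)
  if (n_boot > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    n <- nrow(measurements)
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      dat <- measurements[idx, , drop = FALSE]
      if (length(unique(dat$l_dna_nm)) < 3L) return(NA_real_)
      fit1(dat, w[idx])
    }, numeric(1))
    boot <- boot[is.finite(boot)]
  }
  structure(list(alpha = alpha,
                 se = if (length(boot) > 1) stats::sd(boot) else NA_real_,
                 rss = objective(alpha, measurements, w),
                 n = nrow(measurements), at_bound = at_bound,
                 boot = boot, l_ml = l_ml, weighted = weighted),
            class = "tiltFit")
}

#' @export
print.tiltFit <- function(x, ...) {
  cat(sprintf(
    "<tiltFit> alpha = %.2f deg (bootstrap s.e. %.2f, %d draws), RSS %.3g, n = %d%s\n",
    x$alpha, x$se, length(x$boot), x$rss, x$n,
    if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}

#' Read a nanoruler measurement table
#'
#' Tab-delimited with header columns `l_dna_nm`, `label_end`, `ratio`,
#' `ratio_sd`, `mode`.
#'
#' @param path File path.
#' @return Data frame of measurements.
#' @export
readRulerTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("l_dna_nm", "ratio")
  if (!all(need %in% names(tab)))
    stop("ruler table must have columns ", paste(need, collapse = ", "))
  if (any(tab$ratio <= 0 | tab$ratio >= 1))
    stop("ratios must lie in (0, 1)")
  if (any(tab$l_dna_nm < 0)) stop("l_dna_nm must be non-negative")
  tab
}

#' Write a nanoruler measurement table
#'
#' @param measurements Data frame as in [readRulerTable()].
#' @param path File path.
#' @export
writeRulerTable <- function(measurements, path) {
  utils::write.table(measurements, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
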