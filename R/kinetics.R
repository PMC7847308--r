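#' Pooled state occupancies with bootstrap s.e.m.
#'
#' The occupancy of a state is the number of frames assigned to it across
#' all decoded paths divided by the total number of frames. The s.e.m. is
#' a seeded bootstrap over traces.
#'
#' @param paths List of integer state paths from [viterbiDecode()].
#' @param K Number of states; default the largest index present.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Integer seed.
#' @return Data frame with `state`, `occupancy`, `sem`.
#' @export
stateOccupancies <- function(paths, K = NULL, n_boot = 200L, seed = NULL) {
  if (length(paths) == 0L) stop("need at least one decoded path")
  if (is.null(K)) K <- max(unlist(paths))
  counts <- vapply(paths, function(p) tabulate(p, K), numeric(K))
  if (K == 1L) counts <- matrix(counts, nrow = 1L)
  occ <- rowSums(counts) / sum(counts)
  sem <- rep(0, K)
  if (length(paths) > 1L && n_boot > 0L) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    n <- length(paths)
    draws <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cs <- rowSums(counts[, idx, drop = FALSE])
      cs / sum(cs)
    }, numeric(K))
    if (K == 1L) draws <- matrix(draws, nrow = 1L)
    sem <- apply(draws, 1L, stats::sd)
  }
  data.frame(state = seq_len(K), occupancy = occ, sem = sem)
}

#' Dwell-time and transition-rate analysis of decoded paths
#'
#' Dwell times are the maximal constant runs of each path; the first and
#' last run of every path are censored (their start/end was not observed)
#' and are excluded from the exponential fits. The exit rate of a state is
#' `1/tau` from a least-squares fit of the log survival function of its
#' complete dwell times; pairwise rates split the exit rate by observed
#' transition counts: `k(i -> j) = k_exit(i) * N(i -> j) / sum_j N(i -> j)`.
#' States with fewer than `min_dwells` complete dwells get `NA` rates
#' (counts are still reported).
#'
#' @param paths List of integer state paths.
#' @param frame_interval Frame interval in seconds (default 0.032).
#' @param K Number of states; default the largest index present.
#' @param min_dwells Minimum complete dwells for a rate fit (default 5).
#' @return A `"kineticsSummary"`: `dwell_mean` (s), `exit_rate` (1/s),
#'   `pair_rates` (K x K, 1/s), `transition_counts` (K x K), `n_dwells`.
#' @export
transitionKinetics <- function(paths, frame_interval = 0.032, K = NULL,
                               min_dwells = 5L) {
  if (frame_interval <= 0) stop("'frame_interval' must be positive")
  if (is.null(K)) K <- max(unlist(paths))
  dwell <- vector("list", K)
  counts <- matrix(0L, K, K)
  for (p in paths) {
    r <- rle(p)
    m <- length(r$lengths)
    if (m >= 2L)
      for (i in seq_len(m - 1L))
        counts[r$values[i], r$values[i + 1L]] <-
          counts[r$values[i], r$values[i + 1L]] + 1L
    if (m >= 3L)  # interior runs only: first and last are censored
      for (i in 2:(m - 1L))
        dwell[[r$values[i]]] <- c(dwell[[r$values[i]]],
                                  r$lengths[i] * frame_interval)
  }
  dwell_mean <- vapply(dwell, function(d)
    if (length(d)) mean(d) else NA_real_, numeric(1))
  exit_rate <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    d <- dwell[[k]]
    if (length(d) >= min_dwells)
      exit_rate[k] <- 1 / fitExponentialDwell(d)
  }
  pair_rates <- matrix(NA_real_, K, K)
  for (k in seq_len(K)) {
    tot <- sum(counts[k, ])
    if (is.finite(exit_rate[k]) && tot > 0)
      pair_rates[k, ] <- exit_rate[k] * counts[k, ] / tot
  }
  diag(pair_rates) <- 0
  structure(list(dwell_mean = dwell_mean, exit_rate = exit_rate,
                 pair_rates = pair_rates, transition_counts = counts,
                 n_dwells = vapply(dwell, length, integer(1)),
                 frame_interval = frame_interval),
            class = "kineticsSummary")
}

# mono-exponential dwell-time constant tau (s) by least squares on the log
# empirical survival function
fitExponentialDwell <- function(d) {
  d <- sort(d)
  n <- length(d)
  surv <- 1 - (seq_len(n) - 0.5) / n     # midpoint survival estimate
  fit <- stats::lm(log(surv) ~ d + 0)
  -1 / stats::coef(fit)[[1L]]
}

#' @export
print.kineticsSummary <- function(x, ...) {
  K <- length(x$exit_rate)
  lab <- if (K == 3L) c("L", "M", "H") else paste0("S", seq_len(K))
  cat("<kineticsSummary>\n")
  for (k in seq_len(K))
    cat(sprintf("  %s: mean dwell %.3f s, exit rate %s 1/s (%d complete dwells)\n",
                lab[k], x$dwell_mean[k],
                if (is.na(x$exit_rate[k])) "NA" else
                  sprintf("%.3f", x$exit_rate[k]),
                x$n_dwells[k]))
  invisible(x)
}

#' Transition density of decoded traces
#'
#' For every state change along a decoded path, records the mean intensity
#' of the segment before and after the transition and bins the pairs into
#' a 2D histogram.
#'
#' @param paths List of integer state paths.
#' @param traces Matching list of `"smTrace"` objects or numeric vectors.
#' @param breaks Number of bins per axis, or a vector of break points.
#' @return A `"transitionDensity"`: `points` (data frame `before`,
#'   `after`), `counts` (matrix), `breaks`.
#' @export
transitionDensity <- function(paths, traces, breaks = 30L) {
  stopifnot(length(paths) == length(traces))
  before <- numeric(0); after <- numeric(0)
  for (i in seq_along(paths)) {
    x <- if (inherits(traces[[i]], "smTrace")) traces[[i]]$intensity
         else as.numeric(traces[[i]])
    r <- rle(paths[[i]])
    m <- length(r$lengths)
    if (m < 2L) next
    ends <- cumsum(r$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    seg_mean <- vapply(seq_len(m),
                       function(j) mean(x[starts[j]:ends[j]]), numeric(1))
    before <- c(before, seg_mean[-m])
    after <- c(after, seg_mean[-1L])
  }
  if (length(before) == 0L) {
    return(structure(list(points = data.frame(before = numeric(0),
                                              after = numeric(0)),
                          counts = matrix(0, 0, 0), breaks = numeric(0)),
                     class = "transitionDensity"))
  }
  if (length(breaks) == 1L)
    breaks <- seq(min(before, after), max(before, after),
                  length.out = breaks + 1L)
  bx <- cut(before, breaks, include.lowest = TRUE)
  by <- cut(after, breaks, include.lowest = TRUE)
  structure(list(points = data.frame(before = before, after = after),
                 counts = table(before = bx, after = by),
                 breaks = breaks),
            class = "transitionDensity")
}

#' @export
print.transitionDensity <- function(x, ...) {
  cat(sprintf("<transitionDensity> %d transitions, %d x %d bins\n",
              nrow(x$points), nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Convert fitted state means to axial heights
#'
#' Per state, `I_G/I_0` is the state mean divided by the mean on-glass
#' intensity; the ratio (and its s.d.) is inverted on the supplied GIET
#' curve via [invertRatio()], with the bracket convention of the ensemble
#' analysis.
#'
#' @param model A [hmmFit()] `"stateModel"`.
#' @param reference_mean_on_glass Mean single-molecule intensity on glass
#'   (the Gaussian-fit mean of the unquenched reference), same scale as
#'   the trace intensities.
#' @param curve A [gietCurve()].
#' @return Data frame with one row per state: `state`, `ratio`,
#'   `ratio_sd`, `d`, `h`, `h_low`, `h_high`.
#' @export
statesToHeights <- function(model, reference_mean_on_glass, curve) {
  stopifnot(inherits(model, "stateModel"), inherits(curve, "gietCurve"))
  if (reference_mean_on_glass <= 0)
    stop("'reference_mean_on_glass' must be positive")
  ratio <- model$means / reference_mean_on_glass
  sd_r <- model$sds / reference_mean_on_glass
  est <- lapply(seq_len(model$K),
                function(k) invertRatio(curve, ratio[k], sd_r[k]))
  data.frame(
    state = seq_len(model$K),
    ratio = ratio, ratio_sd = sd_r,
    d = vapply(est, `[[`, numeric(1), "d"),
    h = vapply(est, `[[`, numeric(1), "h"),
    h_low = vapply(est, `[[`, numeric(1), "h_low"),
    h_high = vapply(est, `[[`, numeric(1), "h_high"))
}

#' Axial localization precision from on-glass traces
#'
#' The relative intensity error of each trace is the RMSD of its
#' intensity around the trace mean divided by that mean; the pooled
#' estimate is the mean across traces. Because two independent
#' intensities enter the ratio `I_G/I_0`, the relative error of the ratio
#' is `sqrt(2)` times the pooled estimate.
#'
#' @param traces_on_glass List of `"smTrace"` objects or numeric vectors
#'   recorded on the unquenched reference substrate.
#' @return A `"precisionEstimate"`: `per_trace_relative_rmsd`,
#'   `pooled_relative_error`, `ratio_relative_error`.
#' @export
axialPrecision <- function(traces_on_glass) {
  if (length(traces_on_glass) == 0L) stop("need at least one trace")
  rel <- vapply(traces_on_glass, function(tr) {
    x <- if (inherits(tr, "smTrace")) tr$intensity else as.numeric(tr)
    m <- mean(x)
    if (m == 0) stop("zero-mean trace: relative error undefined")
    sqrt(mean((x - m)^2)) / m
  }, numeric(1))
  pooled <- mean(rel)
  structure(list(per_trace_relative_rmsd = rel,
                 pooled_relative_error = pooled,
                 ratio_relative_error = sqrt(2) * pooled),
            class = "precisionEstimate")
}

#' @export
print.precisionEstimate <- function(x, ...) {
  cat(sprintf(
    "<precisionEstimate> pooled relative error %.2f%% -> ratio error %.2f%% (%d traces)\n",
    100 * x$pooled_relative_error, 100 * x$ratio_relative_error,
    length(x$per_trace_relative_rmsd)))
  invisible(x)
}
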