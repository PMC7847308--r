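#' Step-transition and state-identification segmentation
#'
#' Piecewise-constant segmentation of a single-molecule intensity trace in
#' three stages: (i) recursive change-point detection, splitting a segment
#' wherever the Student-t statistic of the two-sided mean difference
#' exceeds its critical value; (ii) agglomerative merging of segment means
#' into nested candidate state sets; (iii) choice of the state count by
#' minimum description length (fit cost plus model cost). The noise
#' standard deviation is estimated from the median absolute successive
#' difference scaled by `1/(sqrt(2) * 0.6745)`, which is insensitive to
#' the steps themselves.
#'
#' @param x Numeric intensity trace (length >= 10), or an `"smTrace"`.
#' @param sigma Noise s.d.; estimated from `x` when `NULL`.
#' @param alpha Per-segment significance level of the split test
#'   (Bonferroni-corrected over candidate split points).
#' @param min_seg Minimum segment length in frames.
#' @return A `"stasiSegmentation"`: `change_points` (last frame index of
#'   each segment but the final one), `segment_means`, `state_labels` (per
#'   segment), `state_means`, `labels` (per frame), `mdl` (score of the
#'   chosen model), `sigma`.
#' @export
stasiSegment <- function(x, sigma = NULL, alpha = 0.01, min_seg = 2L) {
  if (inherits(x, "smTrace")) x <- x$intensity
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10L) stop("trace too short for segmentation (need >= 10 frames)")
  if (is.null(sigma))
    sigma <- stats::median(abs(diff(x))) / (sqrt(2) * 0.6745)
  sigma <- max(sigma, 1e-12 * max(abs(x), 1))

  # stage i: recursive bisection on the t statistic
  bounds <- list()
  recurse <- function(a, b) {
    len <- b - a + 1L
    if (len < 2L * min_seg) {
      bounds[[length(bounds) + 1L]] <<- c(a, b)
      return(invisible())
    }
    sp <- best_split(x[a:b], sigma, min_seg)
    crit <- stats::qt(1 - alpha / (2 * max(len - 1L, 1L)), df = max(len - 2L, 1L))
    if (sp$index > 0 && sp$stat > crit) {
      recurse(a, a + sp$index - 1L)
      recurse(a + sp$index, b)
    } else {
      bounds[[length(bounds) + 1L]] <<- c(a, b)
    }
  }
  recurse(1L, n)
  bounds <- bounds[order(vapply(bounds, `[`, numeric(1), 1L))]
  seg_start <- vapply(bounds, `[`, numeric(1), 1L)
  seg_end <- vapply(bounds, `[`, numeric(1), 2L)
  seg_len <- seg_end - seg_start + 1L
  seg_mean <- vapply(seq_along(bounds),
                     function(i) mean(x[seg_start[i]:seg_end[i]]), numeric(1))
  n_seg <- length(seg_mean)
  n_cp <- n_seg - 1L

  # stage ii: agglomerative merge of segment means (length-weighted),
  # recording the grouping at every candidate state count
  groupings <- vector("list", n_seg)
  grp <- seq_len(n_seg)
  groupings[[n_seg]] <- grp
  if (n_seg > 1L) for (K in (n_seg - 1L):1L) {
    ids <- unique(grp)
    means <- vapply(ids, function(g)
      stats::weighted.mean(seg_mean[grp == g], seg_len[grp == g]), numeric(1))
    o <- order(means)
    ids <- ids[o]; means <- means[o]
    j <- which.min(diff(means))
    grp[grp == ids[j + 1L]] <- ids[j]
    groupings[[K]] <- grp
  }

  # stage iii: MDL over candidate state counts; the description length is
  # the Gaussian fit cost plus the cost of the state means and change-point
  # positions (0.5 log2 N each) plus the segment-to-state assignment code
  # (log2 K per segment)
  mdl_of <- function(grp) {
    ids <- unique(grp)
    K <- length(ids)
    st_mean <- vapply(ids, function(g)
      stats::weighted.mean(seg_mean[grp == g], seg_len[grp == g]), numeric(1))
    fitted <- st_mean[match(grp, ids)][rep(seq_len(n_seg), seg_len)]
    ssr <- sum((x - fitted)^2)
    ssr / (2 * sigma^2 * log(2)) + 0.5 * (K + n_cp) * log2(n) +
      n_seg * log2(K)
  }
  scores <- vapply(seq_len(n_seg),
                   function(K) mdl_of(groupings[[K]]), numeric(1))
  Kbest <- which.min(scores)
  grp <- groupings[[Kbest]]
  ids <- unique(grp)
  st_mean <- vapply(ids, function(g)
    stats::weighted.mean(seg_mean[grp == g], seg_len[grp == g]), numeric(1))
  o <- order(st_mean)
  state_of_seg <- match(match(grp, ids), o)  # 1 = lowest mean
  st_mean <- st_mean[o]
  labels <- rep(state_of_seg, seg_len)

  structure(list(
    change_points = if (n_cp > 0) as.integer(seg_end[-n_seg]) else integer(0),
    segment_means = seg_mean,
    segment_bounds = cbind(start = as.integer(seg_start),
                           end = as.integer(seg_end)),
    state_labels = state_of_seg,
    state_means = st_mean,
    labels = labels,
    mdl = scores[Kbest],
    sigma = sigma, n = n
  ), class = "stasiSegmentation")
}

#' @export
print.stasiSegmentation <- function(x, ...) {
  cat(sprintf(
    "<stasiSegmentation> %d frames, %d segments, %d states (MDL %.1f, sigma %.3g)\n",
    x$n, nrow(x$segment_bounds), length(x$state_means), x$mdl, x$sigma))
  invisible(x)
}

#' Rank traces by segmentation fit and keep the best fraction
#'
#' Goodness of fit is the residual variance of the piecewise-constant
#' segmentation divided by the trace variance (scale-invariant); traces
#' with the smallest normalized residual variance rank first. Ties are
#' broken by trace order, so the selection is deterministic.
#'
#' @param traces List of `"smTrace"` objects or numeric vectors.
#' @param segmentations Matching list of [stasiSegment()] results.
#' @param fraction Fraction of traces to keep (default 0.33).
#' @return Integer indices of the selected traces (best first).
#' @export
selectTrainingTraces <- function(traces, segmentations, fraction = 0.33) {
  stopifnot(length(traces) == length(segmentations))
  n <- length(traces)
  if (n < 3L) {
    warning("fewer than 3 traces: using all for initialization")
    return(seq_len(n))
  }
  score <- vapply(seq_len(n), function(i) {
    x <- if (inherits(traces[[i]], "smTrace")) traces[[i]]$intensity
         else as.numeric(traces[[i]])
    s <- segmentations[[i]]
    fitted <- s$state_means[s$labels]
    v <- stats::var(x)
    if (v <= 0) return(0)
    mean((x - fitted)^2) / v
  }, numeric(1))
  keep <- max(1L, floor(fraction * n))
  order(score)[seq_len(keep)]
}
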