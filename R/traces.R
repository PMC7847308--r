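#' Link localizations into single-molecule intensity traces
#'
#' Localizations are processed frame by frame and attached to the nearest
#' existing trace whose running-mean anchor lies within `search_radius`;
#' unmatched localizations start new traces. Within a frame, assignments
#' are made in order of increasing distance and each trace accepts at most
#' one localization per frame, so the result does not depend on the input
#' ordering of localizations within a frame. Traces shorter than
#' `min_frames` are discarded, and any pair of surviving traces whose
#' anchors lie closer than `exclusion` are both removed to avoid
#' crosstalk.
#'
#' @param locs Data frame with columns `x_nm`, `y_nm`, `frame`,
#'   `intensity` (positions in nm).
#' @param search_radius Linking radius in nm (default 150).
#' @param min_frames Minimum trace length in frames (default 100).
#' @param exclusion Minimum anchor separation in nm (default 500).
#' @param frame_interval Frame interval in seconds (default 0.032).
#' @return List of `"smTrace"` objects: each has `id`, a data frame
#'   `localizations` (`frame`, `x_nm`, `y_nm`, `intensity`), `intensity`
#'   (numeric vector), `anchor` (mean x/y), `frame_interval`.
#' @export
buildTraces <- function(locs, search_radius = 150, min_frames = 100L,
                        exclusion = 500, frame_interval = 0.032) {
  need <- c("x_nm", "y_nm", "frame", "intensity")
  if (!is.data.frame(locs) || !all(need %in% names(locs)))
    stop("'locs' must be a data frame with columns ",
         paste(need, collapse = ", "))
  locs <- locs[order(locs$frame), , drop = FALSE]

  anchors_x <- numeric(0); anchors_y <- numeric(0); counts <- integer(0)
  members <- list()
  for (f in unique(locs$frame)) {
    rows <- which(locs$frame == f)
    n_tr <- length(anchors_x)
    if (n_tr == 0L) {
      for (r in rows) {
        anchors_x <- c(anchors_x, locs$x_nm[r])
        anchors_y <- c(anchors_y, locs$y_nm[r])
        counts <- c(counts, 1L)
        members[[length(members) + 1L]] <- r
      }
      next
    }
    dx <- outer(locs$x_nm[rows], anchors_x, "-")
    dy <- outer(locs$y_nm[rows], anchors_y, "-")
    dist <- sqrt(dx^2 + dy^2)
    dist[dist > search_radius] <- NA
    taken_tr <- rep(FALSE, n_tr)
    assigned <- rep(NA_integer_, length(rows))
    # greedy by increasing distance; deterministic under permutations of
    # rows because distances, not input order, drive the assignment
    repeat {
      if (all(is.na(dist))) break
      ij <- arrayInd(which.min(dist), dim(dist))
      i <- ij[1L]; j <- ij[2L]
      assigned[i] <- j
      taken_tr[j] <- TRUE
      dist[i, ] <- NA
      dist[, j] <- NA
    }
    for (k in seq_along(rows)) {
      r <- rows[k]
      j <- assigned[k]
      if (is.na(j)) {
        anchors_x <- c(anchors_x, locs$x_nm[r])
        anchors_y <- c(anchors_y, locs$y_nm[r])
        counts <- c(counts, 1L)
        members[[length(members) + 1L]] <- r
      } else {
        members[[j]] <- c(members[[j]], r)
        counts[j] <- counts[j] + 1L
        anchors_x[j] <- anchors_x[j] + (locs$x_nm[r] - anchors_x[j]) / counts[j]
        anchors_y[j] <- anchors_y[j] + (locs$y_nm[r] - anchors_y[j]) / counts[j]
      }
    }
  }

  keep <- which(counts >= min_frames)
  if (length(keep) > 1L) {
    ax <- anchors_x[keep]; ay <- anchors_y[keep]
    n <- length(keep)
    bad <- rep(FALSE, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (sqrt((ax[i] - ax[j])^2 + (ay[i] - ay[j])^2) < exclusion) {
        bad[i] <- TRUE; bad[j] <- TRUE
      }
    }
    keep <- keep[!bad]
  }

  traces <- vector("list", length(keep))
  for (t2 in seq_along(keep)) {
    rows <- members[[keep[t2]]]
    df <- locs[rows, need[c(3, 1, 2, 4)], drop = FALSE]
    df <- df[order(df$frame), , drop = FALSE]
    rownames(df) <- NULL
    traces[[t2]] <- newSmTrace(
      id = t2, localizations = df,
      anchor = c(x = mean(df$x_nm), y = mean(df$y_nm)),
      frame_interval = frame_interval)
  }
  traces
}

newSmTrace <- function(id, localizations, anchor, frame_interval = 0.032,
                       intensity = NULL) {
  structure(list(
    id = id,
    localizations = localizations,
    intensity = if (is.null(intensity)) localizations$intensity else intensity,
    anchor = anchor,
    frame_interval = frame_interval
  ), class = "smTrace")
}

#' @export
print.smTrace <- function(x, ...) {
  cat(sprintf(
    "<smTrace> id %s: %d frames at %.0f ms, anchor (%.0f, %.0f) nm, mean intensity %.1f\n",
    x$id, length(x$intensity), 1000 * x$frame_interval,
    x$anchor[1], x$anchor[2], mean(x$intensity)))
  invisible(x)
}

#' @export
length.smTrace <- function(x) length(x$intensity)

#' Write traces as a delimited table
#'
#' Tab-delimited with header `trace_id`, `frame`, `x_nm`, `y_nm`,
#' `intensity`.
#'
#' @param traces List of `"smTrace"` objects.
#' @param path File path.
#' @export
writeTraceTable <- function(traces, path) {
  tabs <- lapply(traces, function(tr)
    cbind(trace_id = tr$id, tr$localizations))
  utils::write.table(do.call(rbind, tabs), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read traces from a delimited table
#'
#' @param path File written by [writeTraceTable()].
#' @param frame_interval Frame interval in seconds.
#' @return List of `"smTrace"` objects.
#' @export
readTraceTable <- function(path, frame_interval = 0.032) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("trace_id", "frame", "x_nm", "y_nm", "intensity")
  if (!all(need %in% names(tab)))
    stop("trace table must have columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$trace_id), function(df) {
    df <- df[order(df$frame), , drop = FALSE]
    newSmTrace(id = df$trace_id[1L],
               localizations = df[, c("frame", "x_nm", "y_nm", "intensity")],
               anchor = c(x = mean(df$x_nm), y = mean(df$y_nm)),
               frame_interval = frame_interval)
  })
}
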