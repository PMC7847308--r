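#' Fit a Gaussian-emission hidden Markov model to pooled traces
#'
#' Baum-Welch on the pooled traces, each treated as an independent
#' sequence, with Gaussian state emissions and log-space recursions.
#' Initialization comes from the change-point segmentations of a training
#' subset (state means/s.d.s pooled across traces, transitions from
#' labelled-frame pseudo-counts); a plain quantile initialization is used
#' when no segmentations are supplied. States are re-sorted ascending by
#' mean on return (low/medium/high convention).
#'
#' @param traces List of `"smTrace"` objects or numeric intensity vectors.
#' @param K Number of states (default 3).
#' @param init_from Optional list of [stasiSegment()] results for the
#'   traces named by `init_traces` (default: all of `traces`).
#' @param init_traces Indices of the traces that `init_from` refers to.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param var_floor Lower bound on state s.d. as a fraction of the pooled
#'   data s.d.; hitting it flags the state as degenerate.
#' @return A `"stateModel"`: `K`, `means`, `sds`, `transition_matrix`
#'   (row-stochastic, per frame), `initial_distribution`, `loglik` trace,
#'   `converged`, `degenerate` flags.
#' @export
hmmFit <- function(traces, K = 3L, init_from = NULL, init_traces = NULL,
                   max_iter = 1000L, tol = 1e-6, var_floor = 1e-3) {
  xs <- lapply(traces, function(tr)
    if (inherits(tr, "smTrace")) tr$intensity else as.numeric(tr))
  if (K < 1L) stop("'K' must be at least 1")
  pooled <- unlist(xs)
  if (length(pooled) < 10L * K)
    stop("pooled trace length must be at least 10 * K")

  # --- initialization -----------------------------------------------------
  # pooled frame values carry their trace-local state mean; clustering the
  # state-mean scale into K groups aligns states across traces
  seg_mean_per_frame <- NULL
  if (!is.null(init_from)) {
    if (is.null(init_traces)) init_traces <- seq_along(init_from)
    val_all <- unlist(lapply(init_traces, function(i) xs[[i]]))
    seg_mean_per_frame <- unlist(lapply(init_from, function(s)
      s$state_means[s$labels]))
    if (length(unique(seg_mean_per_frame)) < K) seg_mean_per_frame <- NULL
  }
  if (!is.null(seg_mean_per_frame)) {
    trans <- matrix(1, K, K)  # pseudo-counts
    km <- stats::kmeans(seg_mean_per_frame, K, nstart = 5L,
                        iter.max = 50L)
    cl <- km$cluster
    ord <- order(km$centers)
    cl <- match(cl, ord)
    mu <- vapply(seq_len(K), function(k) mean(val_all[cl == k]), numeric(1))
    sd0 <- vapply(seq_len(K), function(k) {
      v <- stats::sd(val_all[cl == k])
      if (!is.finite(v) || v <= 0) stats::sd(val_all) / K else v
    }, numeric(1))
    # transition pseudo-counts from the labelled frames
    pos <- 1L
    for (i in seq_along(init_from)) {
      len <- init_from[[i]]$n
      lab <- cl[pos:(pos + len - 1L)]
      pos <- pos + len
      for (t2 in seq_len(len - 1L))
        trans[lab[t2], lab[t2 + 1L]] <- trans[lab[t2], lab[t2 + 1L]] + 1
    }
    A <- trans / rowSums(trans)
    pi0 <- tabulate(cl, K) + 1
    pi0 <- pi0 / sum(pi0)
  } else {
    qs <- stats::quantile(pooled, probs = (seq_len(K) - 0.5) / K)
    mu <- as.numeric(qs)
    sd0 <- rep(stats::sd(pooled) / K, K)
    A <- matrix(0.05 / max(K - 1, 1), K, K); diag(A) <- 0.95
    if (K == 1L) A <- matrix(1, 1, 1)
    pi0 <- rep(1 / K, K)
  }
  floor_sd <- var_floor * stats::sd(pooled)
  if (!is.finite(floor_sd) || floor_sd <= 0) floor_sd <- 1e-8
  sd0 <- pmax(sd0, floor_sd)

  # --- EM -----------------------------------------------------------------
  ll_hist <- numeric(0)
  degenerate <- rep(FALSE, K)
  for (iter in seq_len(max_iter)) {
    logA <- log(A); logPi <- log(pi0)
    ll <- 0
    g_sum <- rep(0, K)          # sum of gamma
    gx_sum <- rep(0, K)         # sum of gamma * x
    gx2_sum <- rep(0, K)        # sum of gamma * x^2
    xi_sum <- matrix(0, K, K)
    pi_acc <- rep(0, K)
    for (x in xs) {
      fb <- fwdbwd_gauss(x, mu, sd0, logA, logPi)
      ll <- ll + fb$loglik
      g <- fb$gamma
      g_sum <- g_sum + colSums(g)
      gx_sum <- gx_sum + colSums(g * x)
      gx2_sum <- gx2_sum + colSums(g * x^2)
      xi_sum <- xi_sum + fb$xi
      pi_acc <- pi_acc + g[1L, ]
    }
    ll_hist <- c(ll_hist, ll)
    mu_new <- gx_sum / g_sum
    var_new <- gx2_sum / g_sum - mu_new^2
    sd_new <- sqrt(pmax(var_new, 0))
    deg <- sd_new < floor_sd
    degenerate <- degenerate | deg
    sd_new[deg] <- floor_sd
    if (K > 1L) {
      A_new <- xi_sum / pmax(rowSums(xi_sum), .Machine$double.eps)
    } else A_new <- matrix(1, 1, 1)
    pi_new <- pi_acc / sum(pi_acc)
    mu <- mu_new; sd0 <- sd_new; A <- A_new; pi0 <- pi_new
    if (iter >= 2L) {
      rel <- abs(ll_hist[iter] - ll_hist[iter - 1L]) /
        (abs(ll_hist[iter - 1L]) + .Machine$double.eps)
      if (rel < tol) break
    }
  }
  if (any(degenerate))
    warning("variance floor applied to state(s) ",
            paste(which(degenerate), collapse = ", "))

  o <- order(mu)
  structure(list(K = as.integer(K), means = mu[o], sds = sd0[o],
                 transition_matrix = A[o, o, drop = FALSE],
                 initial_distribution = pi0[o],
                 loglik = ll_hist,
                 converged = length(ll_hist) < max_iter,
                 degenerate = degenerate[o]),
            class = "stateModel")
}

#' @export
print.stateModel <- function(x, ...) {
  cat(sprintf("<stateModel> K = %d, loglik = %.2f (%d EM iterations%s)\n",
              x$K, x$loglik[length(x$loglik)], length(x$loglik),
              if (x$converged) ", converged" else ""))
  lab <- if (x$K == 3L) c("L", "M", "H") else paste0("S", seq_len(x$K))
  for (k in seq_len(x$K))
    cat(sprintf("  %s: mean %.1f, sd %.1f, p(stay) %.3f\n", lab[k],
                x$means[k], x$sds[k], x$transition_matrix[k, k]))
  invisible(x)
}

#' Most probable state path of a trace under a fitted model
#'
#' Viterbi decoding with ties broken toward the lower state index.
#'
#' @param trace An `"smTrace"` or numeric intensity vector.
#' @param model A [hmmFit()] `"stateModel"`.
#' @return Integer vector of 1-based state indices (1 = lowest mean).
#' @export
viterbiDecode <- function(trace, model) {
  stopifnot(inherits(model, "stateModel"))
  x <- if (inherits(trace, "smTrace")) trace$intensity else as.numeric(trace)
  viterbi_gauss(x, model$means, model$sds,
                log(model$transition_matrix),
                log(model$initial_distribution))
}
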