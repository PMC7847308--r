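#' Simulate GIET-modulated single-molecule intensity traces
#'
#' A continuous-time Markov chain over K conformational states is sampled
#' at the camera frame interval (per-frame transition matrix
#' `expm(Q * dt)`). Each state sits at a height `h` above the monolayer;
#' its mean intensity is `on_glass_mean * curve(h + monolayer)` and the
#' per-frame intensity is Gaussian with a constant coefficient of
#' variation. Optionally a single irreversible photobleaching step to
#' background is drawn from an exponential time. Ground-truth state paths
#' are returned alongside the traces.
#'
#' @param heights Per-state heights above the monolayer in nm (ascending
#'   means come out of ascending heights).
#' @param curve A [gietCurve()] covering `heights + monolayer`.
#' @param rate_matrix K x K continuous-time generator (1/s): rows sum to
#'   zero, off-diagonals non-negative. A zero matrix freezes the chain.
#' @param on_glass_mean Mean unquenched intensity (a.u.).
#' @param noise_cv Coefficient of variation of the Gaussian emission
#'   noise (default 0.075).
#' @param frame_interval Frame interval in s (default 0.032).
#' @param n_traces,n_frames Number of traces and frames per trace.
#' @param bleach_rate Photobleaching rate in 1/s (default 0, no bleaching).
#' @param background Post-bleach mean intensity (default 0).
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `traces` (list of `"smTrace"`), `states` (list of
#'   integer ground-truth paths), `state_means` (design mean intensities),
#'   `transition_matrix` (per-frame), `params`.
#' @export
simulateTraces <- function(heights, curve, rate_matrix, on_glass_mean,
                           noise_cv = 0.075, frame_interval = 0.032,
                           n_traces = 100L, n_frames = 500L,
                           bleach_rate = 0, background = 0, seed = NULL) {
  stopifnot(inherits(curve, "gietCurve"))
  K <- length(heights)
  Q <- as.matrix(rate_matrix)
  if (!all(dim(Q) == K)) stop("'rate_matrix' must be K x K")
  if (any(Q[row(Q) != col(Q)] < 0) || any(abs(rowSums(Q)) > 1e-8))
    stop("'rate_matrix' must have non-negative off-diagonals and zero row sums")
  if (noise_cv < 0) stop("'noise_cv' must be non-negative")
  d <- heights + curve$monolayer
  if (any(d < min(curve$d) | d > max(curve$d)))
    stop("heights outside the curve range after adding the monolayer thickness")
  state_means <- on_glass_mean * predict(curve, d)

  P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * frame_interval)))
  P[P < 0] <- 0
  P <- P / rowSums(P)

  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  p_bleach <- 1 - exp(-bleach_rate * frame_interval)

  traces <- vector("list", n_traces)
  states <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    s <- integer(n_frames)
    s[1L] <- sample.int(K, 1L)
    for (t2 in seq_len(n_frames - 1L))
      s[t2 + 1L] <- sample.int(K, 1L, prob = P[s[t2], ])
    mu <- state_means[s]
    bleached <- FALSE
    if (p_bleach > 0) {
      hit <- which(stats::runif(n_frames) < p_bleach)
      if (length(hit)) {
        mu[hit[1L]:n_frames] <- background
        s[hit[1L]:n_frames] <- NA_integer_
        bleached <- TRUE
      }
    }
    x <- stats::rnorm(n_frames, mean = mu, sd = noise_cv * pmax(abs(mu), 1e-12))
    anchor <- c(x = stats::runif(1, 0, 5e4), y = stats::runif(1, 0, 5e4))
    df <- data.frame(frame = seq_len(n_frames), x_nm = unname(anchor[1L]),
                     y_nm = unname(anchor[2L]), intensity = x)
    traces[[i]] <- newSmTrace(id = i, localizations = df, anchor = anchor,
                              frame_interval = frame_interval)
    states[[i]] <- s
  }
  list(traces = traces, states = states, state_means = state_means,
       transition_matrix = P,
       params = list(heights = heights, on_glass_mean = on_glass_mean,
                     noise_cv = noise_cv, frame_interval = frame_interval,
                     bleach_rate = bleach_rate, seed = seed))
}

#' Simulate a TIRF image stack of immobilized emitters
#'
#' Spots are placed uniformly with a minimum pairwise separation and
#' rendered as 2D Gaussian point-spread functions; pixel counts are
#' Poisson photon noise on top of a constant background, plus optional
#' Gaussian read noise. Per-frame spot brightness can be supplied (e.g.
#' from [simulateTraces()]) or defaults to a constant photon budget.
#'
#' @param frame_size Frame side length in pixels.
#' @param n_frames Number of frames.
#' @param n_spots Number of emitters (placement fails if they cannot be
#'   separated by `min_separation` in a reasonable number of attempts).
#' @param pixel_size Pixel size in nm (default 107).
#' @param psf_sigma PSF sigma in pixels (default 1.3).
#' @param photon_budget Expected photons per spot per frame, a scalar or
#'   an `n_spots x n_frames` matrix.
#' @param background Expected background photons per pixel (default 5).
#' @param read_noise Gaussian read-noise s.d. in counts (default 0).
#' @param min_separation Minimum spot separation in nm (default 500).
#' @param seed Integer seed.
#' @return List with `stack` (array `[row, col, frame]`) and `truth`
#'   (data frame `spot`, `x_nm`, `y_nm`, 0-based pixel-centre origin).
#' @export
simulateImageStack <- function(frame_size = 64L, n_frames = 10L,
                               n_spots = 3L, pixel_size = 107,
                               psf_sigma = 1.3, photon_budget = 2000,
                               background = 5, read_noise = 0,
                               min_separation = 500, seed = NULL) {
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  side_nm <- frame_size * pixel_size
  margin <- 4 * psf_sigma * pixel_size
  if (n_spots > 0 && side_nm - 2 * margin <= 0)
    stop("frame too small for the PSF margin")
  xs <- numeric(0); ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n_spots) {
    attempts <- attempts + 1L
    if (attempts > 200L * max(n_spots, 1L))
      stop("cannot place ", n_spots, " spots with ", min_separation,
           " nm separation in a ", round(side_nm), " nm field")
    cand_x <- stats::runif(1, margin, side_nm - margin)
    cand_y <- stats::runif(1, margin, side_nm - margin)
    if (length(xs) == 0L ||
        all(sqrt((xs - cand_x)^2 + (ys - cand_y)^2) >= min_separation)) {
      xs <- c(xs, cand_x); ys <- c(ys, cand_y)
    }
  }
  if (is.matrix(photon_budget)) {
    stopifnot(nrow(photon_budget) == n_spots,
              ncol(photon_budget) == n_frames)
    bud <- photon_budget
  } else {
    bud <- matrix(photon_budget, n_spots, n_frames)
  }

  px <- seq_len(frame_size) - 1  # pixel centres, 0-based
  stack <- array(0, c(frame_size, frame_size, n_frames))
  for (f in seq_len(n_frames)) {
    lam <- matrix(background, frame_size, frame_size)
    for (s in seq_len(n_spots)) {
      x0 <- xs[s] / pixel_size; y0 <- ys[s] / pixel_size
      gy <- exp(-(px - y0)^2 / (2 * psf_sigma^2))
      gx <- exp(-(px - x0)^2 / (2 * psf_sigma^2))
      psf <- outer(gy, gx)
      lam <- lam + bud[s, f] * psf / sum(psf)
    }
    img <- matrix(stats::rpois(length(lam), lam), frame_size, frame_size)
    if (read_noise > 0)
      img <- img + matrix(stats::rnorm(length(lam), 0, read_noise),
                          frame_size, frame_size)
    stack[, , f] <- img
  }
  list(stack = stack,
       truth = data.frame(spot = seq_len(n_spots), x_nm = xs, y_nm = ys))
}

#' Simulate a DNA-nanoruler calibration dataset
#'
#' Ratios are the GIET curve evaluated at `l_dna * sin(alpha) + l_ml`,
#' multiplied by multiplicative Gaussian noise of coefficient of
#' variation `noise_cv`.
#'
#' @param alpha True tilt angle in degrees, (0, 90].
#' @param l_dna Contour lengths in nm; default the seven calibration
#'   lengths `c(1.7, 5.1, 6.8, 8.5, 10.2, 11.9, 17.0)`.
#' @param curve A [gietCurve()].
#' @param noise_cv Multiplicative noise c.v. (default 0.03).
#' @param l_ml Monolayer thickness in nm.
#' @param mode Reported measurement mode label.
#' @param seed Integer seed.
#' @return Data frame with columns `l_dna_nm`, `label_end`, `ratio`,
#'   `ratio_sd`, `mode` (the schema of [readRulerTable()]).
#' @export
simulateRulerData <- function(alpha, l_dna = c(1.7, 5.1, 6.8, 8.5, 10.2,
                                               11.9, 17.0),
                              curve, noise_cv = 0.03, l_ml = 2.5,
                              mode = "intensity", seed = NULL) {
  stopifnot(inherits(curve, "gietCurve"))
  if (alpha <= 0 || alpha > 90) stop("'alpha' must lie in (0, 90] degrees")
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  d <- rulerDistance(l_dna, alpha, l_ml)
  true_ratio <- predict(curve, pmin(pmax(d, min(curve$d)), max(curve$d)))
  ratio <- true_ratio * (1 + stats::rnorm(length(l_dna), 0, noise_cv))
  ratio <- pmin(pmax(ratio, 1e-6), 1 - 1e-6)
  data.frame(l_dna_nm = l_dna,
             label_end = ifelse(l_dna == 0, "lipid_dye", "3prime"),
             ratio = ratio,
             ratio_sd = noise_cv * true_ratio,
             mode = mode)
}
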