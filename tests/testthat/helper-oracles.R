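# Shared fixtures and independent oracles for the optics tests.

# Lazily built, memoized calibration curves (step 0.1 nm keeps the suite fast;
# interpolation error at that step is far below the tolerances asserted here).
.curve_cache <- new.env(parent = emptyenv())
cachedCurve <- function(name, step = 0.1) {
  key <- paste0(name, "_", step)
  if (is.null(.curve_cache[[key]])) {
    fl <- gietFluorophore(name)
    .curve_cache[[key]] <- gietCurve(fl, d_min = 2.5, d_max = 30, step = step)
  }
  .curve_cache[[key]]
}

# Independent recursive-Fresnel oracle, coded directly from the two-media
# Fresnel formulas (impedance-free form) without reference to the package
# internals. Scalar in u.
oracleReflection <- function(u, pol, wavelength, n_list, t_list) {
  # n_list: indices from the emitter medium downwards (first entry emitter
  # half-space, last entry substrate half-space); t_list thicknesses of the
  # interior layers, aligned with n_list[2:(m-1)]
  k0 <- 2 * pi / wavelength
  n1 <- n_list[[1]]
  kpar <- Re(n1) * u * k0
  kzs <- lapply(n_list, function(nj) {
    v <- sqrt(as.complex(nj^2 * k0^2 - kpar^2))
    if (Im(v) < 0 || (Im(v) == 0 && Re(v) < 0)) v <- -v
    v
  })
  fres <- function(i, j) {
    ni <- n_list[[i]]; nj <- n_list[[j]]
    if (pol == "s") {
      (kzs[[i]] - kzs[[j]]) / (kzs[[i]] + kzs[[j]])
    } else {
      (nj^2 * kzs[[i]] - ni^2 * kzs[[j]]) /
        (nj^2 * kzs[[i]] + ni^2 * kzs[[j]])
    }
  }
  m <- length(n_list)
  r <- fres(m - 1, m)
  if (m > 2) for (i in (m - 2):1) {
    phase <- exp(2i * kzs[[i + 1]] * t_list[[i]])
    r <- (fres(i, i + 1) + r * phase) / (1 + fres(i, i + 1) * r * phase)
  }
  r
}

# Brute-force fixed-grid trapezoid integration of the dipole emission-power
# integral (propagating part substituted u = sin t, evanescent tail
# u = cosh s), independent of the adaptive quadrature in the package.
bruteForcePower <- function(stack, d, n_nodes = 5e5) {
  n_top <- 1.33
  k1 <- 2 * pi * n_top / stack$emission_wavelength
  trap <- function(y, h) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  # propagating part, u = sin t, w = cos t: the 1/w factors cancel exactly
  tt <- seq(0, pi / 2, length.out = n_nodes)
  u1 <- sin(tt); w1 <- cos(tt)
  rp1 <- stackReflection(stack, "p", u1)
  rs1 <- stackReflection(stack, "s", u1)
  ph1 <- exp(2i * k1 * w1 * d)
  perp_prop <- trap(Re(u1^3 * rp1 * ph1), tt[2] - tt[1])
  par_prop <- trap(Re(u1 * (rs1 - w1^2 * rp1) * ph1), tt[2] - tt[1])
  # evanescent part, u = cosh s, w = i sinh s: the measure cancels the
  # 1/w singularity and only the imaginary parts of r survive
  ss <- seq(0, asinh(45 / (2 * k1 * d)), length.out = n_nodes)
  u2 <- cosh(ss); v2 <- sinh(ss)
  rp2 <- stackReflection(stack, "p", u2)
  rs2 <- stackReflection(stack, "s", u2)
  damp <- exp(-2 * k1 * v2 * d)
  perp_evan <- trap(u2^3 * Im(rp2) * damp, ss[2] - ss[1])
  par_evan <- trap(u2 * Im(rs2 + v2^2 * rp2) * damp, ss[2] - ss[1])
  sp <- 1 + 1.5 * (perp_prop + perp_evan)
  sl <- 1 + 0.75 * (par_prop + par_evan)
  (sp + 2 * sl) / 3
}

# all-water stack: homogeneous medium with the default layer thicknesses
waterStack <- function(wavelength = 518) {
  opticalStack(list(
    opticalLayer("water", 1.33),
    opticalLayer("water", 1.33, 0.34),
    opticalLayer("water", 1.33, 2.5),
    opticalLayer("water", 1.33)
  ), wavelength)
}

rulerLengths <- c(1.7, 5.1, 6.8, 8.5, 10.2, 11.9, 17.0)
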