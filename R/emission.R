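#' Generalized Fresnel reflection coefficient of a layered stack
#'
#' Amplitude reflection coefficient of the stack seen from the emitter's
#' (top) half-space, computed by the recursive Fresnel (scattering-matrix)
#' method with complex indices. The interface recursion with phase factors
#' `exp(2i kz t)` stays bounded deep into the evanescent region, where the
#' characteristic-matrix formulation overflows. The in-plane wavenumber is
#' normalized to the wavenumber of the
#' emitter medium: `u = k_par / (n_top * k0)`; `u > 1` is the evanescent
#' region. Normal wavenumbers take the branch with non-negative imaginary
#' part so fields decay away from the emitter.
#'
#' Sign conventions: at a single interface at normal incidence both
#' polarizations reduce to `(n1 - n2) / (n1 + n2)` with `n1` the emitter
#' medium; for p-polarization this is the convention in which a perfect
#' mirror has `r_p = +1`.
#'
#' @param stack An [opticalStack()]; the emitter sits in its top half-space.
#' @param polarization `"s"` or `"p"`.
#' @param u Numeric vector of normalized in-plane wavenumbers, `u >= 0`.
#' @return Complex vector of reflection coefficients, one per `u`.
#' @export
stackReflection <- function(stack, polarization = c("s", "p"), u) {
  polarization <- match.arg(polarization)
  stopifnot(inherits(stack, "opticalStack"))
  if (any(u < 0)) stop("'u' must be non-negative")
  n <- indicesFromTop(stack)          # emitter medium first
  t <- thicknessFromTop(stack)
  k0 <- 2 * pi / stack$emission_wavelength
  n1 <- n[1L]
  m <- length(n)

  # kz in every medium, branch Im >= 0 (rows: media, cols: u)
  kpar2 <- (Re(n1) * u)^2             # emitter medium is lossless by construction
  kz <- matrix(0i, m, length(u))
  for (j in seq_len(m)) {
    v <- sqrt(as.complex(n[j]^2 - kpar2)) * k0
    flip <- Im(v) < 0 | (Im(v) == 0 & Re(v) < 0)
    v[flip] <- -v[flip]
    kz[j, ] <- v
  }
  # modal admittances; interface coefficient r_ij = (q_i - q_j)/(q_i + q_j),
  # the convention in which a perfect mirror has r_p = +1
  q <- if (polarization == "s") kz else kz / matrix(n^2, m, length(u))

  # recursion upward from the substrate: r_{j,stack} =
  # (r_{j,j+1} + r_{j+1,stack} e^{2i kz_{j+1} t_{j+1}}) /
  # (1 + r_{j,j+1} r_{j+1,stack} e^{2i kz_{j+1} t_{j+1}})
  r <- (q[m - 1L, ] - q[m, ]) / (q[m - 1L, ] + q[m, ])
  if (m > 2L) for (j in (m - 2L):1L) {
    rj <- (q[j, ] - q[j + 1L, ]) / (q[j, ] + q[j + 1L, ])
    ph <- exp(2i * kz[j + 1L, ] * t[j + 1L])
    r <- (rj + r * ph) / (1 + rj * r * ph)
  }
  r
}

# integrand pieces for the plane-wave (CPS) expansion; w = kz/k1 in the
# emitter medium with Im(w) >= 0
.wOf <- function(u) {
  v <- sqrt(as.complex(1 - u^2))
  flip <- Im(v) < 0 | (Im(v) == 0 & Re(v) < 0)
  v[flip] <- -v[flip]
  v
}

# Re of the reflected-field integrand at height z above the top interface.
# perpendicular dipole: (3/2) u^3/w r_p e^{2 i k1 w z}
# parallel dipole:      (3/4) u/w (r_s - w^2 r_p) e^{2 i k1 w z}
.integrandPerp <- function(stack, k1, z) {
  force(stack); force(k1); force(z)
  function(u) {
    w <- .wOf(u)
    rp <- stackReflection(stack, "p", u)
    Re((u^3 / w) * rp * exp(2i * k1 * w * z))
  }
}

.integrandPar <- function(stack, k1, z) {
  force(stack); force(k1); force(z)
  function(u) {
    w <- .wOf(u)
    rp <- stackReflection(stack, "p", u)
    rs <- stackReflection(stack, "s", u)
    Re((u / w) * (rs - w^2 * rp) * exp(2i * k1 * w * z))
  }
}

# adaptive quadrature of f over u in [0, Inf), split at the branch point
# u = 1: propagating part via u = sin(t) (removes the 1/w singularity),
# evanescent tail via u = cosh(s) exploiting the exp(-2 k1 sinh(s) z) decay
.cpsIntegral <- function(f, k1, z, rel.tol = 1e-8) {
  g1 <- function(t) f(sin(t)) * cos(t)
  smax <- asinh(45 / (2 * k1 * max(z, 0.05)))
  g2 <- function(s) f(cosh(s)) * sinh(s)
  i1 <- tryCatch(
    stats::integrate(g1, 0, pi / 2, rel.tol = rel.tol, abs.tol = rel.tol,
                     subdivisions = 500L, stop.on.error = TRUE)$value,
    error = function(e) stop("quadrature failed on the propagating part (z = ",
                             signif(z, 4), " nm): ", conditionMessage(e)))
  i2 <- tryCatch(
    stats::integrate(g2, 0, smax, rel.tol = rel.tol, abs.tol = rel.tol,
                     subdivisions = 2000L, stop.on.error = TRUE)$value,
    error = function(e) stop("quadrature failed on the evanescent part (z = ",
                             signif(z, 4), " nm): ", conditionMessage(e)))
  i1 + i2
}

#' Normalized emission power of a dipole above the stack
#'
#' Total power dissipated by an oscillating point dipole in the top
#' half-space, normalized to its free-space (homogeneous-medium) value
#' S0, computed from the plane-wave expansion of the dipole field and the
#' stack's generalized reflection coefficients. The isotropic average is
#' `(S_perp + 2 S_par) / 3`.
#'
#' The axial coordinate `d` follows the convention of the published GIET
#' calibrations: it equals the width of the aqueous gap between the top of
#' the stack (the monolayer surface in the default geometry) and the
#' emitter. Heights above the monolayer are reported downstream as
#' `h = d - 2.5` nm.
#'
#' @param stack An [opticalStack()].
#' @param d Axial distance coordinate in nm (scalar or vector); must be at
#'   least the monolayer thickness of the stack.
#' @param orientation `"isotropic"`, `"perpendicular"` or `"parallel"`.
#' @param rel.tol Relative quadrature tolerance.
#' @return Numeric vector `S(d)/S0`.
#' @export
relativeEmissionPower <- function(stack, d,
                                  orientation = c("isotropic",
                                                  "perpendicular",
                                                  "parallel"),
                                  rel.tol = 1e-8) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(stack, "opticalStack"))
  t_ml <- monolayerThickness(stack)
  if (any(d < t_ml))
    stop("emitter below the supported range: d must be >= the monolayer ",
         "thickness (", t_ml, " nm)")
  n1 <- Re(indicesFromTop(stack)[1L])
  k1 <- 2 * pi * n1 / stack$emission_wavelength
  vapply(d, function(z) {
    switch(orientation,
      perpendicular = 1 + 1.5 *
        .cpsIntegral(.integrandPerp(stack, k1, z), k1, z, rel.tol),
      parallel = 1 + 0.75 *
        .cpsIntegral(.integrandPar(stack, k1, z), k1, z, rel.tol),
      isotropic = {
        sp <- 1 + 1.5 *
          .cpsIntegral(.integrandPerp(stack, k1, z), k1, z, rel.tol)
        sl <- 1 + 0.75 *
          .cpsIntegral(.integrandPar(stack, k1, z), k1, z, rel.tol)
        (sp + 2 * sl) / 3
      })
  }, numeric(1))
}

#' Relative fluorescence lifetime on graphene
#'
#' `tau_G / tau_0 = S0 / ((1 - phi) S0 + phi S(d))` with `phi` the quantum
#' yield and `S(d)` the orientation-averaged emission power from
#' [relativeEmissionPower()]. In the absence of static quenching the
#' relative fluorescence intensity `I_G / I_0` follows the same curve.
#'
#' @param fluor A [fluorophore()].
#' @param stack An [opticalStack()]; defaults to [defaultStackFor()] the
#'   fluorophore, with the stack's emission wavelength set from the
#'   fluorophore's emission maximum.
#' @param d Axial distance coordinate in nm (see [relativeEmissionPower()]).
#' @return Numeric vector of lifetime ratios in (0, 1].
#' @export
lifetimeRatio <- function(fluor, stack = defaultStackFor(fluor), d) {
  stopifnot(inherits(fluor, "fluorophore"))
  phi <- fluor$quantum_yield
  if (phi <= 0 || phi > 1) stop("'quantum_yield' must lie in (0, 1]")
  s <- relativeEmissionPower(stack, d, "isotropic")
  1 / (1 - phi + phi * s)
}

#' GIET efficiency
#'
#' `1 - tau_G / tau_0`: the fraction of the excited-state decay channelled
#' into graphene at distance `d`.
#'
#' @inheritParams lifetimeRatio
#' @return Numeric vector of efficiencies.
#' @export
gietEfficiency <- function(fluor, stack = defaultStackFor(fluor), d) {
  1 - lifetimeRatio(fluor, stack, d)
}
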