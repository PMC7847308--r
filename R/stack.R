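#' Define a single optical layer
#'
#' A layer of the planar optical stack: either a finite film (positive
#' thickness in nm) or a semi-infinite half-space (`thickness = NA`).
#' Absorbing media carry a complex refractive index with non-negative
#' imaginary part.
#'
#' @param name Layer label, e.g. `"graphene"`.
#' @param refractive_index Complex (or real) refractive index.
#' @param thickness Thickness in nm, or `NA` for a half-space.
#' @return An object of class `"opticalLayer"`.
#' @export
opticalLayer <- function(name, refractive_index, thickness = NA_real_) {
  n <- as.complex(refractive_index)
  if (length(n) != 1L || is.na(n)) stop("'refractive_index' must be a single number")
  if (Im(n) < 0) stop("refractive index must have non-negative imaginary part")
  if (Re(n) <= 0) stop("refractive index must have positive real part")
  if (!is.na(thickness) && thickness <= 0)
    stop("finite layer thickness must be positive (nm)")
  structure(list(name = as.character(name), n = n,
                 thickness = as.numeric(thickness)),
            class = "opticalLayer")
}

#' @export
print.opticalLayer <- function(x, ...) {
  thick <- if (is.na(x$thickness)) "half-space" else sprintf("%.2f nm", x$thickness)
  cat(sprintf("<opticalLayer> %-10s n = %s  (%s)\n", x$name,
              format(x$n, digits = 4), thick))
  invisible(x)
}

#' Assemble a planar optical stack
#'
#' Layers are given from the substrate (bottom) to the superstrate (top).
#' Exactly the first and last layers must be half-spaces; all layers in
#' between must have a finite thickness. The emitter sits in the top
#' half-space.
#'
#' @param layers List of [opticalLayer()] objects, bottom to top.
#' @param emission_wavelength Vacuum emission wavelength in nm.
#' @return An object of class `"opticalStack"`.
#' @seealso [gietStack()] for the bundled graphene presets.
#' @export
opticalStack <- function(layers, emission_wavelength) {
  if (!is.list(layers) || length(layers) < 2L)
    stop("'layers' must be a list of at least two opticalLayer objects")
  if (!all(vapply(layers, inherits, logical(1), "opticalLayer")))
    stop("every element of 'layers' must be an opticalLayer")
  thick <- vapply(layers, function(l) l$thickness, numeric(1))
  if (!is.na(thick[1L]) || !is.na(thick[length(thick)]))
    stop("first and last layers must be half-spaces (thickness = NA)")
  if (length(thick) > 2L && anyNA(thick[-c(1L, length(thick))]))
    stop("interior layers must have finite thickness")
  if (!is.numeric(emission_wavelength) || emission_wavelength <= 0)
    stop("'emission_wavelength' must be positive (nm)")
  structure(list(layers = layers,
                 emission_wavelength = as.numeric(emission_wavelength)),
            class = "opticalStack")
}

#' @export
print.opticalStack <- function(x, ...) {
  cat(sprintf("<opticalStack> %d layers, emission %.0f nm (top to bottom):\n",
              length(x$layers), x$emission_wavelength))
  for (l in rev(x$layers)) print(l)
  invisible(x)
}

# thickness of the top finite layer (the monolayer in the default geometry);
# 0 when the stack has no finite layers
monolayerThickness <- function(stack) {
  k <- length(stack$layers)
  if (k < 3L) return(0)
  stack$layers[[k - 1L]]$thickness
}

# complex indices ordered from the emitter medium downwards
indicesFromTop <- function(stack) {
  rev(vapply(stack$layers, function(l) l$n, complex(1)))
}

thicknessFromTop <- function(stack) {
  rev(vapply(stack$layers, function(l) l$thickness, numeric(1)))
}

#' Graphene-on-glass stack presets
#'
#' The four-layer geometry used for GIET calibration: glass substrate
#' (n = 1.52), single-sheet graphene (0.34 nm; n = 2.68 + 1.21i in the
#' 520 nm emission band, n = 2.76 + 1.40i in the 670 nm band), a lipid
#' monolayer (2.5 nm, n = 1.44) and water (n = 1.33) on top.
#'
#' @param preset `"giet520"` or `"giet670"`, selecting the graphene index
#'   tabulated for the corresponding emission band. Other wavelengths
#'   require a user-assembled stack via [opticalStack()]; no interpolation
#'   between the two tabulated indices is attempted.
#' @param emission_wavelength Vacuum emission wavelength in nm; defaults
#'   to the nominal band wavelength of the preset.
#' @return An `"opticalStack"`.
#' @export
gietStack <- function(preset = c("giet520", "giet670"),
                      emission_wavelength = NULL) {
  preset <- match.arg(preset)
  n_graphene <- switch(preset,
    giet520 = complex(real = 2.68, imaginary = 1.21),
    giet670 = complex(real = 2.76, imaginary = 1.40))
  if (is.null(emission_wavelength))
    emission_wavelength <- switch(preset, giet520 = 520, giet670 = 670)
  opticalStack(list(
    opticalLayer("glass", 1.52),
    opticalLayer("graphene", n_graphene, 0.34),
    opticalLayer("lipid", 1.44, 2.5),
    opticalLayer("water", 1.33)
  ), emission_wavelength)
}

#' Define a fluorophore
#'
#' @param name Fluorophore label.
#' @param emission_max Emission maximum in nm (emission is treated as
#'   monochromatic at this wavelength).
#' @param quantum_yield Fluorescence quantum yield in (0, 1].
#' @param free_space_lifetime Unquenched lifetime in ns.
#' @return An object of class `"fluorophore"`.
#' @export
fluorophore <- function(name, emission_max, quantum_yield,
                        free_space_lifetime) {
  if (!is.numeric(quantum_yield) || quantum_yield <= 0 || quantum_yield > 1)
    stop("'quantum_yield' must lie in (0, 1]")
  if (!is.numeric(free_space_lifetime) || free_space_lifetime <= 0)
    stop("'free_space_lifetime' must be positive (ns)")
  if (!is.numeric(emission_max) || emission_max <= 0)
    stop("'emission_max' must be positive (nm)")
  structure(list(name = as.character(name),
                 emission_max = as.numeric(emission_max),
                 quantum_yield = as.numeric(quantum_yield),
                 free_space_lifetime = as.numeric(free_space_lifetime)),
            class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("<fluorophore> %s: emission %.0f nm, QY %.2f, tau0 %.2f ns\n",
              x$name, x$emission_max, x$quantum_yield, x$free_space_lifetime))
  invisible(x)
}

# bundled fluorophore parameters (emission max nm, quantum yield, tau0 ns)
.fluorophores <- list(
  FAM        = c(518, 0.75, 3.0),
  EGFP       = c(507, 0.60, 2.1),
  mNeonGreen = c(517, 0.80, 2.8),
  Dy647P1    = c(667, 0.27, 1.3)
)

#' Bundled fluorophore presets
#'
#' FAM (518 nm, QY 0.75, 3.0 ns), EGFP (507 nm, 0.60, 2.1 ns),
#' mNeonGreen (517 nm, 0.80, 2.8 ns) and Dy647P1 (667 nm, 0.27, 1.3 ns).
#'
#' @param name One of `"FAM"`, `"EGFP"`, `"mNeonGreen"`, `"Dy647P1"`.
#' @return A `"fluorophore"`.
#' @export
gietFluorophore <- function(name = c("FAM", "EGFP", "mNeonGreen", "Dy647P1")) {
  name <- match.arg(name)
  p <- .fluorophores[[name]]
  fluorophore(name, p[1], p[2], p[3])
}

#' Default graphene stack for a bundled fluorophore
#'
#' Green emitters (FAM, EGFP, mNeonGreen) use the 520 nm graphene index,
#' Dy647P1 the 670 nm index; the stack's emission wavelength is set to the
#' fluorophore's emission maximum.
#'
#' @param fluor A `"fluorophore"`.
#' @return An `"opticalStack"`.
#' @export
defaultStackFor <- function(fluor) {
  stopifnot(inherits(fluor, "fluorophore"))
  preset <- if (fluor$emission_max >= 600) "giet670" else "giet520"
  gietStack(preset, emission_wavelength = fluor$emission_max)
}
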