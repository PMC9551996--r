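#' Grayscale field
#'
#' A 2D raster standing in for an HR-pQCT transverse slice of cancellous bone
#' or one of its derived density / modulus fields. The `semantics_tag` tracks
#' the preprocessing chain and may only advance along
#' raw -> vbmd -> ash_density -> modulus.
#'
#' @param values numeric matrix; all entries finite.
#' @param pixel_pitch pixel edge length in mm.
#' @param semantics_tag one of "raw", "vbmd", "ash_density", "modulus".
#' @return object of class `grayscale_field`.
#' @export
grayscale_field <- function(values, pixel_pitch,
                            semantics_tag = c("raw", "vbmd", "ash_density",
                                              "modulus")) {
  semantics_tag <- match.arg(semantics_tag)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("all field values must be finite")
  if (!(pixel_pitch > 0)) stop("pixel_pitch must be > 0")
  structure(
    list(values = values, pixel_pitch = pixel_pitch,
         semantics_tag = semantics_tag),
    class = "grayscale_field"
  )
}

#' @export
print.grayscale_field <- function(x, ...) {
  cat(sprintf(
    "grayscale_field [%s]: %d x %d px, %.4g mm/px, range [%.4g, %.4g]\n",
    x$semantics_tag, nrow(x$values), ncol(x$values), x$pixel_pitch,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

tag_rank <- function(tag) {
  match(tag, c("raw", "vbmd", "ash_density", "modulus"))
}

# 1D Gaussian kernel truncated at `support` standard deviations and
# normalized to unit sum. Truncation radius floor(support * sigma) in pixels.
gaussian_kernel_1d <- function(sigma, support) {
  r <- floor(support * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Circular (periodic) 1D convolution of each matrix column with kernel k.
conv_cols_circular <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    sh <- j - r - 1L # shift in [-r, r]
    idx <- ((seq_len(n) - 1L + sh) %% n) + 1L
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  out
}

#' Gaussian smoothing of a raw grayscale slice
#'
#' Separable Gaussian low-pass with kernel truncated at `support` standard
#' deviations, applied with periodic (circular) boundary handling so the
#' total grayscale mass is conserved exactly and constants are preserved.
#'
#' @param field a raw-tagged [grayscale_field()].
#' @param sigma Gaussian standard deviation in pixels (default 1.2).
#' @param support truncation radius in standard deviations (default 2.0).
#' @return a smoothed raw-tagged field of the same shape.
#' @export
smooth_field <- function(field, sigma = 1.2, support = 2.0) {
  stopifnot(inherits(field, "grayscale_field"))
  if (field$semantics_tag != "raw") stop("smooth_field expects a raw field")
  if (!(sigma > 0) || !(support > 0)) {
    stop("sigma and support must be > 0")
  }
  k <- gaussian_kernel_1d(sigma, support)
  v <- conv_cols_circular(field$values, k)
  v <- t(conv_cols_circular(t(v), k))
  grayscale_field(v, field$pixel_pitch, "raw")
}

#' Maximum-intensity projection over randomly selected slices
#'
#' Keeps the pixel-wise maximum over `k` slices sampled without replacement
#' from the provided list (seeded). Projecting several thin sections onto one
#' plane thickens the apparent trabecular network, which keeps the derived
#' 2D finite element model connected.
#'
#' @param slices list of same-shaped [grayscale_field()]s with a common tag.
#' @param k number of slices to project (default 15).
#' @param seed integer seed for the slice selection.
#' @return a single field, pixel-wise maximum of the selected slices.
#' @export
max_projection <- function(slices, k = 15L, seed = 1L) {
  if (length(slices) < k) {
    stop(sprintf("need at least k = %d slices, got %d", k, length(slices)))
  }
  dims <- vapply(slices, function(s) dim(s$values), integer(2))
  if (any(dims != dims[, 1])) stop("all slices must share the same shape")
  tags <- vapply(slices, function(s) s$semantics_tag, character(1))
  if (length(unique(tags)) != 1) stop("all slices must share the same tag")
  sel <- withr_seed(seed, sample.int(length(slices), k))
  v <- slices[[sel[1]]]$values
  for (i in sel[-1]) v <- pmax(v, slices[[i]]$values)
  grayscale_field(v, slices[[1]]$pixel_pitch, tags[1])
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Grayscale to volumetric BMD calibration
#'
#' Applies the scanner's linear calibration `vbmd = slope * value + intercept`
#' (hydroxyapatite-equivalent density, mg/cm^3). Negative calibrated values
#' are clamped to zero: physical densities are non-negative.
#'
#' @param field a raw-tagged field.
#' @param slope,intercept calibration coefficients (defaults 1 and 0: the
#'   synthetic generator emits fields already on a vBMD-like scale).
#' @return a vbmd-tagged field.
#' @export
calibrate_vbmd <- function(field, slope = 1, intercept = 0) {
  stopifnot(inherits(field, "grayscale_field"))
  if (field$semantics_tag != "raw") stop("calibrate_vbmd expects a raw field")
  v <- slope * field$values + intercept
  v[v < 0] <- 0
  grayscale_field(v, field$pixel_pitch, "vbmd")
}

#' vBMD to ash density
#'
#' Converts hydroxyapatite-equivalent density to bone ash density with the
#' affine relation `rho_ash = 0.877 * rho_HA + 0.079` (both in mg/cm^3).
#'
#' @param field a vbmd-tagged field.
#' @return an ash_density-tagged field (mg/cm^3).
#' @export
vbmd_to_ash <- function(field) {
  stopifnot(inherits(field, "grayscale_field"))
  if (field$semantics_tag != "vbmd") stop("vbmd_to_ash expects a vbmd field")
  grayscale_field(0.877 * field$values + 0.079, field$pixel_pitch,
                  "ash_density")
}

#' Ash density to elastic modulus
#'
#' Power-law density-modulus mapping `E = coeff * (unit_scale * rho_ash) ^
#' exponent` in MPa, evaluated per element and floored at `e_floor` so that
#' marrow/void regions keep a small positive stiffness and never make the
#' finite element system singular. The default law
#' `E[MPa] = 10500 * rho_ash[g/cm^3] ^ 2.29` is a widely used vertebral
#' relation; `unit_scale = 1e-3` converts the mg/cm^3 ash field to g/cm^3.
#'
#' @param field an ash_density-tagged field (mg/cm^3).
#' @param coeff power-law coefficient (MPa at 1 g/cm^3).
#' @param exponent power-law exponent.
#' @param unit_scale multiplicative density unit conversion applied before
#'   the law (default 1e-3, mg/cm^3 -> g/cm^3).
#' @param e_floor minimum modulus in MPa (default 1e-6 * coeff).
#' @return a modulus-tagged field (MPa).
#' @export
ash_to_modulus <- function(field, coeff = 10500, exponent = 2.29,
                           unit_scale = 1e-3, e_floor = 1e-6 * coeff) {
  stopifnot(inherits(field, "grayscale_field"))
  if (field$semantics_tag != "ash_density") {
    stop("ash_to_modulus expects an ash_density field")
  }
  if (coeff < 0 || exponent < 0) stop("coeff and exponent must be >= 0")
  e <- coeff * (unit_scale * field$values)^exponent
  e[e < e_floor] <- e_floor
  grayscale_field(e, field$pixel_pitch, "modulus")
}

#' Parameters of the synthetic trabecular slice generator
#'
#' Controls the anisotropic Gaussian-random-field generator that stands in
#' for HR-pQCT transverse slices of vertebral cancellous bone. Defaults
#' emulate a 14.9 x 14.9 mm field at 82 um pixel pitch. `target_solid_fraction`
#' is the apparent solid area fraction of the thresholded maximum-intensity
#' projection (projection over 15 thin sections makes this far higher than
#' single-slice bone volume fraction). The two correlation lengths set the
#' in-plane trabecular spacing and its anisotropy.
#'
#' @param size_mm field edge length in mm (default 14.9).
#' @param pixel_pitch mm per pixel (default 0.082).
#' @param target_solid_fraction apparent solid fraction in (0, 1)
#'   (default 0.8: the maximum projection over 15 thin sections of elderly
#'   vertebral cancellous bone is a dense, plate-like slab).
#' @param correlation_length_x,correlation_length_y correlation lengths in mm
#'   (defaults 1.0 and 0.5: transversely anisotropic network).
#' @param n_slices number of slices to synthesize (default 15).
#' @param vbmd_base grayscale value (mg/cm^3 hydroxyapatite under the
#'   identity calibration) of bone-phase pixels at the solid threshold
#'   (default 1100): projected HR-pQCT slices have a bimodal bone/marrow
#'   histogram, so the bone phase starts well above zero.
#' @param vbmd_scale grayscale increment per unit standardized field excess
#'   above the solid threshold (default 250).
#' @param seed integer seed.
#' @return object of class `synth_bone_params`.
#' @export
synth_bone_params <- function(size_mm = 14.9, pixel_pitch = 0.082,
                              target_solid_fraction = 0.8,
                              correlation_length_x = 1.0,
                              correlation_length_y = 0.5,
                              n_slices = 15L, vbmd_base = 1100,
                              vbmd_scale = 250, seed = 1L) {
  if (!(target_solid_fraction > 0 && target_solid_fraction < 1)) {
    stop("target_solid_fraction must be in (0, 1)")
  }
  if (!(correlation_length_x > 0 && correlation_length_y > 0)) {
    stop("correlation lengths must be > 0")
  }
  if (n_slices < 1) stop("n_slices must be >= 1")
  n_px <- round(size_mm / pixel_pitch)
  if (n_px < 8) stop("degenerate field size")
  structure(list(
    size_mm = size_mm, pixel_pitch = pixel_pitch,
    target_solid_fraction = target_solid_fraction,
    correlation_length_x = correlation_length_x,
    correlation_length_y = correlation_length_y,
    n_slices = as.integer(n_slices), vbmd_base = vbmd_base,
    vbmd_scale = vbmd_scale,
    seed = as.integer(seed), n_px = as.integer(n_px)
  ), class = "synth_bone_params")
}

# One anisotropic Gaussian random field realization on an n x n grid via
# spectral filtering of white noise (circulant, hence consistent with the
# periodic smoothing convention). Returned standardized to mean 0, sd 1.
gaussian_random_field <- function(n, pitch, lx, ly) {
  freq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * pitch) # cycles/mm
  kx <- 2 * pi * freq
  # rows index y, columns index x
  KY2 <- matrix(kx^2, n, n) * ly^2
  KX2 <- t(matrix(kx^2, n, n)) * lx^2
  amp <- exp(-(KX2 + KY2) / 4) # sqrt of a Gaussian spectral density
  w <- matrix(stats::rnorm(n * n), n, n)
  f <- Re(stats::fft(stats::fft(w) * amp, inverse = TRUE)) / (n * n)
  (f - mean(f)) / stats::sd(f)
}

#' Synthesize trabecular-bone-like raw slices
#'
#' Draws `n_slices` anisotropic Gaussian-random-field realizations and maps
#' them monotonically to a vBMD-like grayscale with a step-plus-ramp map:
#' pixels whose field value exceeds the (1 - target_solid_fraction) quantile
#' of the pixel-wise maximum projection over all generated slices become
#' bone-phase pixels at `vbmd_base + vbmd_scale * excess`, the rest marrow
#' at zero, emulating the bimodal grayscale histogram of a projected
#' HR-pQCT section. Thresholding the maximum projection at its
#' (1 - target_solid_fraction) quantile therefore reproduces the requested
#' solid fraction by construction. Fully deterministic under `seed`.
#'
#' @param params a [synth_bone_params()].
#' @return list of `n_slices` raw-tagged [grayscale_field()]s.
#' @export
synth_slices <- function(params) {
  stopifnot(inherits(params, "synth_bone_params"))
  n <- params$n_px
  fields <- withr_seed(params$seed, {
    lapply(seq_len(params$n_slices), function(i) {
      gaussian_random_field(n, params$pixel_pitch,
                            params$correlation_length_x,
                            params$correlation_length_y)
    })
  })
  proj <- Reduce(pmax, fields)
  thr <- stats::quantile(proj, 1 - params$target_solid_fraction,
                         names = FALSE, type = 7)
  lapply(fields, function(f) {
    v <- (params$vbmd_base + (f - thr) * params$vbmd_scale) * (f > thr)
    grayscale_field(v, params$pixel_pitch, "raw")
  })
}

#' Full synthetic bone target chain: slices to heterogeneous FE model
#'
#' Runs the whole image-to-model chain on synthetic slices: Gaussian
#' smoothing of each raw slice, maximum-intensity projection over
#' `projection_k` randomly selected slices, linear vBMD calibration, ash
#' density conversion, density-modulus power law, and conversion to a voxel
#' plane-stress model.
#'
#' @param params a [synth_bone_params()].
#' @param poisson Poisson's ratio of the bone tissue elements (default 0.30).
#' @param sigma,support Gaussian smoothing parameters (defaults 1.2 px, 2.0).
#' @param projection_k number of slices entering the projection (default
#'   `min(15, n_slices)`).
#' @param slope,intercept scanner calibration (defaults identity).
#' @param coeff,exponent,unit_scale density-modulus law, see
#'   [ash_to_modulus()].
#' @return a list with the modulus-tagged field (`field`) and the
#'   [plane_stress_model()] (`model`).
#' @export
bone_target_model <- function(params, poisson = 0.30,
                              sigma = 1.2, support = 2.0,
                              projection_k = NULL,
                              slope = 1, intercept = 0,
                              coeff = 10500, exponent = 2.29,
                              unit_scale = 1e-3) {
  slices <- synth_slices(params)
  if (is.null(projection_k)) projection_k <- min(15L, length(slices))
  smoothed <- lapply(slices, smooth_field, sigma = sigma, support = support)
  proj <- max_projection(smoothed, k = projection_k, seed = params$seed)
  vb <- calibrate_vbmd(proj, slope = slope, intercept = intercept)
  ash <- vbmd_to_ash(vb)
  mod <- ash_to_modulus(ash, coeff = coeff, exponent = exponent,
                        unit_scale = unit_scale)
  list(
    field = mod,
    model = plane_stress_model(mod$values, poisson, mod$pixel_pitch)
  )
}
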