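# Seeded generator of ground-truthed spectra. The XAS-like defaults
# emulate a transition-metal K-edge: two weak pre-edge peaks (1s->3d),
# three rising-edge/charge-transfer peaks and a cumulative-Gaussian edge
# jump, with homoscedastic Gaussian noise. All truth values are synthetic
# package constants, not fitted values of any real data set.

#' Truth table for a synthetic spectrum
#'
#' @param components data.frame with columns `kind`, `amplitude`,
#'   `center`, `width` (FWHM for peaks, sigma for steps).
#' @param grid abscissa vector.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed integer RNG seed; regeneration with the same truth table
#'   is bitwise identical.
#' @return a `truth_table`.
#' @export
truth_table <- function(components, grid, noise_sd = 0, seed = 1L) {
  stopifnot(is.data.frame(components),
            all(c("kind", "amplitude", "center", "width") %in% names(components)))
  if (!all(components$kind %in% supported_kinds())) {
    stop_invalid("unknown kind(s) in truth table: %s",
                 paste(setdiff(components$kind, supported_kinds()), collapse = ", "))
  }
  if (any(components$width <= 0)) stop_invalid("truth widths must be > 0")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  structure(list(components = components, grid = as.numeric(grid),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "truth_table")
}

width_attr_name <- function(kind) {
  switch(kind, gaussian = "fwhmg", lorentzian = "fwhml",
         pseudovoigt = "fwhmv", voigt = "fwhmv", "sigma")
}

truth_attrs <- function(row) {
  attrs <- list(amplitude = row$amplitude, center = row$center)
  attrs[[width_attr_name(row$kind)]] <- row$width
  attrs
}

#' Noise-free composite curve of a truth table
#'
#' @param truth a `truth_table`.
#' @return numeric intensity vector on the truth grid.
#' @export
truth_curve <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  comps <- truth$components
  y <- numeric(length(truth$grid))
  for (i in seq_len(nrow(comps))) {
    y <- y + eval_component(comps$kind[i], truth$grid, truth_attrs(comps[i, ]))
  }
  y
}

#' Generate a spectrum from a truth table
#'
#' `y = sum of component curves + Normal(0, noise_sd)` drawn from the
#' truth table's seed.
#'
#' @param truth a `truth_table`.
#' @param x_label,y_label column labels for the resulting spectrum.
#' @return list with `spectrum` and the `truth` used.
#' @export
make_spectrum <- function(truth, x_label = "energy", y_label = "intensity") {
  stopifnot(inherits(truth, "truth_table"))
  y <- truth_curve(truth)
  if (truth$noise_sd > 0) {
    y <- y + withr::with_seed(truth$seed,
                              stats::rnorm(length(y), 0, truth$noise_sd))
  }
  list(spectrum = new_spectrum(truth$grid, y, x_label, y_label), truth = truth)
}

XAS_GRID <- seq(7105, 7130, length.out = 146)

# synthetic K-edge truth: 2 pre-edge + 3 rising-edge Gaussians + edge jump
xas_truth_components <- function(amplitude_scale = 1) {
  data.frame(
    kind = c(rep("gaussian", 5), "cumulative_gaussian"),
    amplitude = c(0.055, 0.070, 0.180, 0.300, 0.450, 1.0) *
      c(amplitude_scale, amplitude_scale, amplitude_scale,
        amplitude_scale, amplitude_scale, 1),
    center = c(7112.6, 7114.4, 7117.2, 7120.0, 7125.6, 7122.3),
    width = c(1.1, 1.3, 1.8, 2.0, 2.6, 1.2))
}

#' Generate a synthetic XAS-like spectrum pair
#'
#' Two 146-point spectra on a 7105-7130 eV grid, each the sum of two
#' pre-edge Gaussians, three rising-edge Gaussians and a
#' cumulative-Gaussian edge jump, plus Gaussian noise. The pair shares
#' all peak centers by construction while the second spectrum's peak
#' amplitudes are uniformly scaled, emulating two closely related
#' complexes measured at the same edge.
#'
#' @param seed integer seed; the two spectra use independent sub-seeds
#'   derived from it.
#' @param noise_sd noise standard deviation (default 0.005, on a
#'   normalized-intensity scale).
#' @param amplitude_scale_2 amplitude factor of the second spectrum's
#'   peaks (default 1.2).
#' @return list with `spectra` (list of 2 `spectrum`) and `truths`
#'   (list of 2 `truth_table`).
#' @export
make_xas_pair <- function(seed = 1L, noise_sd = 0.005, amplitude_scale_2 = 1.2) {
  seed <- as.integer(seed)
  t1 <- truth_table(xas_truth_components(1), XAS_GRID, noise_sd, seed)
  t2 <- truth_table(xas_truth_components(amplitude_scale_2), XAS_GRID,
                    noise_sd, seed + 500000L)
  s1 <- make_spectrum(t1, x_label = "Energy", y_label = "sample_1_norm")
  s2 <- make_spectrum(t2, x_label = "Energy", y_label = "sample_2_norm")
  list(spectra = list(s1$spectrum, s2$spectrum), truths = list(t1, t2))
}

#' Six-Gaussian benchmark truth table
#'
#' A generic multi-peak deconvolution benchmark: six partially
#' overlapping Gaussians of comparable amplitude on a 200-point grid,
#' used for model-selection experiments (fitting nested models with
#' fewer or more peaks than the truth).
#'
#' @param seed integer RNG seed.
#' @param noise_sd Gaussian noise standard deviation (default 0.02,
#'   i.e. a few percent of the smallest peak height).
#' @return a `truth_table`.
#' @export
six_gaussian_truth <- function(seed = 1L, noise_sd = 0.02) {
  truth_table(
    data.frame(kind = "gaussian",
               amplitude = c(1.0, 0.75, 0.9, 0.6, 0.85, 0.7),
               center = c(1.8, 4.0, 6.2, 8.0, 10.1, 12.2),
               width = c(1.0, 1.2, 1.1, 1.3, 1.0, 1.2)),
    grid = seq(0, 14, length.out = 200),
    noise_sd = noise_sd, seed = as.integer(seed))
}

#' Build a fit project whose initial values follow a truth table
#'
#' Convenience for tests and examples: converts a truth table into the
#' declarative component list [fit()] consumes, optionally perturbing the
#' initial values and bounding amplitudes/widths to be positive.
#'
#' @param truth a `truth_table`.
#' @param perturb relative perturbation of initial values (0 = start at
#'   truth).
#' @param center_window half-width (eV) of the box constraint on centers
#'   (default 5).
#' @param seed seed for the perturbation draw.
#' @return a `fit_project`.
#' @export
project_from_truth <- function(truth, perturb = 0, center_window = 5, seed = 1L) {
  stopifnot(inherits(truth, "truth_table"))
  comps <- truth$components
  jitter <- if (perturb > 0) {
    withr::with_seed(seed, stats::runif(3 * nrow(comps), 1 - perturb, 1 + perturb))
  } else rep(1, 3 * nrow(comps))
  components <- lapply(seq_len(nrow(comps)), function(i) {
    kind <- comps$kind[i]
    wname <- width_attr_name(kind)
    j <- 3 * (i - 1)
    attrs <- list(
      amplitude = list(value = comps$amplitude[i] * jitter[j + 1], min = 0),
      center = list(value = comps$center[i] +
                      (jitter[j + 2] - 1) * comps$width[i],
                    min = comps$center[i] - center_window,
                    max = comps$center[i] + center_window))
    attrs[[wname]] <- list(value = comps$width[i] * jitter[j + 3],
                           min = comps$width[i] * 0.05,
                           max = comps$width[i] * 20)
    attrs <- lapply(attrs, function(a) {
      validate_parameter_spec(a, "synthetic")
    })
    list(index = as.character(i), kind = kind, attributes = attrs)
  })
  structure(list(settings = list(), description = list(source = "synthetic"),
                 components = components, metadata = list()),
            class = "fit_project")
}
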