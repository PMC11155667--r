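# Numerical lineshape kernel: peaks, steps and backgrounds evaluated on an
# abscissa grid. All peak models are FWHM-parameterized and amplitude means
# integrated AREA, not height, so intensities are comparable across kinds.

PEAK_KINDS <- c("gaussian", "lorentzian", "pseudovoigt", "voigt")
STEP_KINDS <- c("heaviside", "arctan", "erf", "logistic", "cumulative_gaussian")
BACKGROUND_KINDS <- c("constant", "linear", "polynomial", "exponential")

# attribute sets consulted per kind; everything else in a spec is ignored
KIND_ATTRIBUTES <- list(
  gaussian            = c("amplitude", "center", "fwhmg"),
  lorentzian          = c("amplitude", "center", "fwhml"),
  pseudovoigt         = c("amplitude", "center", "fwhmv", "fraction"),
  voigt               = c("amplitude", "center", "fwhmv", "gamma"),
  heaviside           = c("amplitude", "center", "sigma"),
  arctan              = c("amplitude", "center", "sigma"),
  erf                 = c("amplitude", "center", "sigma"),
  logistic            = c("amplitude", "center", "sigma"),
  cumulative_gaussian = c("amplitude", "center", "sigma"),
  constant            = "intercept",
  linear              = c("intercept", "slope"),
  polynomial          = paste0("c", 0:7),
  exponential         = c("amplitude", "decay", "center")
)

# FWHM of a Gaussian = 2*sqrt(2*ln 2)*sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

stop_model <- function(...) {
  stop(errorCondition(sprintf(...), class = c("peakfitr_model_error", "error")))
}
stop_invalid <- function(...) {
  stop(errorCondition(sprintf(...), class = c("peakfitr_validation_error", "error")))
}

attr_or <- function(attrs, name, default) {
  v <- attrs[[name]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) default else as.numeric(v)
}

check_width <- function(w, name) {
  if (!is.finite(w) || w <= 0) {
    stop_invalid("lineshape width '%s' must be finite and > 0 (got %g)", name, w)
  }
  w
}

#' Evaluate the Faddeeva function w(z) for Im(z) >= 0
#'
#' `w(z) = exp(-z^2) erfc(-iz)`, the kernel of the Voigt profile. Uses the
#' complex error function for moderate `|z|` and a Lentz-style continued
#' fraction in the asymptotic regime where `exp(-z^2)` would overflow.
#'
#' @param z complex vector with non-negative imaginary part.
#' @return complex vector of the same length.
#' @keywords internal
faddeeva <- function(z) {
  out <- complex(length(z))
  small <- Mod(z) <= 4
  if (any(small)) {
    zs <- z[small]
    out[small] <- exp(-zs^2) * (1 - pracma::erfz(-1i * zs))
  }
  if (any(!small)) {
    zl <- z[!small]
    # w(z) = (i/sqrt(pi)) / (z - 1/2/(z - 1/(z - 3/2/(z - 2/(z - ...)))))
    f <- zl
    for (k in rev(seq_len(40))) f <- zl - (k / 2) / f
    out[!small] <- (1i / sqrt(pi)) / f
  }
  out
}

ls_gaussian <- function(x, amplitude, center, fwhm) {
  sigma <- check_width(fwhm, "fwhmg") * FWHM_TO_SIGMA
  amplitude * stats::dnorm(x, mean = center, sd = sigma)
}

ls_lorentzian <- function(x, amplitude, center, fwhm) {
  g <- check_width(fwhm, "fwhml") / 2
  amplitude * (g / pi) / ((x - center)^2 + g^2)
}

ls_pseudovoigt <- function(x, amplitude, center, fwhm, fraction) {
  check_width(fwhm, "fwhmv")
  if (!is.finite(fraction) || fraction < 0 || fraction > 1) {
    stop_invalid("pseudo-Voigt fraction must lie in [0, 1] (got %g)", fraction)
  }
  amplitude * (fraction * ls_lorentzian(x, 1, center, fwhm) +
               (1 - fraction) * ls_gaussian(x, 1, center, fwhm))
}

ls_voigt <- function(x, amplitude, center, fwhm, gamma) {
  sigma <- check_width(fwhm, "fwhmv") * FWHM_TO_SIGMA
  if (is.null(gamma)) gamma <- fwhm / 2
  if (!is.finite(gamma) || gamma < 0) {
    stop_invalid("Voigt gamma must be finite and >= 0 (got %g)", gamma)
  }
  if (gamma == 0) return(ls_gaussian(x, amplitude, center, fwhm))
  z <- ((x - center) + 1i * gamma) / (sigma * sqrt(2))
  amplitude * Re(faddeeva(z)) / (sigma * sqrt(2 * pi))
}

#' Evaluate a peak lineshape on a grid
#'
#' All peak kinds follow the area convention: the integral of the returned
#' curve over an unbounded grid equals `amplitude`, and the maximum sits at
#' `center`. Widths are full widths at half maximum.
#'
#' @param kind one of `"gaussian"`, `"lorentzian"`, `"pseudovoigt"`,
#'   `"voigt"`.
#' @param grid numeric abscissa vector (finite).
#' @param attrs named list of attributes. Missing entries default to
#'   `amplitude = 1`, `center = 0`, width `= 1`, `fraction = 0.5` and
#'   `gamma = fwhmv / 2`.
#' @return numeric intensity vector, same length as `grid`.
#' @examples
#' eval_peak("gaussian", 0, list())          # 2 * sqrt(log(2) / pi)
#' eval_peak("lorentzian", 0, list(fwhml = 1))  # 2 / pi
#' @export
eval_peak <- function(kind, grid, attrs = list()) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% PEAK_KINDS)) {
    stop_model("unknown peak kind '%s'; supported: %s",
               as.character(kind)[1], paste(PEAK_KINDS, collapse = ", "))
  }
  if (!all(is.finite(grid))) stop_invalid("abscissa grid must be finite")
  a <- attr_or(attrs, "amplitude", 1)
  c0 <- attr_or(attrs, "center", 0)
  switch(kind,
    gaussian    = ls_gaussian(grid, a, c0, attr_or(attrs, "fwhmg", 1)),
    lorentzian  = ls_lorentzian(grid, a, c0, attr_or(attrs, "fwhml", 1)),
    pseudovoigt = ls_pseudovoigt(grid, a, c0, attr_or(attrs, "fwhmv", 1),
                                 attr_or(attrs, "fraction", 0.5)),
    voigt       = {
      fwhm <- attr_or(attrs, "fwhmv", 1)
      ls_voigt(grid, a, c0, fwhm, attr_or(attrs, "gamma", fwhm / 2))
    })
}

#' Evaluate a step (edge) function on a grid
#'
#' Monotone non-decreasing curves (for positive `amplitude`) rising from 0
#' to `amplitude`, used for edge jumps such as the XAS ionization step
#' modeled by a cumulative Gaussian.
#'
#' @param kind one of `"heaviside"`, `"arctan"`, `"erf"`, `"logistic"`,
#'   `"cumulative_gaussian"`.
#' @param grid numeric abscissa vector.
#' @param attrs named list with `amplitude` (asymptotic height, default 1),
#'   `center` (inflection, default 0) and `sigma` (width scale, default 1).
#' @return numeric intensity vector.
#' @export
eval_step <- function(kind, grid, attrs = list()) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% STEP_KINDS)) {
    stop_model("unknown step kind '%s'; supported: %s",
               as.character(kind)[1], paste(STEP_KINDS, collapse = ", "))
  }
  a <- attr_or(attrs, "amplitude", 1)
  c0 <- attr_or(attrs, "center", 0)
  s <- check_width(attr_or(attrs, "sigma", 1), "sigma")
  t <- (grid - c0) / s
  switch(kind,
    heaviside           = a * as.numeric(grid >= c0),
    arctan              = a * (0.5 + atan(t) / pi),
    erf                 = a * 0.5 * (1 + pracma::erf(t)),
    logistic            = a / (1 + exp(-t)),
    cumulative_gaussian = a * stats::pnorm(t))
}

#' Evaluate a background function on a grid
#'
#' @param kind `"constant"`, `"linear"`, `"polynomial"` or `"exponential"`.
#' @param grid numeric abscissa vector.
#' @param coeffs named list: `intercept` for constant; `intercept`/`slope`
#'   for linear; `c0`, `c1`, ... (ascending powers) for polynomial;
#'   `amplitude`, `decay`, optional `center` for exponential
#'   `amplitude * exp(-(x - center) / decay)`.
#' @return numeric intensity vector.
#' @export
eval_background <- function(kind, grid, coeffs = list()) {
  if (!is.character(kind) || length(kind) != 1L || !(kind %in% BACKGROUND_KINDS)) {
    stop_model("unknown background kind '%s'; supported: %s",
               as.character(kind)[1], paste(BACKGROUND_KINDS, collapse = ", "))
  }
  switch(kind,
    constant = {
      if (is.null(coeffs$intercept) && length(coeffs) > 1L) {
        stop_invalid("constant background takes a single coefficient 'intercept'")
      }
      rep(attr_or(coeffs, "intercept", 0), length(grid))
    },
    linear = {
      extra <- setdiff(names(coeffs), c("intercept", "slope"))
      if (length(extra)) {
        stop_invalid("linear background takes 'intercept' and 'slope' only (got %s)",
                     paste(extra, collapse = ", "))
      }
      attr_or(coeffs, "intercept", 0) + attr_or(coeffs, "slope", 0) * grid
    },
    polynomial = {
      keys <- names(coeffs)
      if (!length(keys) || !all(grepl("^c[0-9]+$", keys))) {
        stop_invalid("polynomial background coefficients must be named c0, c1, ...")
      }
      deg <- as.integer(sub("^c", "", keys))
      y <- numeric(length(grid))
      for (i in seq_along(keys)) y <- y + as.numeric(coeffs[[i]]) * grid^deg[i]
      y
    },
    exponential = {
      decay <- check_width(attr_or(coeffs, "decay", 1), "decay")
      attr_or(coeffs, "amplitude", 1) *
        exp(-(grid - attr_or(coeffs, "center", 0)) / decay)
    })
}

#' Evaluate any supported component kind
#'
#' Dispatches to [eval_peak()], [eval_step()] or [eval_background()].
#'
#' @inheritParams eval_peak
#' @return numeric intensity vector.
#' @export
eval_component <- function(kind, grid, attrs = list()) {
  if (kind %in% PEAK_KINDS) return(eval_peak(kind, grid, attrs))
  if (kind %in% STEP_KINDS) return(eval_step(kind, grid, attrs))
  if (kind %in% BACKGROUND_KINDS) return(eval_background(kind, grid, attrs))
  stop_model("unknown component kind '%s'", as.character(kind)[1])
}

#' Supported component kinds
#'
#' @return character vector of all lineshape, step and background names.
#' @export
supported_kinds <- function() c(PEAK_KINDS, STEP_KINDS, BACKGROUND_KINDS)
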