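# shared fixtures: all built in code at test time

# a model document in the standard declarative layout: one Gaussian with
# amplitude/center/fwhmg specs
fig4_style_json <- function() {
  paste0('{"fitting": {"description": {"project_name": "demo"},',
         ' "peaks": {"1": {"gaussian": {',
         '"amplitude": {"max": 2, "min": 0, "vary": true, "value": 1},',
         '"center": {"max": 2, "min": -2, "vary": true, "value": 0},',
         '"fwhmg": {"max": 2.5, "min": 0.00002, "vary": true, "value": 1}',
         '}}}}}')
}

# manual fit_project constructor for tests that need full control
manual_project <- function(components, settings = list()) {
  comps <- lapply(components, function(co) {
    co$attributes <- lapply(co$attributes, function(a) {
      peakfitr:::validate_parameter_spec(a, "test")
    })
    co
  })
  structure(list(settings = settings, description = list(),
                 components = comps, metadata = list()),
            class = "fit_project")
}

single_gaussian_project <- function(amplitude = 1, center = 0, fwhmg = 1,
                                    amp_max = Inf) {
  manual_project(list(list(index = "1", kind = "gaussian", attributes = list(
    amplitude = list(value = amplitude, min = 0, max = amp_max),
    center = list(value = center),
    fwhmg = list(value = fwhmg, min = 1e-3)))))
}

# rebuild a project with attribute values replaced by fitted ones
project_with_values <- function(project, ps) {
  vals <- param_values(ps)
  project$components <- lapply(project$components, function(co) {
    co$attributes <- lapply(stats::setNames(names(co$attributes),
                                            names(co$attributes)), function(an) {
      a <- co$attributes[[an]]
      a$value <- unname(vals[sprintf("%s_%s_%s", co$kind, an, co$index)])
      a
    })
    co
  })
  project
}

# nested-model initialization for model-selection ladders: k below the
# truth's peak count drops the lowest-amplitude peaks, k above adds one
# low-amplitude extra peak
ladder_truth <- function(truth, k) {
  comps <- truth$components
  if (k <= nrow(comps)) {
    keep <- order(comps$amplitude, decreasing = TRUE)[seq_len(k)]
    comps <- comps[sort(keep), , drop = FALSE]
  } else {
    comps <- rbind(comps, data.frame(kind = "gaussian", amplitude = 0.02,
                                     center = 7.1, width = 1.0))
  }
  truth_table(comps, truth$grid, truth$noise_sd, truth$seed)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual / expected - 1)), tol)
}
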