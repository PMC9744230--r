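#' Construct the mechanistic model parameter set
#'
#' Bundles every constant of the glucose--insulin--exocytosis model together
#' with the two estimated parameters: insulin sensitivity `S_I` and maximal
#' insulin secretion capacity `sigma`.  All fixed constants come from the
#' shipped default parameter file (see [default_model_parameters()]); any
#' field can be overridden by name.
#'
#' @param S_I insulin sensitivity (model-native day^-1 per uIU/mL scale),
#'   admissible range `[0.005, 3]`.
#' @param sigma maximal insulin secretion capacity (unitless), admissible
#'   range `[0.01, 10]`.
#' @param ... named overrides of any field of the default parameter list
#'   (e.g. `gamma`, `k`, `V`, `exo_coeffs`, `hgp_coeffs`, `ogtt_input`).
#'
#' @return An object of class `model_parameters`: a named list with fields
#'   `S_I`, `sigma`, `gamma`, `E_G0`, `si_scale`, `k`, `V`, `beta`,
#'   `hepa_SI`, `r2_0`, `exo_coeffs`, `hgp_coeffs`, `ogtt_input`.
#' @export
#' @examples
#' p <- model_parameters(S_I = 0.3, sigma = 3)
#' p$gamma
model_parameters <- function(S_I = NULL, sigma = NULL, ...) {
  p <- default_model_parameters()
  if (!is.null(S_I)) p$S_I <- S_I
  if (!is.null(sigma)) p$sigma <- sigma
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(p)) stop("unknown model parameter field: ", nm)
    if (is.list(p[[nm]]) && is.list(dots[[nm]])) {
      p[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      p[[nm]] <- dots[[nm]]
    }
  }
  validate_model_parameters(p)
  class(p) <- "model_parameters"
  p
}

#' Load the shipped default model constants
#'
#' Reads `inst/extdata/default_model_parameters.yaml`, the single source of
#' all fixed model constants.
#'
#' @param file optional path to an alternative parameter file in the same
#'   flat YAML layout.
#' @return A named list (not yet classed); see [model_parameters()].
#' @export
default_model_parameters <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "default_model_parameters.yaml",
                        package = "ogttda", mustWork = TRUE)
  }
  p <- yaml::read_yaml(file)
  p$model_version <- NULL
  p
}

validate_model_parameters <- function(p) {
  stopifnot(
    is.numeric(p$S_I), p$S_I >= 0.005, p$S_I <= 3,
    is.numeric(p$sigma), p$sigma >= 0.01, p$sigma <= 10,
    p$E_G0 > 0, p$k > 0, p$V > 0, p$beta > 0, p$r2_0 > 0,
    p$si_scale > 0, p$hepa_SI >= 0,
    p$ogtt_input$dose_g >= 0
  )
  invisible(p)
}

#' Parameter bounds used throughout inference
#'
#' @return list with elements `S_I` and `sigma`, each `c(lower, upper)`.
#' @export
parameter_bounds <- function() {
  list(S_I = c(0.005, 3), sigma = c(0.01, 10))
}

# Glucose-sensing sigmoid shared by the exocytosis coefficients.  Increasing
# in G; increasing K+-ATP channel density (gamma) raises the half-activation
# glucose and therefore lowers secretion.
exo_kappa <- function(G, gamma, ec) {
  1 / (1 + exp(-(G - ec$K_half * (1 + gamma)) / ec$K_slope))
}

#' Evaluate the exocytosis coefficient functions
#'
#' The vesicle pools obey the linear fast subsystem
#' `dN5/dt = c55 N5 + c56 N6` and `dN6/dt = c60 + c65 N5 + c66 N6`, with
#' coefficients that depend on glucose `G`, channel density `gamma`, the
#' secretion capacity `sigma`, and the baseline priming rate `r2_0`:
#' `c55(G, gamma)` (fusion + unpriming loss), `c56(G, gamma, r2_0)`
#' (priming gain), `c65` (constant unpriming return), `c66(G, gamma, r2_0)`
#' (priming + undocking loss) and `c60(G, gamma, sigma)` (sigma-scaled
#' docking influx).  `C_ISR(G, gamma)` is the calcium-dependent fusion rate
#' so that the insulin secretion rate is `ISR = C_ISR * N5`.
#'
#' @param G plasma glucose, mg/dL.
#' @param params a [model_parameters()] object.
#' @return named list `c55, c56, c65, c66, c60, C_ISR` (all finite reals).
#' @export
exocytosis_coefficients <- function(G, params) {
  ec <- params$exo_coeffs
  kap <- exo_kappa(G, params$gamma, ec)
  C_ISR <- ec$cisr_max * kap
  r2 <- params$r2_0 * (ec$r2_base + kap)
  list(
    c55 = -(C_ISR + ec$r_unprime),
    c56 = r2,
    c65 = ec$r_unprime,
    c66 = -(r2 + ec$r_undock),
    c60 = params$sigma * (ec$dock_base + ec$dock_max * kap),
    C_ISR = C_ISR
  )
}
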