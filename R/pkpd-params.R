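#' Patient-specific PK/PD parameters
#'
#' Bundles the 12 constants that drive the compartmental pharmacokinetic
#' model and the sigmoid-Emax effect law for a single virtual patient.
#' Amounts are in mg, volumes in L, concentrations in mg/L and time in
#' minutes throughout the package.
#'
#' @param ka absorption rate (1/min).
#' @param BIO bioavailability, in (0, 1].
#' @param Q intercompartmental clearance (L/min).
#' @param V1,V2 central / peripheral compartment volumes (L).
#' @param CL clearance rate (L/min).
#' @param Rsyn endogenous levodopa synthesis rate (mg/min).
#' @param kEO effect-compartment equilibration rate (1/min).
#' @param BASE baseline effect, the lowest attainable TRS score.
#' @param EMAX maximum change from baseline (TRS units).
#' @param EC50 effect-compartment concentration at half-maximal effect (mg/L).
#' @param gamma Hill coefficient; how steeply the response rises with
#'   concentration.
#'
#' @details `BASE` and `BASE + EMAX` bound the effect values of the patient
#'   and must lie inside the TRS scale `[-3, 3]`.
#'
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(ka, BIO, Q, V1, V2, CL, Rsyn, kEO,
                           BASE, EMAX, EC50, gamma) {
  p <- list(ka = ka, BIO = BIO, Q = Q, V1 = V1, V2 = V2, CL = CL,
            Rsyn = Rsyn, kEO = kEO, BASE = BASE, EMAX = EMAX,
            EC50 = EC50, gamma = gamma)
  p <- lapply(p, as.numeric)
  class(p) <- "patient_params"
  validate_patient_params(p)
  p
}

validate_patient_params <- function(p) {
  pos <- c("ka", "Q", "V1", "V2", "CL", "kEO", "EC50", "gamma")
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("patient parameter '%s' must be strictly positive", nm))
  }
  if (p$BIO <= 0 || p$BIO > 1) stop("BIO must be in (0, 1]")
  if (p$Rsyn < 0) stop("Rsyn must be non-negative")
  if (p$BASE < -3) stop("BASE must be >= -3 (TRS scale)")
  if (p$BASE + p$EMAX > 3 + 1e-9)
    stop("BASE + EMAX must be <= 3 (TRS scale)")
  if (p$EMAX < 0) stop("EMAX must be non-negative")
  invisible(p)
}

#' @export
print.patient_params <- function(x, ...) {
  cat("PK/PD patient parameters:\n")
  print(unlist(x))
  invisible(x)
}

param_names <- function() {
  c("ka", "BIO", "Q", "V1", "V2", "CL", "Rsyn", "kEO",
    "BASE", "EMAX", "EC50", "gamma")
}

#' Population model for sampling virtual patients
#'
#' A multivariate-normal description of the PK/PD parameter distribution in
#' a PD population: a mean vector, a covariance matrix and per-parameter
#' admissible intervals used to clip draws to physiological ranges.
#'
#' @param means named numeric vector over the 12 parameters
#'   (see [patient_params()]).
#' @param covariance symmetric positive-semidefinite matrix in the same
#'   parameter order.
#' @param clip_bounds 2-row matrix (`lower`, `upper`) with one column per
#'   parameter.
#'
#' @return An object of class `population_model`.
#' @export
population_model <- function(means, covariance, clip_bounds) {
  nms <- param_names()
  means <- means[nms]
  if (anyNA(means)) stop("means must cover all 12 PK/PD parameters")
  covariance <- as.matrix(covariance)
  dimnames(covariance) <- list(nms, nms)
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semi-definite")
  clip_bounds <- as.matrix(clip_bounds)[, nms, drop = FALSE]
  if (any(means < clip_bounds[1, ] | means > clip_bounds[2, ]))
    stop("population means must lie inside clip_bounds")
  structure(list(means = means, covariance = covariance,
                 clip_bounds = clip_bounds),
            class = "population_model")
}

#' Read / write a population model (YAML)
#'
#' The population file stores means, per-parameter standard deviations, a
#' correlation matrix and clip bounds; the covariance is reconstructed as
#' `D %*% corr %*% D` with `D = diag(sd)`.
#'
#' @param path path to a YAML file.
#' @return [read_population()] returns a `population_model`.
#' @export
read_population <- function(path) {
  y <- yaml::read_yaml(path)
  nms <- param_names()
  means <- unlist(y$means)[nms]
  sds <- unlist(y$sd)[nms]
  corr <- diag(length(nms))
  dimnames(corr) <- list(nms, nms)
  for (entry in y$correlations) {
    a <- entry$pair[[1]]; b <- entry$pair[[2]]
    corr[a, b] <- corr[b, a] <- entry$value
  }
  covariance <- diag(sds) %*% corr %*% diag(sds)
  lower <- unlist(y$clip_lower)[nms]
  upper <- unlist(y$clip_upper)[nms]
  population_model(means, covariance, rbind(lower = lower, upper = upper))
}

#' Default synthetic PD population
#'
#' A documented synthetic population shipped with the package whose
#' simulated TRS dynamics stay inside `[-3, 3]` and show a visible oral
#' dose response (typical unmedicated state near `BASE`, a 100 mg dose
#' lifting the state into positive TRS territory). It is a configuration
#' file, not code: see `system.file("extdata", "population_default.yaml",
#' package = "pdsched")`.
#'
#' @return A `population_model`.
#' @export
default_population <- function() {
  read_population(system.file("extdata", "population_default.yaml",
                              package = "pdsched"))
}

#' Sample virtual patients from a population model
#'
#' Draws parameter vectors from the multivariate normal defined by the
#' population means and covariance, then clips each parameter to its
#' admissible interval. `EMAX` is additionally clipped to `3 - BASE` so the
#' effect bounds always sit inside the TRS scale.
#'
#' @param pop a [population_model()].
#' @param n number of patients.
#' @param seed integer seed; draws are reproducible under the same seed.
#' @return A list of `patient_params` of length `n`.
#' @export
sample_patients <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  draws <- MASS::mvrnorm(n, mu = pop$means, Sigma = pop$covariance)
  draws <- matrix(draws, nrow = n, dimnames = list(NULL, param_names()))
  lower <- pop$clip_bounds[1, ]
  upper <- pop$clip_bounds[2, ]
  lapply(seq_len(n), function(i) {
    x <- pmin(pmax(draws[i, ], lower), upper)
    x["EMAX"] <- min(x["EMAX"], 3 - x["BASE"])
    do.call(patient_params, as.list(x))
  })
}

#' @rdname sample_patients
#' @export
sample_patient <- function(pop, seed = NULL) sample_patients(pop, 1L, seed)[[1]]

#' Serialize patients to / from JSON
#'
#' @param patients list of `patient_params`.
#' @param path file path.
#' @export
write_patients <- function(patients, path) {
  jsonlite::write_json(lapply(patients, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  lapply(jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE),
         function(p) do.call(patient_params, p))
}
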