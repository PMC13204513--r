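#' Construct a covariate snapshot for one neonate
#'
#' A covariate set holds the patient state that feeds the typical-value
#' equations of a popPK model: body weight, postmenstrual age (PMA),
#' postnatal age (PNA) and serum creatinine (SCr), with optional urine
#' output and the time on the study clock at which the snapshot applies.
#' Units are fixed at this boundary: kg, weeks, days, µmol/L, mL/kg/h,
#' hours.  Converters belong in the I/O layer.
#'
#' @param weight_kg Body weight (kg), > 0.
#' @param pma_weeks Postmenstrual age (weeks), > 0.
#' @param pna_days Postnatal age (days), >= 0. Optional (`NA` allowed) when
#'   the model does not use PNA.
#' @param scr_umol_L Serum creatinine (µmol/L), > 0. Optional (`NA`) when the
#'   model does not use SCr.
#' @param urine_output_ml_kg_h Optional urine output rate (mL/kg/h).
#' @param measurement_time_h Time of the snapshot, hours on the study clock.
#'
#' @return An object of class `covariate_set` (a named list).
#' @examples
#' covariate_set(weight_kg = 1.06, pma_weeks = 28.9, scr_umol_L = 56)
#' @export
covariate_set <- function(weight_kg, pma_weeks, pna_days = NA_real_,
                          scr_umol_L = NA_real_,
                          urine_output_ml_kg_h = NA_real_,
                          measurement_time_h = 0) {
  cov <- list(weight_kg = as.numeric(weight_kg),
              pma_weeks = as.numeric(pma_weeks),
              pna_days = as.numeric(pna_days),
              scr_umol_L = as.numeric(scr_umol_L),
              urine_output_ml_kg_h = as.numeric(urine_output_ml_kg_h),
              measurement_time_h = as.numeric(measurement_time_h))
  class(cov) <- "covariate_set"
  validate_covariate_set(cov)
  cov
}

validate_covariate_set <- function(cov) {
  for (f in c("weight_kg", "pma_weeks")) {
    v <- cov[[f]]
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("covariate '%s' must be a positive finite number (got %s)",
                   f, format(v)), call. = FALSE)
    }
  }
  if (!is.na(cov$scr_umol_L) && cov$scr_umol_L <= 0) {
    stop("covariate 'scr_umol_L' must be > 0 when present", call. = FALSE)
  }
  if (!is.na(cov$pna_days) && cov$pna_days < 0) {
    stop("covariate 'pna_days' must be >= 0", call. = FALSE)
  }
  invisible(cov)
}

#' @export
print.covariate_set <- function(x, ...) {
  cat("<covariate_set> WT", x$weight_kg, "kg, PMA", x$pma_weeks, "wk, PNA",
      x$pna_days, "d, SCr", x$scr_umol_L, "umol/L\n")
  invisible(x)
}

#' Typical vancomycin clearance under the Chung 2023 neonatal model
#'
#' Clearance combines linear weight scaling to a 70 kg reference, a Hill
#' (sigmoid Emax) maturation function of postmenstrual age with half-maximal
#' maturation at 47.7 weeks, and a power function of serum creatinine
#' referenced to 34 µmol/L:
#' \deqn{CL = 13.9 \cdot (WT/70) \cdot
#'   \frac{PMA^{0.739}}{PMA^{0.739} + 47.7^{0.739}} \cdot
#'   (SCr/34)^{-0.653}}
#'
#' @param cov A [covariate_set()] with positive `weight_kg`, `pma_weeks`
#'   and `scr_umol_L`.
#' @return Typical clearance in L/h.
#' @examples
#' chung2023_typical_clearance(
#'   covariate_set(weight_kg = 1.06, pma_weeks = 28.9, scr_umol_L = 56))
#' @seealso [chung2023_typical_volume()], [chung2023_model()]
#' @export
chung2023_typical_clearance <- function(cov) {
  stopifnot(inherits(cov, "covariate_set"))
  validate_covariate_set(cov)
  if (is.na(cov$scr_umol_L)) {
    stop("Chung 2023 clearance requires serum creatinine", call. = FALSE)
  }
  wt <- cov$weight_kg; pma <- cov$pma_weeks; scr <- cov$scr_umol_L
  13.9 * (wt / 70) * pma^0.739 / (pma^0.739 + 47.7^0.739) *
    (scr / 34)^(-0.653)
}

#' Typical vancomycin volume of distribution under the Chung 2023 model
#'
#' Volume scales linearly with body weight from a 65.5 L reference at 70 kg:
#' \deqn{V = 65.5 \cdot (WT/70)}
#'
#' @inheritParams chung2023_typical_clearance
#' @return Typical central volume in L.
#' @examples
#' chung2023_typical_volume(covariate_set(weight_kg = 70, pma_weeks = 40))
#' @export
chung2023_typical_volume <- function(cov) {
  stopifnot(inherits(cov, "covariate_set"))
  validate_covariate_set(cov)
  65.5 * (cov$weight_kg / 70)
}

#' Declare a popPK covariate model
#'
#' Models are declared as a small set of multiplicative term kinds applied to
#' a base typical value per structural parameter, so published neonatal
#' covariate models can be expressed without a formula interpreter:
#' \describe{
#'   \item{power}{`(cov/ref)^exponent` — covers allometric weight scaling
#'     (exponent 0.75 or 1) and power creatinine terms.}
#'   \item{hill}{`cov^hill / (cov^hill + tm50^hill)` — sigmoidal maturation,
#'     e.g. of PMA.}
#'   \item{linear}{`1 + slope * (cov - ref)` — additive covariate shifts.}
#' }
#'
#' @param name Model identifier.
#' @param n_compartments 1 or 2 (only one-compartment models are evaluable by
#'   the bundled prediction engine).
#' @param params Named list, one entry per structural parameter (`cl_L_h`,
#'   `v_L`, optionally `q_L_h`, `vp_L`). Each entry is a list with `base`
#'   (positive typical value at the reference covariates) and optional
#'   `terms`, a list of term lists with a `kind` field as above and a
#'   `covariate` naming a [covariate_set()] field.
#' @param iiv Named numeric vector of lognormal inter-individual variances
#'   (variance of log parameter), e.g. `c(cl_L_h = 0.1)`. May be empty.
#' @param residual Residual error model: list with any of `additive_sd`
#'   (mg/L) and `proportional_cv` (fraction). May be `NULL` when the model is
#'   used for point prediction only.
#'
#' @return An object of class `poppk_model`.
#' @examples
#' toy <- poppk_model("allometric-toy", 1, params = list(
#'   cl_L_h = list(base = 2, terms = list(
#'     list(kind = "power", covariate = "weight_kg", ref = 70,
#'          exponent = 0.75))),
#'   v_L = list(base = 40, terms = list(
#'     list(kind = "power", covariate = "weight_kg", ref = 70,
#'          exponent = 1)))))
#' evaluate_model(toy, covariate_set(weight_kg = 70, pma_weeks = 40))
#' @export
poppk_model <- function(name, n_compartments = 1, params, iiv = numeric(),
                        residual = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            n_compartments %in% c(1, 2), is.list(params))
  if (!all(c("cl_L_h", "v_L") %in% names(params))) {
    stop("'params' must define at least 'cl_L_h' and 'v_L'", call. = FALSE)
  }
  two_cpt_pars <- c("q_L_h", "vp_L") %in% names(params)
  if (n_compartments == 2 && !all(two_cpt_pars)) {
    stop("a 2-compartment model must define 'q_L_h' and 'vp_L'",
         call. = FALSE)
  }
  if (n_compartments == 1 && any(two_cpt_pars)) {
    stop("'q_L_h'/'vp_L' are only meaningful for 2-compartment models",
         call. = FALSE)
  }
  for (p in names(params)) {
    spec <- params[[p]]
    if (!is.numeric(spec$base) || spec$base <= 0) {
      stop(sprintf("parameter '%s': 'base' must be a positive number", p),
           call. = FALSE)
    }
    for (term in spec$terms %||% list()) {
      if (!term$kind %in% c("power", "allometric", "hill", "linear")) {
        stop(sprintf("unknown term kind '%s' in parameter '%s'",
                     term$kind, p), call. = FALSE)
      }
      if (is.null(term$covariate)) {
        stop(sprintf("term in parameter '%s' lacks a 'covariate'", p),
             call. = FALSE)
      }
    }
  }
  iiv <- unlist(iiv) %||% numeric()
  if (length(iiv) && (is.null(names(iiv)) || any(iiv < 0))) {
    stop("'iiv' must be a named vector of non-negative variances",
         call. = FALSE)
  }
  structure(list(name = name, n_compartments = as.integer(n_compartments),
                 params = params, iiv = iiv, residual = residual),
            class = "poppk_model")
}

#' @export
print.poppk_model <- function(x, ...) {
  cat(sprintf("<poppk_model> %s: %d-compartment, parameters: %s\n",
              x$name, x$n_compartments, paste(names(x$params),
                                              collapse = ", ")))
  invisible(x)
}

eval_term <- function(term, cov, param_name) {
  value <- cov[[term$covariate]]
  if (is.null(value) || is.na(value)) {
    stop(sprintf(
      "model covariate '%s' (needed by parameter '%s') is missing from the covariate set",
      term$covariate, param_name), call. = FALSE)
  }
  kind <- if (term$kind == "allometric") "power" else term$kind
  out <- switch(kind,
    power = (value / term$ref)^term$exponent,
    hill = value^term$hill / (value^term$hill + term$tm50^term$hill),
    linear = 1 + term$slope * (value - term$ref))
  out
}

#' Evaluate a model's typical structural parameters at given covariates
#'
#' Multiplies each parameter's base typical value by its declared covariate
#' terms.  For the built-in Chung 2023 definition the result matches
#' [chung2023_typical_clearance()] / [chung2023_typical_volume()] exactly.
#'
#' @param model A [poppk_model()].
#' @param cov A [covariate_set()] supplying every covariate the model
#'   references; a missing covariate raises an error naming the symbol.
#' @return An object of class `structural_params`: a named list with
#'   `cl_L_h`, `v_L` and, for two-compartment models, `q_L_h` and `vp_L`.
#' @export
evaluate_model <- function(model, cov) {
  stopifnot(inherits(model, "poppk_model"), inherits(cov, "covariate_set"))
  validate_covariate_set(cov)
  out <- lapply(names(model$params), function(p) {
    spec <- model$params[[p]]
    mult <- 1
    for (term in spec$terms %||% list()) {
      mult <- mult * eval_term(term, cov, p)
    }
    spec$base * mult
  })
  names(out) <- names(model$params)
  bad <- vapply(out, function(v) !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) {
    stop(sprintf("model '%s' produced non-positive or non-finite %s at these covariates",
                 model$name, paste(names(out)[bad], collapse = ", ")),
         call. = FALSE)
  }
  structure(out, class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat("<structural_params>", paste(sprintf("%s=%.4g", names(x),
                                           unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

#' Draw individual structural parameters with lognormal variability
#'
#' Each parameter with a declared inter-individual variance omega^2 is drawn
#' as `typical * exp(eta)` with `eta ~ N(0, omega^2)`; parameters without a
#' declared variance keep their typical values.  Needed by simulation-based
#' diagnostics (VPC) and the synthetic cohort generator.
#'
#' @inheritParams evaluate_model
#' @param seed Optional integer; when given, draws are made under a private
#'   RNG state so the call is reproducible and leaves the session RNG
#'   untouched.
#' @return A `structural_params` object.
#' @export
sample_individual_params <- function(model, cov, seed = NULL) {
  if (is.null(model$iiv) || !length(model$iiv)) {
    stop(paste("model declares no inter-individual variability;",
               "add an 'iiv' spec (zero variances give typical values)"),
         call. = FALSE)
  }
  typ <- evaluate_model(model, cov)
  with_seed(seed, {
    for (p in names(model$iiv)) {
      if (!p %in% names(typ)) next
      typ[[p]] <- typ[[p]] * exp(stats::rnorm(1, 0, sqrt(model$iiv[[p]])))
    }
    typ
  })
}

#' The built-in Chung 2023 neonatal vancomycin model definition
#'
#' Returns the Chung 2023 model expressed in the declarative registry, so the
#' generic [evaluate_model()] path reproduces the dedicated equation
#' functions exactly.  The residual-error form of the original model is not
#' fixed here; supply `residual` (and optionally `iiv`) to configure
#' simulation-based use.
#'
#' @param iiv Named lognormal variances; default 0.1 on both `cl_L_h` and
#'   `v_L`.
#' @param residual Residual error model as in [poppk_model()]; default
#'   additive sd 2 mg/L.
#' @return A [poppk_model()].
#' @examples
#' m <- chung2023_model()
#' evaluate_model(m, covariate_set(1.06, 28.9, scr_umol_L = 56))
#' @export
chung2023_model <- function(iiv = c(cl_L_h = 0.1, v_L = 0.1),
                            residual = list(additive_sd = 2)) {
  poppk_model(
    name = "Chung 2023",
    n_compartments = 1,
    params = list(
      cl_L_h = list(base = 13.9, terms = list(
        list(kind = "power", covariate = "weight_kg", ref = 70, exponent = 1),
        list(kind = "hill", covariate = "pma_weeks", tm50 = 47.7,
             hill = 0.739),
        list(kind = "power", covariate = "scr_umol_L", ref = 34,
             exponent = -0.653))),
      v_L = list(base = 65.5, terms = list(
        list(kind = "power", covariate = "weight_kg", ref = 70,
             exponent = 1)))),
    iiv = iiv,
    residual = residual)
}

#' Read a model definition file
#'
#' Model definitions are YAML documents mirroring the [poppk_model()]
#' arguments: `name`, `n_compartments`, `params` (each with `base` and
#' `terms`), optional `iiv` and `residual`.  A definition of the built-in
#' Chung 2023 model ships with the package:
#' `system.file("extdata/models/chung2023.yaml", package = "neovanc")`.
#'
#' @param path Path to a YAML model definition.
#' @return A [poppk_model()].
#' @export
read_model_def <- function(path) {
  doc <- yaml::read_yaml(path)
  poppk_model(name = doc$name,
              n_compartments = doc$n_compartments %||% 1,
              params = doc$params,
              iiv = unlist(doc$iiv) %||% numeric(),
              residual = doc$residual)
}
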