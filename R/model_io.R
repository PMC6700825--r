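RISK_MODEL_SCHEMA_VERSION <- 1L

#' Bundle the three screening model components
#'
#' @param median A `median_model`.
#' @param prior A `prior_model`.
#' @param gaussian A `gaussian_model`.
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(median, prior, gaussian) {
  stopifnot(inherits(median, "median_model"),
            inherits(prior, "prior_model"),
            inherits(gaussian, "gaussian_model"))
  structure(list(median = median, prior = prior, gaussian = gaussian),
            class = "risk_model")
}

#' Write a risk model to a versioned YAML file
#'
#' All fitted/configured parameters (median formulas, covariate
#' adjustments, prior factor LR tables, group Gaussians) in one
#' human-readable file.
#'
#' @param model A `risk_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  # named atomic vectors must become lists, or YAML drops their names
  yamlify <- function(x) {
    if (is.list(x)) lapply(x, yamlify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  g <- lapply(unclass(model$gaussian), function(f) {
    list(mean = as.list(f$mean), cov = apply(f$cov, 1, as.list), n = f$n)
  })
  obj <- list(
    schema_version = RISK_MODEL_SCHEMA_VERSION,
    median = yamlify(unclass(model$median)),
    prior = yamlify(unclass(model$prior)),
    gaussian = g
  )
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Read a risk model from YAML
#'
#' @param path Path written by [write_risk_model()].
#' @return A `risk_model`.
#' @export
read_risk_model <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema_version) ||
      obj$schema_version != RISK_MODEL_SCHEMA_VERSION) {
    stop("unsupported risk model schema version")
  }
  md <- obj$median
  med <- median_model(
    coef = lapply(md$coef, unlist),
    weight_reference = md$weight_reference,
    weight_slope = unlist(md$weight_slope),
    ethnicity_factors = lapply(md$ethnicity_factors, unlist),
    smoking_factors = unlist(md$smoking_factors),
    ga_window = unlist(md$ga_window)
  )
  pr <- prior_model(
    baseline = unlist(obj$prior$baseline),
    lr = lapply(obj$prior$lr, function(f) lapply(f, unlist))
  )
  gs <- lapply(obj$gaussian, function(f) {
    cv <- do.call(rbind, lapply(f$cov, unlist))
    dimnames(cv) <- list(markers_all, markers_all)
    list(mean = unlist(f$mean), cov = cv, n = f$n)
  })
  class(gs) <- "gaussian_model"
  risk_model(med, pr, gs)
}
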