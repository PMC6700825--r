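markers_all <- c("map", "plgf", "pappa")
markers_adjusted <- c("plgf", "pappa")

#' Construct a median model
#'
#' The expected median of each marker is log10-linear in gestational age
#' (days): `median(ga) = 10^(intercept + slope * ga)`. PLGF and PAPP-A
#' MoM values additionally carry multiplicative covariate adjustments for
#' maternal weight (log-linear in centred weight), ethnicity and smoking;
#' MAP MoM is gestational-age adjusted only.
#'
#' @param coef Named list `map`, `plgf`, `pappa`, each
#'   `c(intercept, slope)` on the log10 scale (per day).
#' @param weight_reference Reference weight (kg) at which the weight
#'   adjustment is neutral.
#' @param weight_slope Named numeric (`plgf`, `pappa`): slope of log10 MoM
#'   per kg of centred weight.
#' @param ethnicity_factors Named list (`plgf`, `pappa`) of named numeric
#'   multiplicative MoM factors per ethnicity; the reference category has
#'   factor 1.
#' @param smoking_factors Named numeric (`plgf`, `pappa`): multiplicative
#'   MoM factor for smokers.
#' @param ga_window Valid screening window in days.
#' @return Object of class `median_model`.
#' @export
median_model <- function(coef,
                         weight_reference = 53,
                         weight_slope = c(plgf = 0, pappa = 0),
                         ethnicity_factors = list(plgf = c(chinese = 1),
                                                  pappa = c(chinese = 1)),
                         smoking_factors = c(plgf = 1, pappa = 1),
                         ga_window = c(77, 97)) {
  stopifnot(all(markers_all %in% names(coef)))
  m <- structure(
    list(
      coef = coef,
      weight_reference = weight_reference,
      weight_slope = weight_slope,
      ethnicity_factors = ethnicity_factors,
      smoking_factors = smoking_factors,
      ga_window = ga_window
    ),
    class = "median_model"
  )
  for (mk in markers_all) {
    if (any(expected_median(m, mk, seq(ga_window[1], ga_window[2])) <= 0)) {
      stop("expected median must be positive over the screening window")
    }
  }
  m
}

#' Default median model
#'
#' Shipped gestational-age median coefficients and covariate adjustments.
#' These are package defaults calibrated so that expected medians at
#' 89 days match the concentration-to-MoM ratios of the study population
#' this package models; they are refittable from any training cohort with
#' [fit_median_model()].
#'
#' @return A `median_model`.
#' @export
default_median_model <- function() {
  median_model(
    coef = list(
      map = c(intercept = 1.89215, slope = 0.0002),
      plgf = c(intercept = 1.01574, slope = 0.0065),
      pappa = c(intercept = 2.21758, slope = 0.0160)
    ),
    weight_reference = 53,
    weight_slope = c(plgf = -0.003, pappa = -0.005),
    ethnicity_factors = list(plgf = c(chinese = 1), pappa = c(chinese = 1)),
    smoking_factors = c(plgf = 1.2, pappa = 0.85)
  )
}

#' Expected marker median at a gestational age
#'
#' @param model A `median_model`.
#' @param marker One of `"map"`, `"plgf"`, `"pappa"`.
#' @param ga_days Gestational age in days, within the model's window.
#' @return Expected median in the marker's units (vectorised over
#'   `ga_days`).
#' @export
expected_median <- function(model, marker, ga_days) {
  stopifnot(inherits(model, "median_model"))
  marker <- match.arg(marker, markers_all)
  w <- model$ga_window
  if (any(ga_days < w[1] | ga_days > w[2])) {
    stop(sprintf("gestational age outside screening window [%g, %g] days",
                 w[1], w[2]))
  }
  cf <- model$coef[[marker]]
  10^(cf[["intercept"]] + cf[["slope"]] * ga_days)
}

#' Multiple of the median
#'
#' @param level Observed marker level (marker units), positive.
#' @param expected Expected median for the same gestational age, positive.
#' @return `level / expected` (dimensionless MoM).
#' @export
compute_mom <- function(level, expected) {
  if (any(level <= 0) || any(expected <= 0)) {
    stop("marker level and expected median must be positive")
  }
  level / expected
}

#' Covariate adjustment of a MoM value
#'
#' Divides a raw MoM by the expected multiplicative shift due to maternal
#' weight, ethnicity and smoking. Only PLGF and PAPP-A are adjusted; MAP
#' MoM is returned unchanged.
#'
#' @param mom Raw MoM, positive (vectorised).
#' @param marker `"map"`, `"plgf"` or `"pappa"`.
#' @param weight_kg Maternal weight (kg).
#' @param ethnicity Ethnicity category; must be present in the model's
#'   factor table.
#' @param smoking Logical.
#' @param model A `median_model`.
#' @return Adjusted MoM.
#' @export
adjust_mom <- function(mom, marker, weight_kg, ethnicity, smoking, model) {
  stopifnot(inherits(model, "median_model"))
  marker <- match.arg(marker, markers_all)
  if (any(mom <= 0)) stop("MoM must be positive")
  if (marker == "map") return(mom)
  eth_tab <- model$ethnicity_factors[[marker]]
  unknown <- setdiff(unique(ethnicity), names(eth_tab))
  if (length(unknown)) {
    stop("unknown ethnicity category: ", paste(unknown, collapse = ", "))
  }
  shift <- 10^(model$weight_slope[[marker]] * (weight_kg - model$weight_reference)) *
    unname(eth_tab[ethnicity]) *
    ifelse(smoking, model$smoking_factors[[marker]], 1)
  mom / shift
}

#' Truncate a log10 MoM value
#'
#' Clamps log10 MoM to configured limits; extreme MoM values would
#' otherwise produce unbounded likelihood ratios.
#'
#' @param value log10 MoM (vectorised).
#' @param limits `c(lo, hi)` with `lo < hi`.
#' @return List with `value` (clamped) and `truncated` (logical flag per
#'   element; boundary-exact values are not flagged).
#' @export
truncate_log_mom <- function(value, limits = c(-1, 1)) {
  if (limits[1] >= limits[2]) stop("truncation limits must satisfy lo < hi")
  clamped <- pmin(pmax(value, limits[1]), limits[2])
  list(value = clamped, truncated = clamped != value)
}

#' Fit a median model from a training cohort
#'
#' Per marker, least-squares fit of log10(level) on gestational age in
#' days. The weight adjustment is then fitted by regressing residual
#' log10 MoM on weight centred at the training median; ethnicity and
#' smoking factors are geometric-mean MoM ratios against the reference
#' category (most frequent ethnicity; non-smokers).
#'
#' @param cohort Cohort `data.frame` (see [cohort_schema()]), typically
#'   restricted to pregnancies unaffected by PE.
#' @param unaffected_only Drop PE cases (by `pe_status` if present, else
#'   by the PE definition applied to outcome columns) before fitting.
#' @return A `median_model`.
#' @export
fit_median_model <- function(cohort, unaffected_only = TRUE) {
  if (unaffected_only) {
    status <- if (!is.null(cohort$pe_status)) cohort$pe_status else
      suppressWarnings(classify_pe(cohort$onset_ga_weeks, cohort$proteinuria,
                                   cohort$ga_delivery_weeks))
    cohort <- cohort[status == "none", , drop = FALSE]
  }
  if (nrow(cohort) < 50) stop("need at least 50 training records")
  if (length(unique(cohort$ga_days)) < 2) {
    stop("degenerate design: a single gestational age in training data")
  }
  level_cols <- c(map = "map_mmHg", plgf = "plgf_pgml", pappa = "pappa_mUL")
  coef <- list()
  resid_log_mom <- list()
  for (mk in markers_all) {
    fit <- stats::lm(log10(cohort[[level_cols[[mk]]]]) ~ cohort$ga_days)
    coef[[mk]] <- c(intercept = unname(stats::coef(fit)[1]),
                    slope = unname(stats::coef(fit)[2]))
    resid_log_mom[[mk]] <- stats::resid(fit)
  }
  ref_weight <- stats::median(cohort$weight_kg)
  eth_levels <- names(sort(table(cohort$ethnicity), decreasing = TRUE))
  w_slope <- c(plgf = 0, pappa = 0)
  eth_factors <- list()
  smk_factors <- c(plgf = 1, pappa = 1)
  for (mk in markers_adjusted) {
    r <- resid_log_mom[[mk]]
    wfit <- stats::lm(r ~ I(cohort$weight_kg - ref_weight))
    w_slope[[mk]] <- unname(stats::coef(wfit)[2])
    r_w <- stats::resid(wfit)
    ref_mean <- mean(r_w[cohort$ethnicity == eth_levels[1]])
    f <- vapply(eth_levels, function(e) {
      10^(mean(r_w[cohort$ethnicity == e]) - ref_mean)
    }, numeric(1))
    f[eth_levels[1]] <- 1
    eth_factors[[mk]] <- f
    smk_factors[[mk]] <- if (any(cohort$smoking) && any(!cohort$smoking)) {
      10^(mean(r_w[cohort$smoking]) - mean(r_w[!cohort$smoking]))
    } else 1
  }
  median_model(
    coef = coef,
    weight_reference = ref_weight,
    weight_slope = w_slope,
    ethnicity_factors = eth_factors,
    smoking_factors = smk_factors,
    ga_window = c(77, 97)
  )
}

#' Compute the adjusted, truncated MoM panel of a cohort
#'
#' Raw MoM = level / expected median at the subject's gestational age;
#' PLGF and PAPP-A are covariate-adjusted ([adjust_mom()]); log10 MoM is
#' truncated to `limits`.
#'
#' @param cohort Cohort `data.frame`.
#' @param model A `median_model`.
#' @param limits log10 MoM truncation limits.
#' @return `data.frame` with columns `mom_map`, `mom_plgf`, `mom_pappa`,
#'   their `log10_*` counterparts, and `trunc_*` flags.
#' @export
compute_mom_panel <- function(cohort, model = default_median_model(),
                              limits = c(-1, 1)) {
  level_cols <- c(map = "map_mmHg", plgf = "plgf_pgml", pappa = "pappa_mUL")
  out <- data.frame(row.names = seq_len(nrow(cohort)))
  for (mk in markers_all) {
    raw <- compute_mom(cohort[[level_cols[[mk]]]],
                       expected_median(model, mk, cohort$ga_days))
    adj <- adjust_mom(raw, mk, cohort$weight_kg, cohort$ethnicity,
                      cohort$smoking, model)
    tr <- truncate_log_mom(log10(adj), limits)
    out[[paste0("mom_", mk)]] <- 10^tr$value
    out[[paste0("log10_", mk)]] <- tr$value
    out[[paste0("trunc_", mk)]] <- tr$truncated
  }
  out
}

#' log10 MoM matrix from a MoM panel
#'
#' @param panel Output of [compute_mom_panel()].
#' @return Numeric matrix with columns `map`, `plgf`, `pappa`.
#' @export
log_mom_matrix <- function(panel) {
  m <- as.matrix(panel[paste0("log10_", markers_all)])
  colnames(m) <- markers_all
  m
}
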