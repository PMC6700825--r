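#' BMI band used by the prior-risk factor table
#'
#' @param bmi BMI in kg/m^2.
#' @return Character vector in `"<25"`, `"25-30"`, `">=30"`.
#' @export
bmi_band <- function(bmi) {
  ifelse(bmi < 25, "<25", ifelse(bmi < 30, "25-30", ">=30"))
}

#' Construct a prior-risk model
#'
#' Prior risk is computed from baseline odds multiplied by positive
#' likelihood ratios for five maternal risk factors: BMI band, ethnicity,
#' parity, history of PE, and chronic hypertension. Each factor table
#' carries separate LRs for the early and late horizon; reference levels
#' have LR 1.
#'
#' @param baseline Named numeric `c(early = , late = )`, baseline
#'   (reference-level) risk probabilities in (0, 1).
#' @param lr Named list of factors (`bmi`, `ethnicity`, `parity`,
#'   `prior_pe`, `chronic_htn`); each factor is a list with `early` and
#'   `late` named numeric vectors of LRs per level.
#' @return Object of class `prior_model`.
#' @export
prior_model <- function(baseline, lr) {
  stopifnot(all(c("early", "late") %in% names(baseline)),
            all(baseline > 0 & baseline < 1))
  for (f in lr) {
    stopifnot(all(c("early", "late") %in% names(f)))
    if (any(unlist(f[c("early", "late")]) <= 0)) stop("all LRs must be positive")
  }
  structure(list(baseline = baseline, lr = lr), class = "prior_model")
}

#' Default prior-risk model
#'
#' Shipped placeholder factor likelihood ratios, with baseline risks set
#' so the population-average prior over the default synthetic cohort's
#' characteristic mix approximates incidences of 0.24% (early) and 1.07%
#' (late). These are refittable configuration values, not vendor
#' parameters.
#'
#' @return A `prior_model`.
#' @export
default_prior_model <- function() {
  prior_model(
    baseline = c(early = 0.00165, late = 0.00843),
    lr = list(
      bmi = list(
        early = c("<25" = 1, "25-30" = 1.7, ">=30" = 2.8),
        late = c("<25" = 1, "25-30" = 1.6, ">=30" = 2.4)
      ),
      ethnicity = list(
        early = c(chinese = 1),
        late = c(chinese = 1)
      ),
      parity = list(
        early = c(parous = 1, nulliparous = 1.6),
        late = c(parous = 1, nulliparous = 1.3)
      ),
      prior_pe = list(
        early = c("FALSE" = 1, "TRUE" = 5),
        late = c("FALSE" = 1, "TRUE" = 4)
      ),
      chronic_htn = list(
        early = c("FALSE" = 1, "TRUE" = 8),
        late = c("FALSE" = 1, "TRUE" = 6)
      )
    )
  )
}

lookup_lr <- function(tab, level, factor_name) {
  miss <- setdiff(unique(as.character(level)), names(tab))
  if (length(miss)) {
    stop(sprintf("no %s likelihood ratio for level(s): %s",
                 factor_name, paste(miss, collapse = ", ")))
  }
  unname(tab[as.character(level)])
}

#' Prior risk from maternal characteristics
#'
#' Posterior odds = baseline odds x product of the five factor
#' likelihood ratios; returned as a probability.
#'
#' @param record Cohort `data.frame` (needs `bmi`, `ethnicity`, `parity`,
#'   `prior_pe`, `chronic_htn`), or a one-row list with those fields.
#' @param model A `prior_model`.
#' @param horizon `"early"` or `"late"`.
#' @return Risk probabilities in (0, 1), one per record.
#' @export
prior_risk <- function(record, model = default_prior_model(),
                       horizon = c("early", "late")) {
  stopifnot(inherits(model, "prior_model"))
  h <- match.arg(horizon)
  p0 <- model$baseline[[h]]
  lr <- lookup_lr(model$lr$bmi[[h]], bmi_band(record$bmi), "BMI band") *
    lookup_lr(model$lr$ethnicity[[h]], record$ethnicity, "ethnicity") *
    lookup_lr(model$lr$parity[[h]], record$parity, "parity") *
    lookup_lr(model$lr$prior_pe[[h]], record$prior_pe, "PE history") *
    lookup_lr(model$lr$chronic_htn[[h]], record$chronic_htn, "chronic hypertension")
  odds <- p0 / (1 - p0) * lr
  odds / (1 + odds)
}

#' Fit the multivariate-Gaussian marker model
#'
#' Group-wise sample mean vector and covariance matrix of the log10 MoM
#' triple (MAP, PLGF, PAPP-A) for the unaffected, early-PE and late-PE
#' hypotheses.
#'
#' @param log_mom Numeric matrix of log10 MoM, columns `map`, `plgf`,
#'   `pappa` (see [log_mom_matrix()]).
#' @param group Factor/character per row: `"unaffected"`, `"early"`, or
#'   `"late"`; groups absent from the data are left out of the model.
#' @param pooled Use the pooled (within-group) covariance for every group.
#' @param diagonal Force off-diagonal covariance entries to zero.
#' @return Object of class `gaussian_model`: list of per-group
#'   `list(mean, cov, n)`.
#' @export
fit_gaussian_model <- function(log_mom, group, pooled = FALSE, diagonal = FALSE) {
  stopifnot(is.matrix(log_mom), ncol(log_mom) == 3)
  group <- as.character(group)
  groups <- intersect(c("unaffected", "early", "late"), unique(group))
  if (!length(groups)) stop("no recognised hypothesis groups in 'group'")
  fits <- list()
  for (g in groups) {
    x <- log_mom[group == g, , drop = FALSE]
    if (nrow(x) < 2) stop("need at least 2 records per hypothesis group (", g, ")")
    fits[[g]] <- list(mean = colMeans(x), cov = stats::cov(x), n = nrow(x))
  }
  if (pooled) {
    ns <- vapply(fits, `[[`, numeric(1), "n")
    pc <- Reduce(`+`, Map(function(f) (f$n - 1) * f$cov, fits)) / (sum(ns) - length(ns))
    for (g in groups) fits[[g]]$cov <- pc
  }
  for (g in groups) {
    if (diagonal) fits[[g]]$cov <- diag(diag(fits[[g]]$cov), ncol(log_mom))
    ev <- eigen(fits[[g]]$cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12 * max(abs(ev))) {
      warning("near-singular covariance for group '", g,
              "': falling back to diagonal")
      fits[[g]]$cov <- diag(pmax(diag(fits[[g]]$cov), 1e-12), ncol(log_mom))
    }
    dimnames(fits[[g]]$cov) <- list(colnames(log_mom), colnames(log_mom))
  }
  structure(fits, class = "gaussian_model")
}

# log multivariate normal density via Cholesky (numerically stable)
log_dmvnorm <- function(x, mean, cov) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  k <- ncol(x)
  R <- tryCatch(chol(cov), error = function(e) {
    stop("covariance matrix is not positive definite")
  })
  centered <- sweep(x, 2, mean)
  z <- backsolve(R, t(centered), transpose = TRUE)
  -0.5 * k * log(2 * pi) - sum(log(diag(R))) - 0.5 * colSums(z^2)
}

#' Marker likelihood ratio
#'
#' Ratio of the multivariate-Gaussian densities of the observed log10 MoM
#' vector under the affected versus the unaffected hypothesis, computed
#' in log space.
#'
#' @param x log10 MoM vector, or matrix with one row per pregnancy.
#' @param affected,unaffected Group slices `list(mean, cov)` as stored in
#'   a [fit_gaussian_model()] result.
#' @return Likelihood ratio(s), positive.
#' @export
marker_lr <- function(x, affected, unaffected) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == length(affected$mean),
            ncol(x) == length(unaffected$mean))
  exp(log_dmvnorm(x, affected$mean, affected$cov) -
        log_dmvnorm(x, unaffected$mean, unaffected$cov))
}

#' Posterior risk from prior and likelihood ratio
#'
#' @param prior Prior probability in (0, 1).
#' @param lr Positive likelihood ratio.
#' @return Posterior probability (vectorised).
#' @export
posterior_risk <- function(prior, lr) {
  if (any(prior <= 0 | prior >= 1)) stop("prior must be in (0, 1)")
  if (any(lr <= 0)) stop("likelihood ratio must be positive")
  odds <- prior / (1 - prior) * lr
  odds / (1 + odds)
}

#' Format a risk probability as "1 in N"
#'
#' @param p Probability in (0, 1).
#' @return Character vector, `N = round(1/p)` (at least 1).
#' @export
format_risk <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  sprintf("1 in %.0f", pmax(1, round(1 / p)))
}

#' Screen-positive decision at a "1:N" cutoff
#'
#' Positive when the risk probability is at or above `1/cutoff_n`
#' (boundary inclusive).
#'
#' @param p Risk probability.
#' @param cutoff_n Integer N of the "1:N" cutoff (default 20, the
#'   conventional program default).
#' @return Logical vector.
#' @export
screen_positive <- function(p, cutoff_n = 20) {
  stopifnot(cutoff_n >= 1)
  p >= 1 / cutoff_n
}

#' Score a cohort: prior and posterior early/late PE risks
#'
#' Runs the four-step workflow per pregnancy: prior risk from maternal
#' characteristics, marker likelihood ratio from the adjusted log10 MoM
#' triple under the corresponding hypothesis pair, posterior risk by
#' combining the two on the odds scale. Early and late risks are two
#' independent binary problems.
#'
#' @param cohort Cohort `data.frame` with derived `bmi` column.
#' @param panel MoM panel from [compute_mom_panel()].
#' @param prior A `prior_model`.
#' @param gaussian A `gaussian_model` with an `unaffected` slice and at
#'   least one of `early`/`late`.
#' @return `data.frame`: `id`, `prior_early`, `prior_late`,
#'   `posterior_early`, `posterior_late`, formatted `risk_early`,
#'   `risk_late`.
#' @export
score_cohort <- function(cohort, panel, prior = default_prior_model(),
                         gaussian) {
  stopifnot(inherits(gaussian, "gaussian_model"))
  if (is.null(gaussian$unaffected)) stop("gaussian model lacks the unaffected group")
  x <- log_mom_matrix(panel)
  out <- data.frame(id = cohort$id, stringsAsFactors = FALSE)
  for (h in c("early", "late")) {
    pr <- prior_risk(cohort, prior, h)
    out[[paste0("prior_", h)]] <- pr
    if (is.null(gaussian[[h]])) {
      out[[paste0("posterior_", h)]] <- NA_real_
      next
    }
    # floor against density underflow far in the unaffected tail, where
    # the LR is indistinguishable from zero at double precision
    lr <- pmax(marker_lr(x, gaussian[[h]], gaussian$unaffected), 1e-300)
    post <- posterior_risk(pr, lr)
    out[[paste0("posterior_", h)]] <- post
    out[[paste0("risk_", h)]] <- format_risk(post)
  }
  out
}
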