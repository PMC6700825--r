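#' Empirical ROC curve and AUC
#'
#' The AUC is computed from the rank (Mann-Whitney) statistic with the
#' usual half-credit for ties, which equals the trapezoidal area under
#' the empirical ROC curve. The 95% confidence interval uses DeLong's
#' variance estimate (via pROC).
#'
#' @param scores Numeric risk scores (higher = more suspicious).
#' @param labels Logical (or 0/1) outcome per subject.
#' @param conf Confidence level for the AUC interval.
#' @param ci Compute the DeLong interval (disable for speed in tight loops).
#' @return Object of class `roc_result`: `thresholds` (decreasing, first
#'   is `Inf`), `sensitivity`, `specificity`, `auc`, `auc_ci`.
#' @export
roc_auc <- function(scores, labels, conf = 0.95, ci = TRUE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) sum(scores[labels] >= t), numeric(1)) / n1
  spec <- vapply(thr, function(t) sum(scores[!labels] < t), numeric(1)) / n0
  auc_ci <- c(NA_real_, NA_real_)
  if (ci) {
    ci_v <- suppressMessages(pROC::ci.auc(
      response = labels, predictor = scores,
      levels = c(FALSE, TRUE), direction = "<",
      conf.level = conf, method = "delong", quiet = TRUE
    ))
    auc_ci <- as.numeric(ci_v[c(1, 3)])
  }
  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, auc_ci = auc_ci),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (95%% CI %.3f-%.3f), %d thresholds\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], length(x$thresholds)))
  invisible(x)
}

#' Paired comparison of two AUCs (DeLong test)
#'
#' @param scores_a,scores_b Two score vectors over the same subjects.
#' @param labels Logical outcome per subject.
#' @return List `delta` (AUC_a - AUC_b) and `p` (two-sided).
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have equal length")
  }
  auc_a <- roc_auc(scores_a, labels, ci = FALSE)$auc
  auc_b <- roc_auc(scores_b, labels, ci = FALSE)$auc
  if (identical(scores_a, scores_b)) {
    return(list(delta = 0, p = 1))
  }
  ra <- suppressMessages(pROC::roc(labels, scores_a,
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE))
  rb <- suppressMessages(pROC::roc(labels, scores_b,
                                   levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(delta = auc_a - auc_b, p = unname(tst$p.value))
}

#' Optimal cutoff at the highest average of sensitivity and specificity
#'
#' Ties are broken toward the lower false-positive rate.
#'
#' @param roc A `roc_result`.
#' @return List `threshold`, `dr` (sensitivity, %), `fpr` (%).
#' @export
best_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  avg <- (roc$sensitivity + roc$specificity) / 2
  best <- which(abs(avg - max(avg)) < 1e-12)
  fpr <- 1 - roc$specificity
  best <- best[which.min(fpr[best])]
  list(
    threshold = roc$thresholds[best],
    dr = 100 * roc$sensitivity[best],
    fpr = 100 * fpr[best]
  )
}

#' Detection rate at a fixed false-positive rate
#'
#' The operating threshold is the smallest score threshold whose
#' empirical FPR among unaffected subjects does not exceed the target (no
#' interpolation); subjects with scores at or above the threshold are
#' screen-positive.
#'
#' @param scores Risk scores.
#' @param labels Logical outcome.
#' @param target_fpr Target FPR in percent, in (0, 100].
#' @return List `threshold`, `dr` (%), `ppv` (%), `fpr` (achieved, %).
#' @export
dr_at_fpr <- function(scores, labels, target_fpr) {
  labels <- as.logical(labels)
  if (target_fpr <= 0 || target_fpr > 100) {
    stop("target FPR must be in (0, 100] percent")
  }
  neg <- scores[!labels]
  pos <- scores[labels]
  if (!length(neg) || !length(pos)) stop("both classes must be present")
  cand <- c(sort(unique(scores)), Inf)
  fprs <- vapply(cand, function(t) mean(neg >= t), numeric(1))
  ok <- which(fprs <= target_fpr / 100)
  thr <- cand[ok[1]]
  tp <- sum(pos >= thr)
  fp <- sum(neg >= thr)
  list(
    threshold = thr,
    dr = 100 * tp / length(pos),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    fpr = 100 * fp / length(neg)
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile formulation: `lo = qbeta(a/2, x, n - x + 1)`,
#' `hi = qbeta(1 - a/2, x + 1, n - x)`, with lo = 0 at x = 0 and
#' hi = 100% at x = n.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param conf Confidence level.
#' @return `c(lo, hi)` in percent.
#' @export
clopper_pearson <- function(successes, n, conf = 0.95) {
  if (n < 1 || successes < 0 || successes > n) stop("invalid counts")
  a <- 1 - conf
  lo <- if (successes == 0) 0 else stats::qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lo = 100 * lo, hi = 100 * hi)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test; exact enumeration when `n_a * n_b <= 400` and
#' there are no ties, normal approximation with tie correction otherwise.
#'
#' @param group_a,group_b Numeric vectors, nonempty.
#' @return List `U` (statistic for group a) and `p`.
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("both groups must be nonempty")
  exact <- length(group_a) * length(group_b) <= 400
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p = unname(wt$p.value))
}

#' Marker summary by outcome group
#'
#' Median and IQR of each adjusted MoM per PE and SGA subgroup, with
#' Mann-Whitney p-values versus the corresponding unaffected group.
#'
#' @param cohort Cohort `data.frame` with `pe_status` and `sga` columns.
#' @param panel MoM panel aligned with `cohort` rows.
#' @return `data.frame`: `group`, `n`, `marker`, `median`, `q1`, `q3`,
#'   `p_vs_unaffected`. Empty groups yield `n = 0` rows without a test.
#' @export
summarize_group_moms <- function(cohort, panel) {
  pe <- cohort$pe_status
  sga <- cohort$sga
  groups <- list(
    "Unaffected by PE" = list(idx = pe == "none", ref = NULL),
    "PE" = list(idx = pe != "none", ref = "Unaffected by PE"),
    "Early PE" = list(idx = pe == "early", ref = "Unaffected by PE"),
    "Late PE" = list(idx = pe == "late", ref = "Unaffected by PE"),
    "PE with SGA" = list(idx = pe != "none" & sga, ref = "Unaffected by PE"),
    "Unaffected by SGA" = list(idx = !sga, ref = NULL),
    "SGA" = list(idx = sga, ref = "Unaffected by SGA"),
    "SGA without PE" = list(idx = sga & pe == "none", ref = "Unaffected by SGA")
  )
  rows <- list()
  for (gname in names(groups)) {
    idx <- groups[[gname]]$idx
    ref <- groups[[gname]]$ref
    for (mk in markers_all) {
      v <- panel[[paste0("mom_", mk)]][idx]
      if (!length(v)) {
        rows[[length(rows) + 1L]] <- data.frame(
          group = gname, n = 0L, marker = mk, median = NA_real_,
          q1 = NA_real_, q3 = NA_real_, p_vs_unaffected = NA_real_
        )
        next
      }
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      p <- NA_real_
      if (!is.null(ref)) {
        vref <- panel[[paste0("mom_", mk)]][groups[[ref]]$idx]
        if (length(vref)) p <- mann_whitney(v, vref)$p
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, n = sum(idx), marker = mk, median = q[2],
        q1 = q[1], q3 = q[3], p_vs_unaffected = p
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fixed-FPR screening performance table
#'
#' For each target FPR the operating threshold is set on the full
#' unaffected population ([dr_at_fpr()] convention); detection rates with
#' exact binomial CIs are then reported per subgroup of affected
#' pregnancies, and PPV is computed against the false positives of the
#' whole unaffected population.
#'
#' @param scores Risk scores (probabilities).
#' @param affected Logical, the outcome defining "affected" (e.g. early
#'   PE) used to set the threshold.
#' @param subgroups Named list of logical vectors (subsets of subjects)
#'   whose detection rates are reported.
#' @param target_fprs Target FPRs in percent.
#' @param conf Confidence level for the exact intervals.
#' @return `data.frame` with one row per subgroup x FPR: `fpr_target`,
#'   `cutoff` ("1:N" when thresholds are probabilities), `subgroup`, `n`,
#'   `dr`, `dr_lo`, `dr_hi`, `ppv`, `ppv_lo`, `ppv_hi` (all %).
#' @export
performance_table <- function(scores, affected, subgroups,
                              target_fprs = c(5, 10, 15), conf = 0.95) {
  affected <- as.logical(affected)
  rows <- list()
  for (f in target_fprs) {
    op <- dr_at_fpr(scores, affected, f)
    thr <- op$threshold
    cutoff <- if (is.finite(thr) && thr > 0 && thr < 1) {
      sprintf("1:%d", as.integer(round(1 / thr)))
    } else NA_character_
    fp <- sum(scores[!affected] >= thr)
    for (sname in names(subgroups)) {
      idx <- subgroups[[sname]]
      n <- sum(idx)
      tp <- sum(scores[idx] >= thr)
      dr_ci <- if (n > 0) clopper_pearson(tp, n, conf) else c(NA_real_, NA_real_)
      ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
      ppv_ci <- if (tp + fp > 0) clopper_pearson(tp, tp + fp, conf) else c(NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        fpr_target = f, cutoff = cutoff, subgroup = sname, n = n,
        dr = if (n > 0) 100 * tp / n else NA_real_,
        dr_lo = dr_ci[1], dr_hi = dr_ci[2],
        ppv = ppv, ppv_lo = ppv_ci[1], ppv_hi = ppv_ci[2]
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
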