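# Independent brute-force oracles used across test files. These stay
# deliberately naive (O(n^2) scans, direct density formulas) so they are
# independent of the implementation paths they check.

bf_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

bf_dmvnorm <- function(x, mean, cov) {
  k <- length(mean)
  d <- x - mean
  (2 * pi)^(-k / 2) * det(cov)^(-1 / 2) *
    exp(-0.5 * drop(t(d) %*% solve(cov) %*% d))
}

bf_best_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- c(Inf, sort(unique(scores), decreasing = TRUE))
  best <- NULL
  for (t in cand) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    avg <- (sens + spec) / 2
    if (is.null(best) || avg > best$avg + 1e-12 ||
        (abs(avg - best$avg) <= 1e-12 && 100 * (1 - spec) < best$fpr - 1e-12)) {
      best <- list(threshold = t, avg = avg, dr = 100 * sens, fpr = 100 * (1 - spec))
    }
  }
  best
}

bf_dr_at_fpr <- function(scores, labels, target) {
  labels <- as.logical(labels)
  for (t in c(sort(unique(scores)), Inf)) {
    if (mean(scores[!labels] >= t) <= target / 100) {
      return(list(threshold = t, dr = 100 * mean(scores[labels] >= t)))
    }
  }
}

random_pd_cov <- function(k) {
  a <- matrix(rnorm(k * k), k)
  crossprod(a) / k + diag(0.05, k)
}

# A small but feasible generator configuration for fast end-to-end tests.
small_config <- function(n_total = 300L) {
  cfg <- default_generator_config()
  cfg$n_total <- n_total
  cfg$counts <- list(early_pe = 4L, late_pe = 8L, early_pe_sga = 2L,
                     late_pe_sga = 3L, sga_without_pe = 10L)
  cfg
}

pe_group_labels <- function(cohort) {
  c(none = "unaffected", early = "early", late = "late")[as.character(cohort$pe_status)]
}
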