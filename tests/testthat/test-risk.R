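ref_record <- function(...) {
  rec <- list(bmi = 21, ethnicity = "chinese", parity = "parous",
              prior_pe = FALSE, chronic_htn = FALSE)
  mod <- list(...)
  rec[names(mod)] <- mod
  as.data.frame(rec, stringsAsFactors = FALSE)
}

test_that("prior risk is baseline odds times factor likelihood ratios", {
  m <- default_prior_model()
  # all reference levels: baseline risk exactly
  expect_equal(prior_risk(ref_record(), m, "early"),
               unname(m$baseline["early"]))
  expect_equal(prior_risk(ref_record(), m, "late"),
               unname(m$baseline["late"]))
  # hand odds arithmetic: baseline 1/100, single factor LR 10 -> 10/109
  m2 <- prior_model(
    baseline = c(early = 0.01, late = 0.01),
    lr = list(
      bmi = list(early = c("<25" = 1, "25-30" = 1, ">=30" = 1),
                 late = c("<25" = 1, "25-30" = 1, ">=30" = 1)),
      ethnicity = list(early = c(chinese = 1), late = c(chinese = 1)),
      parity = list(early = c(parous = 1, nulliparous = 1),
                    late = c(parous = 1, nulliparous = 1)),
      prior_pe = list(early = c("FALSE" = 1, "TRUE" = 1),
                      late = c("FALSE" = 1, "TRUE" = 1)),
      chronic_htn = list(early = c("FALSE" = 1, "TRUE" = 10),
                         late = c("FALSE" = 1, "TRUE" = 10))
    )
  )
  expect_equal(prior_risk(ref_record(chronic_htn = TRUE), m2, "early"), 10 / 109)
  # risk increases with each adverse factor level
  expect_gt(prior_risk(ref_record(bmi = 31), m, "early"),
            prior_risk(ref_record(bmi = 27), m, "early"))
  expect_gt(prior_risk(ref_record(bmi = 27), m, "early"),
            prior_risk(ref_record(), m, "early"))
  expect_error(prior_risk(ref_record(ethnicity = "unknown"), m, "early"), "ethnicity")
})

test_that("BMI banding splits at 25 and 30", {
  expect_equal(bmi_band(c(24.99, 25, 29.99, 30, 35)),
               c("<25", "25-30", "25-30", ">=30", ">=30"))
})

test_that("Gaussian model fitting recovers generating parameters", {
  set.seed(99)
  n <- 5000
  mu_u <- c(map = -0.013, plgf = 0.045, pappa = -0.032)
  mu_a <- c(map = 0.053, plgf = -0.143, pappa = -0.310)
  sd_u <- c(0.047, 0.20, 0.21)
  cor_up <- 0.3
  R <- diag(3); R[1, 2] <- R[2, 1] <- cor_up
  S_u <- diag(sd_u) %*% R %*% diag(sd_u)
  draw <- function(n, mu, S) {
    z <- matrix(rnorm(n * 3), ncol = 3) %*% chol(S)
    sweep(z, 2, mu, `+`)
  }
  x <- rbind(draw(n, mu_u, S_u), draw(n, mu_a, S_u))
  colnames(x) <- c("map", "plgf", "pappa")
  grp <- rep(c("unaffected", "early"), each = n)
  fit <- fit_gaussian_model(x, grp)
  expect_lt(max(abs(fit$unaffected$mean - mu_u)), 0.012)
  expect_lt(max(abs(fit$early$mean - mu_a)), 0.012)
  expect_lt(max(abs(fit$unaffected$cov - S_u)), 0.01)

  # identical groups give equal means
  x2 <- rbind(x[1:n, ], x[1:n, ])
  fit2 <- fit_gaussian_model(x2, grp)
  expect_equal(fit2$unaffected$mean, fit2$early$mean)

  # diagonal mode zeroes off-diagonals exactly
  fitd <- fit_gaussian_model(x, grp, diagonal = TRUE)
  offd <- fitd$unaffected$cov[upper.tri(fitd$unaffected$cov)]
  expect_true(all(offd == 0))

  # pooled mode shares one covariance
  fitp <- fit_gaussian_model(x, grp, pooled = TRUE)
  expect_equal(fitp$unaffected$cov, fitp$early$cov)

  # singular covariance falls back to diagonal with a warning
  xs <- x
  xs[, 2] <- xs[, 1]  # perfectly collinear, singular in both groups
  w <- capture_warnings(fits <- fit_gaussian_model(xs, grp))
  expect_true(any(grepl("singular", w)))
  expect_true(all(fits$unaffected$cov[upper.tri(fits$unaffected$cov)] == 0))

  expect_error(fit_gaussian_model(x[1, , drop = FALSE], "early"), "at least 2")
})

test_that("marker LR equals the ratio of Gaussian densities", {
  # identical hypotheses: LR 1 everywhere
  g <- list(mean = c(0, 0, 0), cov = diag(0.04, 3))
  for (i in 1:5) {
    x <- rnorm(3, 0, 0.3)
    expect_equal(unname(marker_lr(x, g, g)), 1)
  }
  # 1-D density-ratio oracle: mu_a = -0.14, mu_u = 0.05, sd = 0.2 at x = -0.14
  a1 <- list(mean = -0.14, cov = matrix(0.04))
  u1 <- list(mean = 0.05, cov = matrix(0.04))
  expect_equal(unname(marker_lr(matrix(-0.14), a1, u1)),
               exp(0.19^2 / (2 * 0.04)), tolerance = 1e-12)
  expect_lt(abs(marker_lr(matrix(-0.14), a1, u1) - 1.57), 0.005)
  # LR monotone decreasing in x when mu_a < mu_u with shared variance
  xs <- matrix(seq(-0.5, 0.5, length.out = 21))
  lrs <- marker_lr(xs, a1, u1)
  expect_true(all(diff(lrs) < 0))
})

test_that("marker LR matches brute-force density evaluation to 1e-10 relative", {
  set.seed(7)
  for (i in 1:200) {
    aff <- list(mean = rnorm(3, 0, 0.3), cov = random_pd_cov(3))
    una <- list(mean = rnorm(3, 0, 0.3), cov = random_pd_cov(3))
    x <- rnorm(3, 0, 0.5)
    got <- unname(marker_lr(x, aff, una))
    want <- bf_dmvnorm(x, aff$mean, aff$cov) / bf_dmvnorm(x, una$mean, una$cov)
    expect_lt(abs(got - want) / abs(want), 1e-10)
  }
  bad <- list(mean = c(0, 0, 0), cov = matrix(-1, 3, 3))
  expect_error(marker_lr(c(0, 0, 0), bad, bad), "positive definite")
})

test_that("posterior risk combines prior and LR on the odds scale", {
  expect_equal(posterior_risk(0.3, 1), 0.3)       # LR 1 leaves the prior
  expect_equal(posterior_risk(0.5, 3), 0.75)
  expect_error(posterior_risk(0, 2), "prior")
  expect_error(posterior_risk(0.5, -1), "positive")
  # composition: sequential updating equals a single update with the product
  set.seed(1)
  for (i in 1:50) {
    p <- runif(1, 0.001, 0.999)
    a <- exp(rnorm(1)); b <- exp(rnorm(1))
    expect_equal(posterior_risk(posterior_risk(p, a), b),
                 posterior_risk(p, a * b), tolerance = 1e-12)
  }
})

test_that("risk formatting and cutoff decisions", {
  expect_equal(format_risk(1 / 45), "1 in 45")
  expect_equal(format_risk(0.5), "1 in 2")
  expect_equal(format_risk(1e-12), "1 in 1000000000000")
  expect_true(screen_positive(0.05, 20))    # boundary inclusive
  expect_false(screen_positive(0.049, 20))
  expect_true(screen_positive(0.3, 20))
})

test_that("posterior probabilities are calibrated on model-generated data", {
  set.seed(123)
  n <- 20000
  prev <- 0.1
  aff <- list(mean = c(0.05, -0.14, -0.28), cov = diag(c(0.03, 0.2, 0.3)^2))
  una <- list(mean = c(-0.01, 0.05, -0.03), cov = diag(c(0.05, 0.2, 0.21)^2))
  lab <- runif(n) < prev
  x <- matrix(NA_real_, n, 3)
  draw <- function(n, g) sweep(matrix(rnorm(n * 3), ncol = 3) %*% chol(g$cov), 2, g$mean, `+`)
  x[lab, ] <- draw(sum(lab), aff)
  x[!lab, ] <- draw(sum(!lab), una)
  post <- posterior_risk(prev, marker_lr(x, aff, una))
  expect_lt(abs(mean(post) - prev), 0.01)
})

test_that("posterior risk moves with each marker in the clinically expected direction", {
  co <- generate_cohort(enriched_config(400L, 2000L), seed = 2)
  panel <- compute_mom_panel(co)
  g <- fit_gaussian_model(log_mom_matrix(panel), pe_group_labels(co))
  base <- c(map = 0, plgf = 0, pappa = 0)
  post_at <- function(x) posterior_risk(0.01, unname(marker_lr(rbind(x), g$early, g$unaffected)))
  for (mk in c("map", "plgf", "pappa")) {
    lo <- base; hi <- base
    lo[mk] <- -0.05; hi[mk] <- 0.05
    if (mk == "map") {
      expect_gt(post_at(hi), post_at(lo))   # higher MAP MoM raises risk
    } else {
      expect_lt(post_at(hi), post_at(lo))   # higher PLGF/PAPP-A MoM lowers risk
    }
  }
})

test_that("score_cohort produces the per-pregnancy risk table", {
  co <- generate_cohort(small_config(300L), seed = 8)
  panel <- compute_mom_panel(co)
  g <- fit_gaussian_model(log_mom_matrix(panel), pe_group_labels(co))
  risks <- score_cohort(co, panel, default_prior_model(), g)
  expect_equal(nrow(risks), nrow(co))
  expect_true(all(risks$posterior_early > 0 & risks$posterior_early < 1))
  expect_true(all(risks$posterior_late > 0 & risks$posterior_late < 1))
  expect_match(risks$risk_early[1], "^1 in \\d+$")
  # PE cases should rank higher than average on their own horizon
  expect_gt(mean(risks$posterior_early[co$pe_status == "early"]),
            mean(risks$posterior_early[co$pe_status == "none"]))
})
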