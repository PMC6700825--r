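test_that("AUC matches hand-checked and degenerate cases", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3),
                       ci = FALSE)$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5), ci = FALSE)$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE),
                       ci = FALSE)$auc, 0.75)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("AUC equals the concordant-pair fraction on random instances", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)          # both classes present
    expect_equal(roc_auc(scores, labels, ci = FALSE)$auc, bf_auc(scores, labels))
  }
})

test_that("AUC and DeLong CI agree with the pROC reference", {
  set.seed(5)
  scores <- c(rnorm(150, 1), rnorm(150))
  labels <- rep(c(TRUE, FALSE), each = 150)
  r <- roc_auc(scores, labels)
  pr <- suppressMessages(pROC::roc(labels, scores, levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
  expect_true(r$auc_ci[1] < r$auc && r$auc < r$auc_ci[2])
  # ROC curve invariants
  expect_true(all(diff(r$sensitivity) >= 0))          # thresholds decrease
  expect_true(all(diff(r$specificity) <= 0))
  expect_true(all(r$sensitivity >= 0 & r$sensitivity <= 1))
})

test_that("paired AUC comparison behaves like a DeLong test", {
  set.seed(17)
  labels <- c(rep(TRUE, 100), rep(FALSE, 400))
  good <- c(rnorm(100, 1.5), rnorm(400))
  noise <- rnorm(500)
  same <- compare_auc(good, good, labels)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  cmp <- compare_auc(good, noise, labels)
  expect_lt(cmp$p, 0.05)
  expect_gt(cmp$delta, 0)
  # antisymmetry
  rev <- compare_auc(noise, good, labels)
  expect_equal(rev$delta, -cmp$delta)
  expect_equal(rev$p, cmp$p, tolerance = 1e-9)
  expect_error(compare_auc(good[-1], noise, labels), "equal length")
})

test_that("best cutoff maximises mean of sensitivity and specificity", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c(FALSE, TRUE), each = 3)
  bc <- best_cutoff(roc_auc(scores, labels, ci = FALSE))
  expect_equal(bc$dr, 100)
  expect_equal(bc$fpr, 0)
  set.seed(23)
  for (i in 1:200) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.4)
    got <- best_cutoff(roc_auc(scores, labels, ci = FALSE))
    want <- bf_best_cutoff(scores, labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$dr, want$dr)
    expect_equal(got$fpr, want$fpr)
  }
  # engineered tie: two thresholds with equal average, lower FPR wins
  scores <- c(0.9, 0.8, 0.2, 0.1)
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  bc <- best_cutoff(roc_auc(scores, labels, ci = FALSE))
  want <- bf_best_cutoff(scores, labels)
  expect_equal(bc$threshold, want$threshold)
  expect_equal(bc$fpr, want$fpr)
})

test_that("fixed-FPR operating point follows the threshold convention", {
  scores <- c(0.9, 0.8, 0.7, 0.65, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  labels <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  # 10-subject hand example vs exhaustive scan
  for (target in c(15, 30, 50, 100)) {
    got <- dr_at_fpr(scores, labels, target)
    want <- bf_dr_at_fpr(scores, labels, target)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$dr, want$dr)
  }
  expect_equal(dr_at_fpr(scores, labels, 100)$dr, 100)
  expect_error(dr_at_fpr(scores, labels, 0), "FPR")
  expect_error(dr_at_fpr(scores, labels, 120), "FPR")

  set.seed(41)
  drs <- c()
  for (i in 1:200) {
    n <- sample(8:50, 1)
    s <- round(runif(n), 2)
    l <- c(TRUE, FALSE, runif(n - 2) < 0.3)
    target <- sample(c(5, 10, 15, 25, 50), 1)
    got <- dr_at_fpr(s, l, target)
    want <- bf_dr_at_fpr(s, l, target)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$dr, want$dr)
    expect_lte(got$fpr, target)
  }
  # DR monotone non-decreasing in the FPR target
  set.seed(43)
  s <- runif(200); l <- runif(200) < 0.2
  drs <- vapply(c(5, 10, 20, 40, 80), function(t) dr_at_fpr(s, l, t)$dr, numeric(1))
  expect_true(all(diff(drs) >= 0))
})

test_that("exact binomial intervals match closed-form endpoints", {
  expect_lt(max(abs(clopper_pearson(7, 8) - c(47.35, 99.68))), 0.005)
  expect_lt(abs(clopper_pearson(5, 5)[1] - 47.82), 0.005)
  expect_equal(unname(clopper_pearson(5, 5)[2]), 100)
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_lt(max(abs(clopper_pearson(6, 10) - c(26.24, 87.84))), 0.005)
  # agreement with binom.test across counts
  for (x in c(0, 1, 4, 9, 10)) {
    expect_equal(unname(clopper_pearson(x, 10)),
                 100 * as.numeric(binom.test(x, 10)$conf.int), tolerance = 1e-9)
  }
  expect_error(clopper_pearson(5, 4), "invalid")
  expect_error(clopper_pearson(-1, 4), "invalid")
})

test_that("exact binomial interval coverage is at least nominal", {
  set.seed(53)
  n <- 30
  cis <- vapply(0:n, function(k) clopper_pearson(k, n), numeric(2))
  for (p in c(0.1, 0.5, 0.9)) {
    x <- rbinom(10000, n, p)
    covered <- mean(cis[1, x + 1] <= 100 * p & 100 * p <= cis[2, x + 1])
    expect_gte(covered, 0.945)
  }
})

test_that("Mann-Whitney test matches exact enumeration and is rank-invariant", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)  # 2/20 orderings are as extreme, two-sided
  same <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.95)
  # invariance under a common monotone transform
  a <- c(0.3, 1.2, 2.5, 4.1); b <- c(0.9, 3.3, 5.2, 6.4)
  r1 <- mann_whitney(a, b)
  r2 <- mann_whitney(exp(a), exp(b))
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p, r2$p)
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
})

test_that("group MoM summaries report medians, IQRs and tests per subgroup", {
  co <- generate_cohort(small_config(400L), seed = 29)
  panel <- compute_mom_panel(co)
  tab <- summarize_group_moms(co, panel)
  expect_true(all(c("Unaffected by PE", "PE", "Early PE", "Late PE",
                    "PE with SGA", "SGA", "SGA without PE") %in% tab$group))
  expect_true(all(tab$q1 <= tab$median & tab$median <= tab$q3, na.rm = TRUE))
  un <- tab[tab$group == "Unaffected by PE", ]
  expect_true(all(is.na(un$p_vs_unaffected)))
  expect_equal(unique(tab$n[tab$group == "PE"]),
               sum(co$pe_status != "none"))
  # medians invariant to row order
  perm <- sample(nrow(co))
  tab2 <- summarize_group_moms(co[perm, ], panel[perm, ])
  expect_equal(tab2$median, tab$median)
  # constant marker: IQR width zero
  panel3 <- panel
  panel3$mom_map <- 1
  tab3 <- summarize_group_moms(co, panel3)
  mm <- tab3[tab3$marker == "map", ]
  expect_true(all(mm$q3 - mm$q1 == 0, na.rm = TRUE))
  # empty group emits an n = 0 row without a test
  co4 <- co[co$pe_status != "early", ]
  panel4 <- panel[co$pe_status != "early", ]
  tab4 <- summarize_group_moms(co4, panel4)
  expect_true(all(tab4$n[tab4$group == "Early PE"] == 0))
})

test_that("fixed-FPR performance table has coherent CIs and counts", {
  co <- generate_cohort(small_config(500L), seed = 37)
  panel <- compute_mom_panel(co)
  g <- fit_gaussian_model(log_mom_matrix(panel), pe_group_labels(co))
  risks <- score_cohort(co, panel, default_prior_model(), g)
  lab <- co$pe_status == "early"
  tab <- performance_table(
    risks$posterior_early, lab,
    subgroups = list("Early PE" = lab, "Early PE with SGA" = lab & co$sga),
    target_fprs = c(5, 10, 15)
  )
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$dr >= 0 & tab$dr <= 100, na.rm = TRUE))
  expect_true(all(tab$dr_lo <= tab$dr & tab$dr <= tab$dr_hi, na.rm = TRUE))
  expect_true(all(tab$ppv_lo <= tab$ppv & tab$ppv <= tab$ppv_hi, na.rm = TRUE))
  expect_match(tab$cutoff[1], "^1:\\d+$")
  # DR non-decreasing with the FPR target within a subgroup
  pe_rows <- tab[tab$subgroup == "Early PE", ]
  expect_true(all(diff(pe_rows$dr) >= 0))
})
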