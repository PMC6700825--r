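#' Log-scale SD from a median's interquartile range
#'
#' Converts a `median (Q1-Q3)` summary of a log-normally distributed
#' quantity into the SD of its log10: `log10(q3/q1) / 1.349`, where
#' 1.349 = 2 * 0.6745 is the normal quartile spacing.
#'
#' @param q1,q3 Lower and upper quartiles, `0 < q1 < q3`.
#' @return SD on the log10 scale.
#' @export
iqr_to_sigma <- function(q1, q3) {
  if (any(q1 <= 0) || any(q3 <= q1)) stop("need 0 < q1 < q3")
  log10(q3 / q1) / 1.349
}

mq <- function(median, q1, q3) c(median = median, q1 = q1, q3 = q3)

#' Default synthetic-cohort generator configuration
#'
#' Encodes the study conditions this package models: 3270 pregnancies
#' with 8 early-PE (5 delivering SGA), 35 late-PE (10 SGA) and 84
#' SGA-without-PE outcomes; group-specific adjusted MoM medians and IQRs
#' for MAP, PLGF and PAPP-A; and maternal-characteristic distributions
#' (log-normal weight/BMI, normal height, per the quartile-spacing rule).
#' Marker log10 MoM distributions are Gaussian and independent across
#' markers by default (group correlations are not published for this
#' population); an optional `marker_correlation` matrix applies a common
#' correlation structure to every group.
#'
#' @return Named list accepted by [generate_cohort()].
#' @export
default_generator_config <- function() {
  list(
    n_total = 3270L,
    mode = "fixed", # "fixed" reproduces the counts exactly; "probabilistic" draws them
    counts = list(
      early_pe = 8L, late_pe = 35L,
      early_pe_sga = 5L, late_pe_sga = 10L,
      sga_without_pe = 84L
    ),
    # adjusted MoM median and quartiles per outcome group, (MAP, PLGF, PAPP-A)
    groups = list(
      unaffected = list(map = mq(0.97, 0.90, 1.04), plgf = mq(1.11, 0.79, 1.47),
                        pappa = mq(0.93, 0.67, 1.29)),
      early_pe = list(map = mq(1.13, 1.10, 1.18), plgf = mq(0.72, 0.49, 0.90),
                      pappa = mq(0.49, 0.28, 1.15)),
      late_pe = list(map = mq(1.04, 0.99, 1.12), plgf = mq(0.59, 0.41, 0.87),
                     pappa = mq(0.83, 0.50, 1.17)),
      sga_without_pe = list(map = mq(0.98, 0.90, 1.07), plgf = mq(0.92, 0.63, 1.28),
                            pappa = mq(0.87, 0.52, 1.20))
    ),
    marker_correlation = NULL,
    trunc_limits = c(-1, 1),
    characteristics = list(
      non_pe = list(
        age = mq(30, 28, 34), weight = mq(53.0, 48.8, 58.6),
        height = mq(160, 156, 163), ga_days = mq(89, 86, 91),
        smoking = 2 / 3227, chronic_htn = 19 / 3227, ivf = 33 / 3227,
        nulliparous = 0.55, prior_pe_parous = 0.02
      ),
      pe = list(
        age = mq(30, 28, 34), weight = mq(56.0, 51.5, 65.0),
        height = mq(157.75, 154.75, 162.25), ga_days = mq(88, 85, 91),
        smoking = 0, chronic_htn = 8 / 43, ivf = 0,
        nulliparous = 0.70, prior_pe_parous = 0.15
      )
    ),
    delivery = list( # decimal weeks: mean, sd, lower, upper
      unaffected = c(39, 1.48, 34, 42),
      early_pe = c(32.3, 1.3, 27, 33.86),
      late_pe = c(37, 1.8, 34, 41),
      sga_without_pe = c(36.8, 3, 28, 41.5)
    ),
    ethnicity = "chinese",
    median_model = default_median_model(),
    id_prefix = "P"
  )
}

draw_lognormal <- function(n, p) 10^stats::rnorm(n, log10(p[["median"]]), iqr_to_sigma(p[["q1"]], p[["q3"]]))
draw_normal <- function(n, p) stats::rnorm(n, p[["median"]], (p[["q3"]] - p[["q1"]]) / 1.349)

# Integer two-reading series whose arm MAP equals `target` to within 1/12 mmHg.
# The second reading compensates the rounding of the first so that the sum
# S1 + 2 D1 + S2 + 2 D2 equals round(6 * target).
synth_arm_readings <- function(target, pulse_pressure, js, jd) {
  d <- target - pulse_pressure / 3
  s <- d + pulse_pressure
  s1 <- round(s + js)
  d1 <- round(d + jd)
  k <- round(6 * target) - s1 - 2 * d1
  d2 <- round((k - round(s)) / 2)
  s2 <- k - 2 * d2
  list(s1 = s1, d1 = d1, s2 = s2, d2 = d2,
       map = (s1 + 2 * d1 + s2 + 2 * d2) / 6)
}

draw_group_log_mom <- function(n, group_params, correlation) {
  mu <- vapply(markers_all, function(mk) log10(group_params[[mk]][["median"]]), numeric(1))
  sd <- vapply(markers_all, function(mk) {
    iqr_to_sigma(group_params[[mk]][["q1"]], group_params[[mk]][["q3"]])
  }, numeric(1))
  z <- matrix(stats::rnorm(n * 3), ncol = 3)
  if (!is.null(correlation)) z <- z %*% chol(correlation)
  x <- sweep(sweep(z, 2, sd, `*`), 2, mu, `+`)
  colnames(x) <- markers_all
  x
}

#' Generate a synthetic screening cohort
#'
#' Draws outcome labels (fixed-count mode reproduces the configured flow
#' exactly), group-conditional log10 MoM triples (truncated to the
#' configured limits), back-computes marker concentrations through the
#' median model at each subject's gestational age (re-applying the
#' covariate adjustment so the analysis pipeline recovers the drawn
#' adjusted MoM), synthesises integer two-reading blood-pressure series
#' per arm such that the BP protocol recovers the intended MAP, and draws
#' maternal characteristics and outcomes consistent with the PE and SGA
#' classification rules.
#'
#' @param config See [default_generator_config()].
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return Cohort `data.frame` in the [cohort_schema()] layout plus
#'   derived `bmi` and `pe_status`, with attributes `marker_group` (the
#'   generating group per row) and `drawn_log_mom` (the generated
#'   truncated log10 MoM matrix).
#' @export
generate_cohort <- function(config = default_generator_config(), seed = 1) {
  set.seed(seed)
  n <- as.integer(config$n_total)
  cnt <- config$counts

  if (identical(config$mode, "probabilistic")) {
    probs <- c(early = cnt$early_pe, late = cnt$late_pe,
               sga = cnt$sga_without_pe) / n
    u <- stats::runif(n)
    grp <- ifelse(u < probs[1], "early_pe",
           ifelse(u < probs[1] + probs[2], "late_pe",
           ifelse(u < sum(probs), "sga_without_pe", "unaffected")))
    n_early <- sum(grp == "early_pe"); n_late <- sum(grp == "late_pe")
    n_sga_wo <- sum(grp == "sga_without_pe")
    n_early_sga <- stats::rbinom(1, n_early, ifelse(cnt$early_pe > 0, cnt$early_pe_sga / cnt$early_pe, 0))
    n_late_sga <- stats::rbinom(1, n_late, ifelse(cnt$late_pe > 0, cnt$late_pe_sga / cnt$late_pe, 0))
  } else {
    n_early <- cnt$early_pe; n_late <- cnt$late_pe; n_sga_wo <- cnt$sga_without_pe
    n_early_sga <- cnt$early_pe_sga; n_late_sga <- cnt$late_pe_sga
    if (n_early + n_late + n_sga_wo > n) stop("group counts exceed n_total")
    if (n_early_sga > n_early || n_late_sga > n_late) {
      stop("SGA-within-PE counts exceed PE group counts")
    }
    grp <- rep(c("early_pe", "late_pe", "sga_without_pe", "unaffected"),
               c(n_early, n_late, n_sga_wo, n - n_early - n_late - n_sga_wo))
  }

  pe_class <- c(early_pe = "early", late_pe = "late",
                sga_without_pe = "none", unaffected = "none")[grp]
  sga <- grp == "sga_without_pe"
  if (n_early > 0) {
    idx <- which(grp == "early_pe")
    sga[sample(idx, min(n_early_sga, length(idx)))] <- TRUE
  }
  if (n_late > 0) {
    idx <- which(grp == "late_pe")
    sga[sample(idx, min(n_late_sga, length(idx)))] <- TRUE
  }

  # maternal characteristics, by PE status (Table-1-style distributions)
  cls <- ifelse(pe_class == "none", "non_pe", "pe")
  ch <- config$characteristics
  pick <- function(field, draw) {
    out <- numeric(n)
    for (k in c("non_pe", "pe")) {
      i <- cls == k
      if (any(i)) out[i] <- draw(sum(i), ch[[k]][[field]])
    }
    out
  }
  pbin <- function(field) {
    p <- ifelse(cls == "non_pe", ch$non_pe[[field]], ch$pe[[field]])
    stats::runif(n) < p
  }
  age <- round(pmax(16, pick("age", draw_normal)), 1)
  weight <- round(pmax(35, pick("weight", draw_lognormal)), 1)
  height <- round(pmin(pmax(pick("height", draw_normal), 140), 185), 1)
  ga_days <- as.integer(pmin(pmax(round(pick("ga_days", draw_normal)), 77), 97))
  crl <- round(pmax(ga_days - 26 + stats::rnorm(n, 0, 2.5), 35), 1)
  smoking <- pbin("smoking")
  chronic_htn <- pbin("chronic_htn")
  conception <- ifelse(pbin("ivf"), "ivf", "spontaneous")
  parity <- ifelse(pbin("nulliparous"), "nulliparous", "parous")
  prior_pe <- parity == "parous" & pbin("prior_pe_parous")

  # group-conditional adjusted log10 MoM, truncated
  x <- matrix(NA_real_, n, 3, dimnames = list(NULL, markers_all))
  for (g in unique(grp)) {
    i <- grp == g
    x[i, ] <- draw_group_log_mom(sum(i), config$groups[[g]], config$marker_correlation)
  }
  x <- truncate_log_mom(x, config$trunc_limits)$value
  adj_mom <- 10^x
  mm <- config$median_model

  # serum markers: undo the covariate adjustment, scale by the GA median
  shift <- function(mk) {
    10^(mm$weight_slope[[mk]] * (weight - mm$weight_reference)) *
      unname(mm$ethnicity_factors[[mk]][rep(config$ethnicity, n)]) *
      ifelse(smoking, mm$smoking_factors[[mk]], 1)
  }
  plgf <- round(adj_mom[, "plgf"] * shift("plgf") * expected_median(mm, "plgf", ga_days), 2)
  pappa <- round(adj_mom[, "pappa"] * shift("pappa") * expected_median(mm, "pappa", ga_days), 2)

  # blood pressure: integer readings engineered so the protocol recovers
  # the intended MAP to within 1/12 mmHg; the stored MAP and MAP MoM are
  # the values the protocol actually recovers
  target_map <- adj_mom[, "map"] * expected_median(mm, "map", ga_days)
  gap <- pmin(pmax(abs(stats::rnorm(n, 1.5, 0.7)), 0.35), 4)
  pp_hi <- pmin(pmax(round(stats::rnorm(n, 42, 6)), 28), 62)
  pp_lo <- pmin(pmax(round(stats::rnorm(n, 42, 6)), 28), 62)
  js <- function() pmin(pmax(round(stats::rnorm(n, 0, 2)), -4), 4)
  jd <- function() pmin(pmax(round(stats::rnorm(n, 0, 0.8)), -1), 1)
  hi <- synth_arm_readings(target_map, pp_hi, js(), jd())
  lo <- synth_arm_readings(target_map - gap, pp_lo, js(), jd())
  hi_left <- stats::runif(n) < 0.5
  fmt <- function(a) sprintf("%d/%d;%d/%d", a$s1, a$d1, a$s2, a$d2)
  bp_left <- ifelse(hi_left, fmt(hi), fmt(lo))
  bp_right <- ifelse(hi_left, fmt(lo), fmt(hi))
  map_final <- pmax(hi$map, lo$map)

  # outcomes consistent with the classification rules
  dl <- config$delivery
  deliv <- numeric(n)
  for (g in unique(grp)) {
    i <- grp == g
    p <- dl[[g]]
    deliv[i] <- round(pmin(pmax(stats::rnorm(sum(i), p[1], p[2]), p[3]), p[4]), 2)
  }
  onset <- rep(NA_real_, n)
  pe_i <- pe_class != "none"
  onset[pe_i] <- round(pmax(deliv[pe_i] - abs(stats::rnorm(sum(pe_i), 3.5, 1.5)), 20.5), 1)
  proteinuria <- pe_i

  ptab <- read_percentile_table()
  p10 <- stats::approx(ptab$ga_week, ptab$p10_g, xout = deliv)$y
  mult <- ifelse(
    sga,
    stats::runif(n, 0.72, 0.995),
    pmax(10^stats::rnorm(n, log10(1.128), 0.045), 1.005)
  )
  birth_weight <- round(p10 * mult)

  cohort <- data.frame(
    id = character(n),
    maternal_age = age, weight_kg = weight, height_cm = height,
    ethnicity = config$ethnicity, smoking = smoking, parity = parity,
    prior_pe = prior_pe, chronic_htn = chronic_htn, conception = conception,
    ga_days = ga_days, crl_mm = crl,
    bp_left = bp_left, bp_right = bp_right, map_mmHg = map_final,
    plgf_pgml = plgf, pappa_mUL = pappa,
    onset_ga_weeks = onset, proteinuria = proteinuria,
    ga_delivery_weeks = deliv, birth_weight_g = birth_weight, sga = sga,
    stringsAsFactors = FALSE
  )

  perm <- sample.int(n)
  cohort <- cohort[perm, ]
  rownames(cohort) <- NULL
  cohort$id <- sprintf("%s%05d", config$id_prefix, seq_len(n))
  cohort$bmi <- compute_bmi(cohort$weight_kg, cohort$height_cm)
  cohort$pe_status <- factor(pe_class[perm], levels = c("none", "early", "late"))
  attr(cohort, "marker_group") <- grp[perm]
  attr(cohort, "drawn_log_mom") <- x[perm, , drop = FALSE]
  cohort
}

#' Generate an independent training/test cohort pair
#'
#' Two cohorts from the same configuration with derived, distinct seeds
#' and disjoint subject id namespaces, for fit-on-train /
#' evaluate-on-test pipelines.
#'
#' @param config Generator configuration.
#' @param split_seed Integer seed for the pair.
#' @return List with elements `train` and `test`.
#' @export
generate_training_test_pair <- function(config = default_generator_config(),
                                        split_seed = 1) {
  cfg_tr <- config; cfg_tr$id_prefix <- "TR"
  cfg_te <- config; cfg_te$id_prefix <- "TE"
  list(
    train = generate_cohort(cfg_tr, seed = (split_seed * 2L) %% .Machine$integer.max),
    test = generate_cohort(cfg_te, seed = (split_seed * 2L + 1L) %% .Machine$integer.max)
  )
}

#' Case-control configuration for enriched method experiments
#'
#' A generator configuration with only early-PE and unaffected outcome
#' groups at enriched counts, used to study intrinsic marker
#' separability without the variance of rare-event sampling.
#'
#' @param n_affected Early-PE count per cohort.
#' @param n_unaffected Unaffected count per cohort.
#' @return Generator configuration list.
#' @export
enriched_config <- function(n_affected = 2000L, n_unaffected = 20000L) {
  cfg <- default_generator_config()
  cfg$n_total <- as.integer(n_affected + n_unaffected)
  cfg$counts <- list(
    early_pe = as.integer(n_affected), late_pe = 0L,
    early_pe_sga = 0L, late_pe_sga = 0L, sga_without_pe = 0L
  )
  cfg
}
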