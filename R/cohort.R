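#' Cohort file schema
#'
#' Column names and types of the delimited cohort format: one row per
#' pregnancy, header row, comma-separated, UTF-8, missing values as `NA`.
#' Blood-pressure series are encoded per arm as `"S/D;S/D;..."` (see
#' [parse_bp_series()]). Gestational age at screening is held in days
#' (screening window 77--97 days, i.e. 11+0 to 13+6 weeks); delivery
#' gestational age in decimal weeks.
#'
#' @return Named character vector mapping column name to type
#'   (`"character"`, `"numeric"`, `"integer"`, `"logical"`).
#' @export
cohort_schema <- function() {
  c(
    id = "character",
    maternal_age = "numeric",        # years
    weight_kg = "numeric",
    height_cm = "numeric",
    ethnicity = "character",
    smoking = "logical",
    parity = "character",            # nulliparous | parous
    prior_pe = "logical",
    chronic_htn = "logical",
    conception = "character",        # spontaneous | ivf
    ga_days = "integer",             # GA at screening, days
    crl_mm = "numeric",
    bp_left = "character",
    bp_right = "character",
    map_mmHg = "numeric",            # final MAP per the BP protocol
    plgf_pgml = "numeric",
    pappa_mUL = "numeric",
    onset_ga_weeks = "numeric",      # hypertension onset; NA when none
    proteinuria = "logical",
    ga_delivery_weeks = "numeric",
    birth_weight_g = "numeric",
    sga = "logical"
  )
}

#' Body-mass index
#'
#' @param weight_kg Weight in kg, positive.
#' @param height_cm Height in cm, positive.
#' @return BMI in kg/m^2 (vectorised).
#' @examples
#' compute_bmi(64, 160) # 25
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive")
  }
  weight_kg / (height_cm / 100)^2
}

#' Classify preeclampsia status
#'
#' PE requires new-onset hypertension after 20 weeks' gestation together
#' with proteinuria; it is early when delivery occurs before 34 weeks and
#' late when delivery is at or after 34 weeks. Hypertension with onset at
#' or before 20 weeks is outside the definition (chronic) and yields
#' `"none"` with a warning.
#'
#' @param onset_ga_weeks Gestational age at hypertension onset (weeks), or
#'   `NA` when no hypertension was recorded. Vectorised.
#' @param proteinuria Logical, proteinuria criterion met.
#' @param ga_delivery_weeks Gestational age at delivery (decimal weeks).
#' @return Factor with levels `none`, `early`, `late`.
#' @export
classify_pe <- function(onset_ga_weeks, proteinuria, ga_delivery_weeks) {
  n <- max(length(onset_ga_weeks), length(proteinuria), length(ga_delivery_weeks))
  onset <- rep_len(onset_ga_weeks, n)
  prot <- rep_len(proteinuria, n)
  deliv <- rep_len(ga_delivery_weeks, n)
  early_onset <- !is.na(onset) & onset <= 20
  if (any(early_onset)) {
    warning(sum(early_onset), " record(s) with hypertension onset <= 20 weeks: ",
            "outside the PE definition (chronic), classified as none")
  }
  pe <- !is.na(onset) & onset > 20 & !is.na(prot) & prot
  out <- ifelse(pe, ifelse(deliv < 34, "early", "late"), "none")
  factor(out, levels = c("none", "early", "late"))
}

#' Read a birth-weight percentile reference table
#'
#' Two-column CSV (`ga_week`, `p10_g`): 10th-percentile birth weight (g)
#' by completed gestational week. The 10th percentile must increase
#' strictly with gestational age.
#'
#' @param path CSV path. The default loads the sex-agnostic synthetic
#'   reference shipped with the package (a stand-in for a national chart,
#'   which is external to this package).
#' @return `data.frame` with columns `ga_week` and `p10_g`.
#' @export
read_percentile_table <- function(path = system.file("extdata",
                                                     "synthetic_p10_birthweight.csv",
                                                     package = "pescreen")) {
  tab <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("ga_week", "p10_g") %in% names(tab))) {
    stop("percentile table must have columns ga_week and p10_g")
  }
  tab <- tab[order(tab$ga_week), ]
  if (any(diff(tab$p10_g) <= 0)) {
    stop("p10_g must be strictly increasing in ga_week")
  }
  tab
}

#' Classify small-for-gestational-age
#'
#' A newborn is SGA when its birth weight is strictly below the 10th
#' percentile for gestational age at delivery. The percentile is linearly
#' interpolated between the weekly rows of the reference table.
#'
#' @param birth_weight_g Birth weight (g), vectorised.
#' @param ga_delivery_weeks Delivery gestational age (decimal weeks).
#' @param table Percentile table, see [read_percentile_table()].
#' @return Logical vector.
#' @export
classify_sga <- function(birth_weight_g, ga_delivery_weeks,
                         table = read_percentile_table()) {
  rng <- range(table$ga_week)
  bad <- ga_delivery_weeks < rng[1] | ga_delivery_weeks > rng[2]
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf(
      "delivery GA outside percentile table range [%g, %g] weeks",
      rng[1], rng[2]
    ))
  }
  p10 <- stats::approx(table$ga_week, table$p10_g, xout = ga_delivery_weeks)$y
  birth_weight_g < p10
}

validate_cohort_row <- function(row) {
  msgs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(row$weight_kg > 0, "weight_kg must be > 0")
  chk(row$height_cm > 0, "height_cm must be > 0")
  chk(row$ga_days >= 77 && row$ga_days <= 97,
      "ga_days outside screening window [77, 97]")
  chk(row$plgf_pgml > 0, "plgf_pgml must be > 0")
  chk(row$pappa_mUL > 0, "pappa_mUL must be > 0")
  chk(row$map_mmHg > 0, "map_mmHg must be > 0")
  chk(row$parity %in% c("nulliparous", "parous"), "unknown parity level")
  chk(row$conception %in% c("spontaneous", "ivf"), "unknown conception level")
  if (!is.na(row$onset_ga_weeks) && row$onset_ga_weeks > 20 &&
      isTRUE(row$proteinuria)) {
    chk(row$ga_delivery_weeks > 20, "PE case with delivery GA <= 20 weeks")
  }
  msgs
}

#' Read and validate a cohort file
#'
#' Reads the delimited cohort format described in [cohort_schema()],
#' coerces columns to their declared types, validates row-level
#' invariants, and derives `bmi` and `pe_status` columns. Rows failing
#' validation are dropped and reported in the `rejected` attribute.
#'
#' @param path CSV path.
#' @return `data.frame` of valid records with derived columns `bmi`
#'   (kg/m^2) and `pe_status` (factor none/early/late); attribute
#'   `rejected` is a `data.frame(row, id, reason)` of dropped rows.
#' @export
read_cohort <- function(path) {
  schema <- cohort_schema()
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(schema), names(raw))
  if (length(missing)) {
    stop("cohort file is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- raw[names(schema)]
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type == "character") next
    x <- df[[col]]
    conv <- switch(type,
      numeric = suppressWarnings(as.numeric(x)),
      integer = suppressWarnings(as.integer(x)),
      logical = as.logical(x)
    )
    bad <- which(!is.na(x) & x != "NA" & x != "" & is.na(conv))
    if (length(bad)) {
      stop(sprintf("column '%s', row %d: cannot parse value '%s' as %s",
                   col, bad[1], x[bad[1]], type))
    }
    df[[col]] <- conv
  }
  reasons <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(validate_cohort_row(df[i, ]), error = function(e) conditionMessage(e))
  })
  nbad <- lengths(reasons) > 0
  rejected <- data.frame(
    row = which(nbad),
    id = df$id[nbad],
    reason = vapply(reasons[nbad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  ok <- df[!nbad, , drop = FALSE]
  rownames(ok) <- NULL
  ok$bmi <- compute_bmi(ok$weight_kg, ok$height_cm)
  ok$pe_status <- suppressWarnings(
    classify_pe(ok$onset_ga_weeks, ok$proteinuria, ok$ga_delivery_weeks)
  )
  attr(ok, "rejected") <- rejected
  ok
}

#' Write a cohort file
#'
#' Writes the schema columns of `cohort` (derived columns such as `bmi`
#' are not written; they are recomputed on read).
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cols <- names(cohort_schema())
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}
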