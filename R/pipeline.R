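#' Default end-to-end pipeline configuration
#'
#' @param use_fitted_medians Refit the gestational-age median model on the
#'   simulated cohort's unaffected pregnancies instead of using the
#'   shipped medians. The default keeps the shipped medians, under which
#'   population MoM medians can legitimately deviate from 1 (a median
#'   model calibrated elsewhere applied to a new population).
#' @return Named list of pipeline settings.
#' @export
pipeline_config <- function(use_fitted_medians = FALSE) {
  list(
    generator = default_generator_config(),
    prior = default_prior_model(),
    use_fitted_medians = use_fitted_medians,
    trunc_limits = c(-1, 1),
    target_fprs = c(5, 10, 15),
    default_cutoff_n = 20
  )
}

subgroup_defs <- function(cohort) {
  pe <- cohort$pe_status
  sga <- cohort$sga
  early_del <- cohort$ga_delivery_weeks < 34
  list(
    early = list(
      affected = pe == "early",
      subgroups = list(
        "Early PE" = pe == "early",
        "Early PE with SGA" = pe == "early" & sga,
        "Early PE with AGA" = pe == "early" & !sga,
        "Early SGA" = sga & early_del,
        "Early SGA without PE" = sga & early_del & pe == "none"
      )
    ),
    late = list(
      affected = pe == "late",
      subgroups = list(
        "Late PE" = pe == "late",
        "Late PE with SGA" = pe == "late" & sga,
        "Late PE with AGA" = pe == "late" & !sga,
        "Late SGA" = sga & !early_del,
        "Late SGA without PE" = sga & !early_del & pe == "none"
      )
    )
  )
}

#' Run the full screening pipeline
#'
#' simulate -> fit -> score -> evaluate, writing every stage product and a
#' provenance manifest into `dir`: `cohort.csv`, `model.yaml`,
#' `risks.csv`, `table_markers.csv` (group MoM summaries),
#' `table_auc.csv` (prior/posterior ROC performance with best cutoffs),
#' `table_fixed_fpr.csv` (subgroup DR/PPV at fixed FPRs),
#' `roc_coordinates.csv`, `manifest.json`. All randomness derives from
#' `seed`; outputs other than the manifest (which carries timestamps) are
#' reproducible byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage products
#'   (`cohort`, `panel`, `model`, `risks`, `tables`).
#' @export
run_pipeline <- function(dir, seed = 1, config = pipeline_config()) {
  for (section in c("generator", "prior", "trunc_limits", "target_fprs")) {
    if (is.null(config[[section]])) {
      stop("pipeline config is missing the '", section, "' section")
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- function(f) file.path(dir, f)

  cohort <- generate_cohort(config$generator, seed)
  write_cohort(cohort, paths("cohort.csv"))

  med <- if (isTRUE(config$use_fitted_medians)) {
    fit_median_model(cohort)
  } else {
    config$generator$median_model
  }
  panel <- compute_mom_panel(cohort, med, config$trunc_limits)
  group <- c(none = "unaffected", early = "early", late = "late")[as.character(cohort$pe_status)]
  gauss <- fit_gaussian_model(log_mom_matrix(panel), group)
  model <- risk_model(med, config$prior, gauss)
  write_risk_model(model, paths("model.yaml"))

  risks <- score_cohort(cohort, panel, config$prior, gauss)
  utils::write.csv(risks, paths("risks.csv"), row.names = FALSE, quote = FALSE)

  tab_markers <- summarize_group_moms(cohort, panel)
  utils::write.csv(tab_markers, paths("table_markers.csv"), row.names = FALSE)

  auc_rows <- list()
  roc_coords <- list()
  for (h in c("early", "late")) {
    lab <- cohort$pe_status == h
    for (kind in c("prior", "posterior")) {
      sc <- risks[[paste0(kind, "_", h)]]
      roc <- roc_auc(sc, lab)
      bc <- best_cutoff(roc)
      auc_rows[[paste0(h, "_", kind)]] <- data.frame(
        horizon = h, risk = kind,
        auc = roc$auc, auc_lo = roc$auc_ci[1], auc_hi = roc$auc_ci[2],
        best_cutoff = format_risk(bc$threshold),
        dr = bc$dr, fpr = bc$fpr,
        dr_at_default_cutoff =
          100 * mean(screen_positive(sc[lab], config$default_cutoff_n))
      )
      roc_coords[[paste0(h, "_", kind)]] <- data.frame(
        horizon = h, risk = kind,
        threshold = roc$thresholds,
        sensitivity = roc$sensitivity,
        specificity = roc$specificity
      )
    }
    cmp <- compare_auc(risks[[paste0("posterior_", h)]],
                       risks[[paste0("prior_", h)]], lab)
    auc_rows[[paste0(h, "_posterior")]]$p_vs_prior <- cmp$p
    auc_rows[[paste0(h, "_prior")]]$p_vs_prior <- NA_real_
  }
  tab_auc <- do.call(rbind, auc_rows)
  rownames(tab_auc) <- NULL
  utils::write.csv(tab_auc, paths("table_auc.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, roc_coords), paths("roc_coordinates.csv"),
                   row.names = FALSE)

  defs <- subgroup_defs(cohort)
  perf <- list()
  for (h in c("early", "late")) {
    pt <- performance_table(
      risks[[paste0("posterior_", h)]], defs[[h]]$affected,
      defs[[h]]$subgroups, config$target_fprs
    )
    pt <- cbind(horizon = h, pt)
    perf[[h]] <- pt
  }
  tab_fpr <- do.call(rbind, perf)
  rownames(tab_fpr) <- NULL
  utils::write.csv(tab_fpr, paths("table_fixed_fpr.csv"), row.names = FALSE)

  cfg_file <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rapply(config, unclass, how = "replace"), cfg_file)
  outputs <- c("cohort.csv", "model.yaml", "risks.csv", "table_markers.csv",
               "table_auc.csv", "table_fixed_fpr.csv", "roc_coordinates.csv")
  manifest <- list(
    package = "pescreen",
    version = as.character(utils::packageVersion("pescreen")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = as.list(tools::md5sum(vapply(outputs, paths, character(1)))),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, paths("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, panel = panel, model = model, risks = risks,
                 tables = list(markers = tab_markers, auc = tab_auc,
                               fixed_fpr = tab_fpr)))
}

#' Import an externally scored cohort table
#'
#' Reads a per-participant spreadsheet (XLS/XLSX via readxl, or CSV)
#' holding recorded posterior risks alongside outcomes, using a
#' user-supplied column mapping (such files do not follow this package's
#' cohort schema). With outcome columns present the result feeds directly
#' into the evaluation functions; without them it degrades to a
#' score-only table.
#'
#' @param path Spreadsheet or CSV path.
#' @param mapping Named character vector from standard names to the
#'   file's column headers. Required: `posterior_early`,
#'   `posterior_late`. Optional: `id`, `pe_status` (values none, early,
#'   late), `sga`.
#' @param sheet Sheet index/name for spreadsheet input.
#' @return `data.frame` with the mapped standard columns.
#' @export
import_supplementary <- function(path, mapping, sheet = 1) {
  required <- c("posterior_early", "posterior_late")
  if (!all(required %in% names(mapping))) {
    stop("mapping must provide: ", paste(required, collapse = ", "))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xls", "xlsx")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading ", ext, " files requires the readxl package")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  missing <- setdiff(unname(mapping), names(raw))
  if (length(missing)) {
    stop("mapped column(s) not found: ", paste(missing, collapse = ", "),
         "; available headers: ", paste(names(raw), collapse = ", "))
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (std in names(mapping)) out[[std]] <- raw[[mapping[[std]]]]
  for (col in intersect(c("posterior_early", "posterior_late"), names(out))) {
    out[[col]] <- as.numeric(out[[col]])
    if (anyNA(out[[col]])) stop("non-numeric values in ", col)
  }
  if (!is.null(out$pe_status)) {
    bad <- setdiff(unique(out$pe_status), c("none", "early", "late"))
    if (length(bad)) stop("invalid pe_status value(s): ", paste(bad, collapse = ", "))
    out$pe_status <- factor(out$pe_status, levels = c("none", "early", "late"))
  }
  if (!is.null(out$sga)) out$sga <- as.logical(out$sga)
  out
}
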