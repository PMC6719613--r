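# Study orchestration: extraction -> split -> per-scanner harmonization ->
# SMOTE + stability selection (training side only) -> train-side cutoffs ->
# evaluation on both sides. Stage ordering guarantees that no test-side
# value can influence a training-side decision.

CLINICAL_COVARIATES <- c("age", "psa_pre", "psa_post", "gleason",
                         "t_stage", "margins", "capra_s")

#' Extract the cohort feature table
#'
#' Decomposes each patient's sequences into wavelet banks and extracts the
#' full feature-variant row (see [extract_all()]).
#'
#' @param cohort A `synthetic_cohort` (or any list with `clinical` and
#'   `images` of the same shape).
#' @param schemes Discretization schemes (default: fixed-bin-number grid
#'   with 16 and 32 bins, the study grid).
#' @param connectivity Zone connectivity (default 26).
#' @return Numeric matrix, patients x feature variants, rownames = patient
#'   ids.
#' @export
extract_feature_table <- function(cohort,
                                  schemes = default_scheme_grid(c(16, 32)),
                                  connectivity = 26) {
  rows <- lapply(cohort$clinical$patient_id, function(pid) {
    im <- cohort$images[[pid]]
    if (is.null(im)) stop("extract_feature_table: no images for ", pid)
    banks <- list(ADC = decompose(im$ADC), T2 = decompose(im$T2))
    extract_all(banks, im$mask, schemes = schemes,
                connectivity = connectivity,
                spacing = list(ADC = im$ADC$spacing, T2 = im$T2$spacing))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- cohort$clinical$patient_id
  tab
}

#' Run the full study
#'
#' Executes the one-shot split-and-evaluate workflow: stratified 2:1
#' train/test split; per-scanner, per-side z-score harmonization; SMOTE
#' rebalancing and stability selection on the training side; training-side
#' Youden cutoffs; evaluation of the clinical-only, radiomics-only and
#' combined models on both sides. Feature variants with missing values
#' (degenerate ROIs) or zero variance within a scanner group are excluded
#' before selection.
#'
#' @param cohort A `synthetic_cohort`.
#' @param features Optional precomputed feature table (from
#'   [extract_feature_table()]); extracted if `NULL`.
#' @param schemes Discretization schemes used when extracting.
#' @param sel_config A [selection_config()]; its seed is replaced by
#'   `seed`.
#' @param seed Integer seed driving split, SMOTE and subsampling.
#' @return A `study_result`: list with `manifest`, `split`, `selection`,
#'   `univariate_clinical`, `univariate_radiomics`, `multivariate`,
#'   `comparison`, and the harmonized tables.
#' @export
run_study <- function(cohort, features = NULL,
                      schemes = default_scheme_grid(c(16, 32)),
                      sel_config = selection_config(), seed = 1) {
  clin <- cohort$clinical
  if (is.null(features))
    features <- extract_feature_table(cohort, schemes = schemes)
  stopifnot(identical(rownames(features), clin$patient_id))

  finite <- colSums(!is.finite(features)) == 0
  features <- features[, finite, drop = FALSE]

  split <- split_cohort(clin, ratio = 2 / 3, seed = seed)
  tr <- split$side == "train"; te <- !tr

  # training side first; nothing below reads test rows until evaluation
  ztr <- suppressWarnings(
    zscore_by_scanner(features[tr, , drop = FALSE], clin$scanner[tr]))
  sel_config$seed <- as.integer(seed)
  selection <- run_selection(ztr$table, clin$event[tr], sel_config)
  sel_keys <- selection$selected

  clin_tr <- as.matrix(clin[tr, CLINICAL_COVARIATES])
  uni_clin <- univariate_report(clin_tr, clin$event[tr])
  uni_rad <- if (length(sel_keys))
    univariate_report(ztr$table[, sel_keys, drop = FALSE], clin$event[tr])
  else NULL

  multiv <- NULL
  if (length(sel_keys) >= 1 && sum(clin$event[tr]) >= 2) {
    dich <- vapply(sel_keys, function(k) {
      x <- ztr$table[, k]
      rr <- roc_auc(x, clin$event[tr])
      yc <- youden_cutoff_stable(x, clin$event[tr], rr$orientation)
      classify_marker(x, yc$cutoff, rr$orientation)
    }, numeric(sum(tr)))
    multiv <- tryCatch(
      cox_fit(dich, clin$time[tr], clin$event[tr]),
      error = function(e) NULL)
  }

  # test side harmonized with its own parameters (per-side convention)
  zte <- suppressWarnings(
    zscore_by_scanner(features[te, , drop = FALSE], clin$scanner[te]))
  common <- intersect(colnames(ztr$table), colnames(zte$table))
  sel_common <- intersect(sel_keys, common)

  comparison <- evaluate_models(
    radiomics_train = ztr$table[, sel_common, drop = FALSE],
    radiomics_test = zte$table[, sel_common, drop = FALSE],
    clinical_train = clin_tr,
    clinical_test = as.matrix(clin[te, CLINICAL_COVARIATES]),
    labels_train = clin$event[tr], labels_test = clin$event[te],
    times_train = clin$time[tr], times_test = clin$time[te],
    radiomics_rank = selection$mean_abs_pc[sel_common])

  manifest <- list(
    n = nrow(clin), n_train = sum(tr), n_test = sum(te),
    n_events = sum(clin$event), seed = seed,
    schemes = vapply(schemes, function(s) s$label, character(1)),
    n_variants_extracted = length(finite),
    n_variants_dropped_nonfinite = sum(!finite),
    n_variants_analyzed = ncol(ztr$table),
    n_smote_synthetic = selection$n_synthetic,
    selection_config = unclass(sel_config))

  structure(list(manifest = manifest, split = split, selection = selection,
                 univariate_clinical = uni_clin,
                 univariate_radiomics = uni_rad,
                 multivariate = multiv, comparison = comparison,
                 train_table = ztr, test_table = zte),
            class = "study_result")
}

#' Write / read a feature table as CSV
#'
#' Header row is `patient_id` followed by one column per feature-variant
#' key (`SEQ|SUBBAND|SCHEME|FEATURE`).
#'
#' @param table Numeric matrix from [extract_feature_table()].
#' @param path CSV path.
#' @return `path` invisibly / the matrix.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(patient_id = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  tab <- as.matrix(df[, -1, drop = FALSE])
  rownames(tab) <- df$patient_id
  tab
}

#' Persist study artifacts for audit
#'
#' Writes the run manifest, split assignment, per-scanner harmonization
#' parameters, the selection result with its stability evidence summary,
#' the univariate/multivariate tables, the model comparison, and the
#' Kaplan-Meier step coordinates.
#'
#' @param study A `study_result` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  jw <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", force = TRUE)
    paths <<- c(paths, p)
  }
  cw <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  jw(study$manifest, "manifest.json")
  jw(list(side = study$split$side, seed = study$split$seed),
     "split.json")
  cw(study$train_table$params, "harmonization_train.csv")
  cw(study$test_table$params, "harmonization_test.csv")
  sel <- study$selection
  jw(list(selected = sel$selected,
          mean_abs_pc = as.list(sel$mean_abs_pc),
          n_above = as.list(sel$n_above),
          pruned = as.list(sel$pruned),
          n_synthetic = sel$n_synthetic),
     "selection.json")
  if (!is.null(study$univariate_clinical))
    cw(study$univariate_clinical, "univariate_clinical.csv")
  if (!is.null(study$univariate_radiomics))
    cw(study$univariate_radiomics, "univariate_radiomics.csv")
  if (!is.null(study$multivariate))
    cw(study$multivariate, "multivariate_cox.csv")

  km <- list()
  strip <- list()
  for (m in names(study$comparison$models)) {
    r <- study$comparison$models[[m]]
    if (is.null(r)) next
    strip[[m]] <- list(factors = r$factors)
    for (s in c("train", "test")) {
      e <- r[[s]]
      strip[[m]][[s]] <- e[c("auc", "auc_p", "sensitivity", "specificity",
                             "logrank_p", "hr", "hr_p")]
      if (!is.null(e$km$curves))
        km[[length(km) + 1]] <- cbind(model = m, side = s, e$km$curves)
    }
  }
  jw(list(models = strip, audit = study$comparison$audit), "models.json")
  if (length(km)) cw(do.call(rbind, km), "km_curves.csv")
  invisible(paths)
}

two_group_p <- function(x, side) {
  if (is.numeric(x) && length(unique(x)) > 5) {
    stats::t.test(x[side == "train"], x[side == "test"])$p.value
  } else {
    tab <- table(x, side)
    if (nrow(tab) < 2) return(NA_real_)
    suppressWarnings(stats::chisq.test(tab)$p.value)
  }
}

#' Human-readable study report
#'
#' Prints cohort characteristics by side (with two-sample train/test
#' p-values), the univariate association tables, the selection summary and
#' the three-model comparison.
#'
#' @param study A `study_result` from [run_study()].
#' @param cohort The cohort the study was run on.
#' @return The report lines, invisibly; printed as a side effect.
#' @export
study_report <- function(study, cohort) {
  clin <- cohort$clinical
  side <- study$split$side
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  push("=== Cohort characteristics (train n=%d / test n=%d) ===",
       sum(side == "train"), sum(side == "test"))
  for (v in c("age", "psa_pre", "psa_post", "gleason", "t_stage",
              "margins", "capra_s", "time")) {
    push("  %-10s mean %6.2f / %6.2f   p=%.2f", v,
         mean(clin[side == "train", v]), mean(clin[side == "test", v]),
         two_group_p(clin[[v]], side))
  }
  push("  %-10s A: %d/%d  B: %d/%d   p=%.2f", "scanner",
       sum(clin$scanner == "A" & side == "train"),
       sum(clin$scanner == "A" & side == "test"),
       sum(clin$scanner == "B" & side == "train"),
       sum(clin$scanner == "B" & side == "test"),
       two_group_p(clin$scanner, side))
  push("  %-10s %d/%d events  p=%.2f", "BCR",
       sum(clin$event[side == "train"]), sum(clin$event[side == "test"]),
       two_group_p(factor(clin$event), side))

  fmt_uni <- function(tab) {
    for (i in seq_len(nrow(tab)))
      push("  %-38s AUC %.2f  Se %3.0f  Sp %3.0f  cutoff %8.3g (%s)  p=%.4f",
           tab$variable[i], tab$auc[i], tab$sensitivity[i],
           tab$specificity[i], tab$cutoff[i], tab$orientation[i],
           tab$p_value[i])
  }
  push("=== Univariate analysis, clinical (training set) ===")
  fmt_uni(study$univariate_clinical)
  if (!is.null(study$univariate_radiomics)) {
    push("=== Univariate analysis, selected radiomic features ===")
    fmt_uni(study$univariate_radiomics)
  }
  push("=== Feature selection ===")
  push("  %d variant(s) analyzed, %d SMOTE row(s) added, %d selected",
       study$manifest$n_variants_analyzed,
       study$manifest$n_smote_synthetic, length(study$selection$selected))
  for (k in study$selection$selected)
    push("  %-38s mean |PC| %.3f (%d/%d subsamples)", k,
         study$selection$mean_abs_pc[k], study$selection$n_above[k],
         study$manifest$selection_config$n_subsamples)
  if (!is.null(study$multivariate)) {
    push("=== Multivariate Cox (training set, dichotomized) ===")
    for (i in seq_len(nrow(study$multivariate)))
      push("  %-38s HR %6.2f [%5.2f, %6.2f]  p=%.4f",
           study$multivariate$term[i], study$multivariate$hr[i],
           study$multivariate$ci_lo[i], study$multivariate$ci_hi[i],
           study$multivariate$p_value[i])
  }
  push("=== Model comparison ===")
  for (m in names(study$comparison$models)) {
    r <- study$comparison$models[[m]]
    if (is.null(r)) next
    push("  %-10s factors: %s", m, paste(r$factors, collapse = " + "))
    for (s in c("train", "test")) {
      e <- r[[s]]
      push("    %-5s AUC %.3f  Se %3.0f  Sp %3.0f  logrank p %s  HR %s",
           s, e$auc, e$sensitivity, e$specificity,
           ifelse(is.na(e$logrank_p), "NA",
                  format.pval(e$logrank_p, digits = 3)),
           ifelse(is.na(e$hr), "NA", sprintf("%.2f", e$hr)))
    }
  }
  cat(paste(out, collapse = "\n"), "\n")
  invisible(out)
}
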