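# ROC/Youden evaluation, Cox regression, Kaplan-Meier / log-rank, and the
# three-model comparison (clinical-only, radiomics-only, combined).

#' AUC by the rank statistic
#'
#' Computes the area under the ROC curve as the Mann-Whitney statistic with
#' mid-ranks for ties. When the raw AUC is below 0.5 the orientation is
#' flipped (low values predict the event) so the reported AUC is always
#' >= 0.5, with the flip recorded. The p-value (AUC vs 0.5) comes from the
#' two-sided Wilcoxon rank-sum test (exact for small samples without ties,
#' normal approximation otherwise).
#'
#' @param values Numeric marker vector.
#' @param labels 0/1 outcome vector containing both classes.
#' @return A `roc_result`: list with `auc`, `orientation` (`"high"` or
#'   `"low"`: which end of the marker predicts the event), `p_value`, `n1`,
#'   `n0`.
#' @export
roc_auc <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  if (length(unique(labels)) < 2)
    stop("roc_auc: labels must contain both classes")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(values)
  auc_raw <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  orientation <- if (auc_raw >= 0.5) "high" else "low"
  p <- suppressWarnings(
    wilcox.test(values[labels == 1], values[labels == 0])$p.value)
  structure(list(auc = max(auc_raw, 1 - auc_raw), orientation = orientation,
                 p_value = p, n1 = n1, n0 = n0),
            class = "roc_result")
}

classify_marker <- function(values, cutoff, orientation) {
  if (orientation == "high") as.integer(values > cutoff)
  else as.integer(values <= cutoff)
}

#' Youden-index operating cutoff
#'
#' Scans midpoints between consecutive sorted distinct marker values and
#' returns the cutoff maximizing `J = Se + Sp - 1` for the given
#' orientation (`"high"`: positive when value > cutoff; `"low"`: positive
#' when value <= cutoff). Ties in J are broken toward the cutoff with the
#' higher sensitivity.
#'
#' @param values Numeric marker vector.
#' @param labels 0/1 outcome vector.
#' @param orientation `"high"` or `"low"` (e.g. from [roc_auc()]).
#' @return List with `cutoff`, `sensitivity`, `specificity` (percent), `j`.
#' @export
youden_cutoff <- function(values, labels, orientation = "high") {
  v <- sort(unique(values))
  cands <- if (length(v) > 1) (head(v, -1) + v[-1]) / 2 else v
  best <- list(j = -Inf, sensitivity = -Inf)
  for (cand in cands) {
    pred <- classify_marker(values, cand, orientation)
    se <- 100 * sum(pred == 1 & labels == 1) / sum(labels == 1)
    sp <- 100 * sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- (se + sp) / 100 - 1
    if (j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && se > best$sensitivity)) {
      best <- list(cutoff = cand, sensitivity = se, specificity = sp, j = j)
    }
  }
  best
}

#' Resampling-stabilized Youden cutoff
#'
#' The single-sample Youden maximizer is highly unstable when events are
#' few; this variant takes the median of the Youden cutoffs over
#' stratified bootstrap replicates (cases and controls resampled
#' separately), then reports sensitivity/specificity of that stabilized
#' cutoff on the full sample. Deterministic: the bootstrap uses a fixed
#' internal seed.
#'
#' @inheritParams youden_cutoff
#' @param n_boot Bootstrap replicates (default 200).
#' @return List with `cutoff`, `sensitivity`, `specificity` (percent), `j`.
#' @export
youden_cutoff_stable <- function(values, labels, orientation = "high",
                                 n_boot = 200) {
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  cuts <- with_seed(1307L, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      youden_cutoff(values[idx], labels[idx], orientation)$cutoff
    }, numeric(1))
  })
  cutoff <- median(cuts)
  pred <- classify_marker(values, cutoff, orientation)
  se <- 100 * sum(pred == 1 & labels == 1) / sum(labels == 1)
  sp <- 100 * sum(pred == 0 & labels == 0) / sum(labels == 0)
  list(cutoff = cutoff, sensitivity = se, specificity = sp,
       j = (se + sp) / 100 - 1)
}

#' Univariate association report
#'
#' One row per variable mirroring a univariate-analysis table: AUC,
#' orientation, Youden cutoff, sensitivity, specificity and the AUC
#' p-value. Rows keep the column order of the input (deterministic).
#'
#' @param table Numeric matrix, subjects x variables.
#' @param labels 0/1 outcome per row.
#' @return Data frame with one row per variable.
#' @export
univariate_report <- function(table, labels) {
  stopifnot(is.matrix(table))
  rows <- lapply(colnames(table), function(k) {
    x <- table[, k]
    rr <- roc_auc(x, labels)
    yc <- youden_cutoff(x, labels, rr$orientation)
    data.frame(variable = k, auc = rr$auc, orientation = rr$orientation,
               cutoff = yc$cutoff, sensitivity = yc$sensitivity,
               specificity = yc$specificity, p_value = rr$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cox proportional-hazards fit
#'
#' Multivariate partial-likelihood fit (Efron tie handling) of the given
#' covariates, typically dichotomized by their training-side Youden
#' cutoffs. When the likelihood is monotone (complete separation drives a
#' coefficient to infinity) the fit is flagged and refit with a ridge
#' penalty so reported hazard ratios stay finite.
#'
#' @param covariates Numeric matrix or data frame, subjects x covariates.
#' @param times Follow-up or time-to-event (months), all > 0.
#' @param events 0/1 event indicator.
#' @return A `survival_fit`: data frame (`term`, `hr`, `ci_lo`, `ci_hi`,
#'   `p_value`) with attributes `loglik` and `penalized`.
#' @export
cox_fit <- function(covariates, times, events) {
  X <- as.matrix(covariates)
  stopifnot(nrow(X) == length(times), all(times > 0),
            all(events %in% c(0, 1)))
  df <- data.frame(X)
  df$.time <- times; df$.event <- events
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(df)[seq_len(ncol(X))]), collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || any(abs(stats::coef(fit)) > 15)) {
    separated <- TRUE
    pen <- paste(sprintf("`%s`", colnames(df)[seq_len(ncol(X))]),
                 collapse = ", ")
    fml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~ survival::ridge(",
      pen, ", theta = 1)"))
    fit <- suppressWarnings(
      survival::coxph(fml, data = df, ties = "efron"))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  out <- data.frame(term = colnames(X), hr = exp(beta),
                    ci_lo = exp(beta - 1.96 * se),
                    ci_hi = exp(beta + 1.96 * se),
                    p_value = 2 * pnorm(-abs(beta / se)),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "loglik") <- as.numeric(fit$loglik[length(fit$loglik)])
  attr(out, "penalized") <- separated
  class(out) <- c("survival_fit", "data.frame")
  out
}

#' Logistic odds-ratio cross-check
#'
#' Odds ratios for the binary outcome from a logistic model on the same
#' covariates, offered alongside [cox_fit()] as a sensitivity analysis.
#'
#' @param covariates Numeric matrix, subjects x covariates.
#' @param labels 0/1 outcome.
#' @return Data frame (`term`, `or`, `p_value`).
#' @export
odds_ratio_fit <- function(covariates, labels) {
  X <- as.matrix(covariates)
  df <- data.frame(X, .y = labels)
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, data = df, family = "binomial"))
  sm <- summary(fit)$coefficients[-1, , drop = FALSE]
  data.frame(term = colnames(X), or = exp(sm[, 1]), p_value = sm[, 4],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimates per group and the two-sided 1-df
#' log-rank test between two groups.
#'
#' @param groups Two-level group label per subject.
#' @param times Follow-up or time-to-event, all > 0.
#' @param events 0/1 event indicator.
#' @return List with `curves` (data frame of step coordinates per group:
#'   `group`, `time`, `n_risk`, `n_event`, `survival`), `chisq`, `p_value`.
#' @export
km_logrank <- function(groups, times, events) {
  stopifnot(length(groups) == length(times), all(times > 0),
            all(events %in% c(0, 1)))
  g <- factor(groups)
  df <- data.frame(.time = times, .event = events, .g = g)
  sf <- survival::survfit(survival::Surv(.time, .event) ~ .g, data = df)
  strata_names <- if (is.null(sf$strata)) levels(g)[1] else
    sub("^\\.g=", "", names(sf$strata))
  reps <- if (is.null(sf$strata)) length(sf$time) else sf$strata
  curves <- data.frame(group = rep(strata_names, reps),
                       time = sf$time, n_risk = sf$n.risk,
                       n_event = sf$n.event, survival = sf$surv,
                       stringsAsFactors = FALSE)
  if (nlevels(g) < 2) {
    chisq <- 0; p <- 1
  } else {
    sd_ <- survival::survdiff(survival::Surv(.time, .event) ~ .g, data = df)
    chisq <- as.numeric(sd_$chisq)
    p <- pchisq(chisq, df = nlevels(g) - 1, lower.tail = FALSE)
  }
  list(curves = curves, chisq = chisq, p_value = p)
}

#' Paired AUC comparison (DeLong)
#'
#' Two-sided DeLong test for the difference between the AUCs of two
#' markers measured on the same subjects, via the placement-value
#' covariance structure.
#'
#' @param x_a,x_b Marker vectors (higher = more event-like).
#' @param labels 0/1 outcome vector.
#' @return List with `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(x_a, x_b, labels) {
  cases <- labels == 1
  placements <- function(x) {
    xc <- x[cases]; xd <- x[!cases]
    v10 <- vapply(xc, function(v) mean((v > xd) + 0.5 * (v == xd)),
                  numeric(1))
    v01 <- vapply(xd, function(v) mean((xc > v) + 0.5 * (xc == v)),
                  numeric(1))
    list(v10 = v10, v01 = v01, auc = mean(v10))
  }
  pa <- placements(x_a); pb <- placements(x_b)
  m <- sum(cases); n <- sum(!cases)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  z <- if (v <= 0) 0 else (pa$auc - pb$auc) / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

# Additive model building on train-side binary risk factors. The anchor is
# a single factor: when a robustness ranking is supplied (mean |PC| over
# the stability subsamples, for selected radiomic features) the top-ranked
# factor anchors the model, otherwise the best single train AUC does. The
# best two-factor additive score replaces the anchor only when the DeLong
# paired test says it genuinely outperforms it, Bonferroni-adjusted for
# the number of candidate pairs scanned. With a handful of training
# events, resubstitution AUC of multi-factor scores overfits badly, so a
# combination has to demonstrate the improvement, mirroring the
# keep-the-single-feature-unless-a-combination-outperforms-it convention.
best_additive <- function(factors, labels, rank = NULL, max_size = 2,
                          alpha = 0.05) {
  if (is.null(factors) || ncol(factors) == 0) return(character(0))
  keys <- colnames(factors)
  score <- function(mm) rowSums(factors[, mm, drop = FALSE])
  score_auc <- function(mm) {
    sc <- score(mm)
    if (length(unique(sc)) < 2) 0.5 else roc_auc(sc, labels)$auc
  }
  anchor <- if (!is.null(rank) && any(keys %in% names(rank))) {
    rk <- rank[intersect(names(rank), keys)]
    names(rk)[order(-rk, names(rk))][1]
  } else {
    singles_auc <- vapply(keys, function(k) score_auc(k), numeric(1))
    keys[order(-singles_auc, keys)][1]
  }
  chosen <- anchor
  if (max_size >= 2 && length(keys) >= 2) {
    prs <- utils::combn(sort(keys), 2, simplify = FALSE)
    pair_auc <- vapply(prs, score_auc, numeric(1))
    labs <- vapply(prs, paste, character(1), collapse = " + ")
    top <- order(-pair_auc, labs)[1]
    if (pair_auc[top] > score_auc(anchor)) {
      dl <- delong_test(score(prs[[top]]), factors[, anchor], labels)
      if (dl$auc_a > dl$auc_b && dl$p_value < alpha / length(prs))
        chosen <- prs[[top]]
    }
  }
  chosen
}

score_model <- function(factor_matrix, members) {
  if (length(members) == 0) return(NULL)
  rowSums(factor_matrix[, members, drop = FALSE])
}

# raw rank AUC in a fixed orientation (high = event-like); unlike
# roc_auc() this may fall below 0.5, which is the honest report for a
# score whose orientation was frozen on the training side
auc_rank_raw <- function(values, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(values)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

eval_side <- function(score, labels, times, events, score_cutoff) {
  rr <- if (length(unique(score)) < 2 || length(unique(labels)) < 2)
    list(auc = 0.5, p_value = 1)
  else list(auc = auc_rank_raw(score, labels),
            p_value = roc_auc(score, labels)$p_value)
  grp <- classify_marker(score, score_cutoff, "high")
  se <- 100 * sum(grp == 1 & labels == 1) / max(1, sum(labels == 1))
  sp <- 100 * sum(grp == 0 & labels == 0) / max(1, sum(labels == 0))
  if (length(unique(grp)) < 2) {
    km <- list(p_value = NA_real_, chisq = NA_real_, curves = NULL)
    hr <- NA_real_; hr_p <- NA_real_
  } else {
    km <- km_logrank(grp, times, events)
    cx <- cox_fit(matrix(grp, ncol = 1, dimnames = list(NULL, "risk_group")),
                  times, events)
    hr <- cx$hr[1]; hr_p <- cx$p_value[1]
  }
  list(auc = rr$auc, auc_p = rr$p_value, sensitivity = se, specificity = sp,
       logrank_p = km$p_value, hr = hr, hr_p = hr_p, km = km)
}

#' Build and evaluate the three prognostic models
#'
#' On the training side each candidate variable (selected radiomic
#' features and clinical covariates) is dichotomized at its Youden cutoff
#' with the [roc_auc()] orientation; greedy additive combination then
#' builds the clinical-only and radiomics-only risk scores, and the
#' combined model pools both factor sets. All orientations, cutoffs and
#' score cutoffs are frozen on the training side before the testing side
#' is touched; the audit slot records them.
#'
#' @param radiomics_train,radiomics_test Numeric matrices of selected
#'   (harmonized) radiomic features; may have zero columns.
#' @param radiomics_rank Optional named robustness ranking of the radiomic
#'   features (e.g. mean |PC| from stability selection); when supplied, its
#'   top feature anchors the radiomics model.
#' @param clinical_train,clinical_test Numeric matrices of ordinal clinical
#'   covariates.
#' @param labels_train,labels_test 0/1 event indicators.
#' @param times_train,times_test Follow-up times (months).
#' @return A `model_comparison`: per model (`clinical`, `radiomics`,
#'   `combined`) and side (`train`, `test`), AUC, Se/Sp, log-rank p, HR;
#'   plus `factors` (model memberships) and `audit` (per-variable
#'   orientation and cutoff, score cutoffs).
#' @export
evaluate_models <- function(radiomics_train, radiomics_test,
                            clinical_train, clinical_test,
                            labels_train, labels_test,
                            times_train, times_test,
                            radiomics_rank = NULL) {
  dichotomize_side <- function(train_mat, test_mat) {
    audit <- list(); tr <- list(); te <- list()
    for (k in colnames(train_mat)) {
      x <- train_mat[, k]
      if (length(unique(x)) < 2) next  # uninformative on train side
      rr <- roc_auc(x, labels_train)
      yc <- youden_cutoff_stable(x, labels_train, rr$orientation)
      audit[[k]] <- list(orientation = rr$orientation, cutoff = yc$cutoff,
                         train_auc = rr$auc)
      tr[[k]] <- classify_marker(x, yc$cutoff, rr$orientation)
      te[[k]] <- classify_marker(test_mat[, k], yc$cutoff, rr$orientation)
    }
    list(train = do.call(cbind, tr), test = do.call(cbind, te),
         audit = audit)
  }
  rad <- dichotomize_side(radiomics_train, radiomics_test)
  cli <- dichotomize_side(clinical_train, clinical_test)

  members <- list(
    clinical = best_additive(cli$train, labels_train),
    radiomics = best_additive(rad$train, labels_train,
                              rank = radiomics_rank))
  members$combined <- c(members$clinical, members$radiomics)

  all_tr <- cbind(cli$train, rad$train)
  all_te <- cbind(cli$test, rad$test)
  results <- list()
  audit <- list(variables = c(cli$audit, rad$audit), score_cutoffs = list())
  for (m in names(members)) {
    if (length(members[[m]]) == 0) {
      results[[m]] <- NULL
      next
    }
    sc_tr <- score_model(all_tr, members[[m]])
    sc_te <- score_model(all_te, members[[m]])
    yc <- youden_cutoff_stable(sc_tr, labels_train, "high")
    audit$score_cutoffs[[m]] <- yc$cutoff
    results[[m]] <- list(
      factors = members[[m]],
      train = eval_side(sc_tr, labels_train, times_train,
                        labels_train, yc$cutoff),
      test = eval_side(sc_te, labels_test, times_test,
                       labels_test, yc$cutoff))
  }
  structure(list(models = results, factors = members, audit = audit),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (AUC / Se% / Sp% / log-rank p / HR)\n")
  for (m in names(x$models)) {
    r <- x$models[[m]]
    if (is.null(r)) next
    cat(sprintf("  %-10s factors: %s\n", m,
                paste(r$factors, collapse = " + ")))
    for (side in c("train", "test")) {
      s <- r[[side]]
      cat(sprintf("    %-5s AUC %.3f  Se %.0f  Sp %.0f  logrank p %s  HR %s\n",
                  side, s$auc, s$sensitivity, s$specificity,
                  format.pval(s$logrank_p, digits = 3),
                  ifelse(is.na(s$hr), "NA", sprintf("%.2f", s$hr))))
    }
  }
  invisible(x)
}
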