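# Clinical-table management: stratified train/test split, per-scanner
# z-score harmonization, SMOTE class rebalancing.

# Evaluate expr under a locally seeded RNG, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split of a cohort
#'
#' Randomly splits patients into training and testing sides at the given
#' ratio, stratified on (event, scanner) so both sides carry both scanners
#' and both outcome classes. Within each stratum the training count is
#' `round(ratio * n_stratum)` (half rounded up), so the realized overall
#' sizes may differ by one from `round(ratio * n)` depending on stratum
#' rounding. Reproducible from `seed`.
#'
#' @param cohort Data frame with columns `event` (0/1) and `scanner`.
#' @param ratio Training fraction (default 2/3).
#' @param seed Integer seed.
#' @return A `split_assignment`: list with `side` (character vector
#'   `"train"`/`"test"` per row), `ratio`, `seed`.
#' @export
split_cohort <- function(cohort, ratio = 2 / 3, seed = 1) {
  stopifnot(all(cohort$event %in% c(0, 1)))
  strata <- interaction(cohort$event, cohort$scanner, drop = TRUE)
  side <- rep("test", nrow(cohort))
  with_seed(seed, {
    for (s in levels(strata)) {
      idx <- which(strata == s)
      if (length(idx) < 3)
        warning("split_cohort: stratum '", s, "' has only ", length(idx),
                " member(s); assigned best-effort")
      n_tr <- round_half_up(ratio * length(idx))
      side[sample(idx, n_tr)] <- "train"
    }
  })
  structure(list(side = side, ratio = ratio, seed = seed),
            class = "split_assignment")
}

#' Per-scanner z-score harmonization
#'
#' Standardizes every feature to mean 0, sd 1 (n-1 denominator) within each
#' scanner group of one cohort side, removing affine inter-scanner
#' intensity distortions. Features with zero variance in any group are
#' dropped with a warning; groups of size 1 are set to 0 with a warning.
#'
#' @param table Numeric matrix, patients x features (rownames = patient
#'   ids, colnames = feature keys).
#' @param scanner Scanner label per row.
#' @return List with `table` (normalized matrix) and `params` (data frame
#'   of per scanner x feature mean and sd).
#' @export
zscore_by_scanner <- function(table, scanner) {
  stopifnot(is.matrix(table), nrow(table) == length(scanner))
  out <- table
  params <- list()
  drop <- logical(ncol(table))
  for (g in unique(scanner)) {
    rows <- scanner == g
    sub <- table[rows, , drop = FALSE]
    mu <- colMeans(sub)
    if (sum(rows) == 1) {
      warning("zscore_by_scanner: scanner group '", g,
              "' has a single member; its features set to 0")
      sg <- rep(1, ncol(sub))
      out[rows, ] <- 0
    } else {
      sg <- apply(sub, 2, sd)
      zero <- is.na(sg) | sg == 0
      drop <- drop | zero
      sg[zero] <- 1
      out[rows, ] <- sweep(sweep(sub, 2, mu), 2, sg, `/`)
    }
    params[[g]] <- data.frame(scanner = g, feature = colnames(table),
                              mean = unname(mu), sd = unname(sg),
                              stringsAsFactors = FALSE)
  }
  if (any(drop)) {
    warning("zscore_by_scanner: dropping ", sum(drop),
            " zero-variance feature(s): ",
            paste(head(colnames(table)[drop], 5), collapse = ", "),
            if (sum(drop) > 5) ", ..." else "")
    out <- out[, !drop, drop = FALSE]
  }
  list(table = out, params = do.call(rbind, params))
}

#' SMOTE minority oversampling
#'
#' Balances a binary-labeled feature table by adding synthetic minority
#' rows `x + u * (x_nn - x)`, `u ~ Uniform(0, 1)`, where `x_nn` is one of
#' the `k` nearest minority neighbors of `x` (Euclidean distance in the
#' given feature space). Original rows are preserved unchanged; base rows
#' are cycled so coverage of the minority class is even. An already
#' balanced table is returned unchanged.
#'
#' @param table Numeric matrix, patients x features.
#' @param labels 0/1 outcome per row.
#' @param k Neighbor count (default 5); reduced with a warning when the
#'   minority class has fewer than `k + 1` members.
#' @param seed Integer seed.
#' @return List with `table`, `labels` (augmented; synthetic rows appended,
#'   rownames `SMOTE_1`, ...), and `n_synthetic`.
#' @export
apply_smote <- function(table, labels, k = 5, seed = 1) {
  stopifnot(is.matrix(table), nrow(table) == length(labels),
            all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == n0)
    return(list(table = table, labels = labels, n_synthetic = 0L))
  minority <- if (n1 < n0) 1 else 0
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  if (n_min < 2)
    stop("apply_smote: minority class has fewer than 2 members")
  if (k > n_min - 1) {
    warning("apply_smote: k reduced from ", k, " to ", n_min - 1)
    k <- n_min - 1
  }
  n_needed <- abs(n0 - n1)
  Xm <- table[min_idx, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  synth <- matrix(NA_real_, n_needed, ncol(table))
  with_seed(seed, {
    for (s in seq_len(n_needed)) {
      b <- ((s - 1) %% n_min) + 1
      j <- nn[b, sample.int(k, 1)]
      u <- runif(1)
      synth[s, ] <- Xm[b, ] + u * (Xm[j, ] - Xm[b, ])
    }
  })
  colnames(synth) <- colnames(table)
  rownames(synth) <- sprintf("SMOTE_%d", seq_len(n_needed))
  list(table = rbind(table, synth),
       labels = c(labels, rep(minority, n_needed)),
       n_synthetic = n_needed)
}
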