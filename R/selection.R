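# Resampling-based stability feature selection.
#
# The training table (after SMOTE rebalancing) is sub-sampled 100 times at
# a 2:1 ratio with outcome stratification; a feature-variant is stable when
# its absolute point-biserial Pearson correlation with the outcome exceeds
# 0.3 in at least 95% of the subsamples. One variant per base feature is
# then kept (highest mean |PC|), and the survivors are greedily pruned so
# that no retained pair correlates above 0.7.

#' Selection configuration
#'
#' @param n_subsamples Number of stratified subsamples (default 100).
#' @param ratio Subsample fraction (default 2/3, i.e. a 2:1 split).
#' @param tau Stability fraction: a variant must clear the correlation
#'   threshold in at least `tau * n_subsamples` subsamples (default 0.95).
#' @param pc_min Absolute correlation threshold (default 0.3).
#' @param strict Whether `|PC| > pc_min` is strict (default TRUE) or
#'   inclusive.
#' @param pc_redundancy Redundancy threshold: survivors whose pairwise
#'   absolute correlation exceeds this are pruned (default 0.7).
#' @param smote Apply SMOTE rebalancing before selection (default TRUE).
#' @param k_smote SMOTE neighbor count (default 5).
#' @param seed Integer seed governing SMOTE and subsampling.
#' @return A `selection_config` list.
#' @export
selection_config <- function(n_subsamples = 100, ratio = 2 / 3, tau = 0.95,
                             pc_min = 0.3, strict = TRUE,
                             pc_redundancy = 0.7, smote = TRUE,
                             k_smote = 5, seed = 1) {
  stopifnot(pc_min > 0, pc_min < 1, tau > 0, tau <= 1,
            pc_redundancy > 0, pc_redundancy < 1)
  structure(list(n_subsamples = as.integer(n_subsamples), ratio = ratio,
                 tau = tau, pc_min = pc_min, strict = strict,
                 pc_redundancy = pc_redundancy, smote = smote,
                 k_smote = k_smote, seed = as.integer(seed)),
            class = "selection_config")
}

#' Stratified random subsamples
#'
#' Draws `n_subsamples` index sets, each holding `ratio` of the rows with
#' class proportions preserved to within one subject.
#'
#' @param labels 0/1 outcome vector.
#' @param config A [selection_config()].
#' @return List of integer index vectors.
#' @export
make_subsamples <- function(labels, config) {
  idx0 <- which(labels == 0); idx1 <- which(labels == 1)
  k0 <- round_half_up(config$ratio * length(idx0))
  k1 <- round_half_up(config$ratio * length(idx1))
  with_seed(config$seed + 1L, {
    lapply(seq_len(config$n_subsamples), function(i)
      sort(c(sample(idx0, k0), sample(idx1, k1))))
  })
}

#' Point-biserial correlation of a feature with a binary outcome
#'
#' The Pearson correlation between a real feature and the 0/1 outcome.
#' Zero variance in either argument yields 0 (such a feature can never
#' clear the stability threshold).
#'
#' @param values Numeric feature vector.
#' @param labels 0/1 outcome vector.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_with_outcome <- function(values, labels) {
  if (sd(values) == 0 || sd(labels) == 0) return(0)
  cor(values, labels)
}

# Correlations of every column of X with y; zero-variance columns -> 0.
cor_with_outcome <- function(X, y) {
  if (sd(y) == 0) return(rep(0, ncol(X)))
  r <- suppressWarnings(as.numeric(cor(X, y)))
  r[!is.finite(r)] <- 0
  r
}

#' Stability check over resampled correlations
#'
#' Computes, for every feature-variant, the absolute point-biserial
#' correlation with the outcome on each subsample; a variant passes when
#' the threshold `pc_min` is cleared in at least `tau * n_subsamples` of
#' them. All correlations are computed (no early exit) so the evidence can
#' be audited.
#'
#' @param table Numeric matrix (rows = subjects, possibly SMOTE-augmented).
#' @param labels 0/1 outcome per row.
#' @param config A [selection_config()].
#' @param subsamples Optional pre-drawn subsamples (from
#'   [make_subsamples()]).
#' @return A `stability_evidence` list: `abs_pc` (n_subsamples x variants
#'   matrix), `n_above` (count clearing the threshold), `pass` (logical),
#'   `mean_abs_pc`.
#' @export
stability_check <- function(table, labels, config,
                            subsamples = make_subsamples(labels, config)) {
  stopifnot(is.matrix(table), nrow(table) == length(labels))
  abs_pc <- matrix(NA_real_, length(subsamples), ncol(table),
                   dimnames = list(NULL, colnames(table)))
  for (i in seq_along(subsamples)) {
    idx <- subsamples[[i]]
    abs_pc[i, ] <- abs(cor_with_outcome(table[idx, , drop = FALSE],
                                        labels[idx]))
  }
  n_above <- if (config$strict) colSums(abs_pc > config$pc_min)
             else colSums(abs_pc >= config$pc_min)
  need <- ceiling(config$tau * length(subsamples) - 1e-9)
  structure(list(abs_pc = abs_pc, n_above = n_above,
                 pass = n_above >= need,
                 mean_abs_pc = colMeans(abs_pc)),
            class = "stability_evidence")
}

#' Keep the best variant of each base feature
#'
#' Among stable variants sharing a base feature (same sequence and feature
#' name, different sub-band/discretization), retains the one maximizing
#' mean |PC|; exact ties go to the lexicographically smallest key.
#'
#' @param evidence A `stability_evidence`.
#' @return Character vector of retained feature-variant keys.
#' @export
select_best_variant <- function(evidence) {
  keys <- names(evidence$pass)[evidence$pass]
  if (length(keys) == 0) return(character(0))
  base <- variant_base(keys)
  mpc <- evidence$mean_abs_pc[keys]
  keep <- character(0)
  for (b in sort(unique(base))) {
    cand <- sort(keys[base == b])
    keep <- c(keep, cand[which.max(mpc[cand])])
  }
  keep
}

#' Greedy redundancy pruning
#'
#' Ranks candidates by mean |PC| (descending, lexicographic tie-break) and
#' accepts each in turn unless its absolute Pearson correlation with an
#' already accepted candidate exceeds `rho`.
#'
#' @param table Numeric matrix holding at least the candidate columns.
#' @param candidates Candidate feature keys.
#' @param evidence A `stability_evidence` covering the candidates.
#' @param rho Redundancy threshold (default 0.7).
#' @return A `selection_result`: list with `selected`, `mean_abs_pc`,
#'   `n_above`, `pruned` (named by the accepted feature that displaced
#'   them), and `evidence`.
#' @export
prune_correlated <- function(table, candidates, evidence,
                             rho = 0.7) {
  ord <- candidates[order(-evidence$mean_abs_pc[candidates], candidates)]
  accepted <- character(0)
  pruned <- character(0)
  pruned_by <- character(0)
  for (k in ord) {
    if (length(accepted) == 0) { accepted <- k; next }
    cc <- abs(suppressWarnings(
      cor(table[, k], table[, accepted, drop = FALSE])))
    cc[!is.finite(cc)] <- 0
    if (any(cc > rho)) {
      pruned <- c(pruned, k)
      pruned_by <- c(pruned_by, accepted[which.max(cc)])
    } else accepted <- c(accepted, k)
  }
  structure(list(selected = accepted,
                 mean_abs_pc = evidence$mean_abs_pc[accepted],
                 n_above = evidence$n_above[accepted],
                 pruned = setNames(pruned_by, pruned),
                 evidence = evidence),
            class = "selection_result")
}

#' Run the full feature-selection workflow
#'
#' Composition: SMOTE rebalancing (unless disabled) -> stability check over
#' stratified subsamples -> best variant per base feature -> greedy
#' redundancy pruning. Fully reproducible from `config$seed`.
#'
#' @param table Numeric matrix of training-side feature variants.
#' @param labels 0/1 outcome per row.
#' @param config A [selection_config()].
#' @return A `selection_result` (see [prune_correlated()]); also carries
#'   `n_synthetic`, the number of SMOTE rows added.
#' @export
run_selection <- function(table, labels, config = selection_config()) {
  n_syn <- 0L
  if (config$smote && sum(labels == 1) != sum(labels == 0)) {
    sm <- apply_smote(table, labels, k = config$k_smote, seed = config$seed)
    table <- sm$table; labels <- sm$labels; n_syn <- sm$n_synthetic
  }
  ev <- stability_check(table, labels, config)
  cand <- select_best_variant(ev)
  res <- if (length(cand) == 0)
    structure(list(selected = character(0),
                   mean_abs_pc = numeric(0), n_above = integer(0),
                   pruned = character(0), evidence = ev),
              class = "selection_result")
  else prune_correlated(table, cand, ev, config$pc_redundancy)
  res$n_synthetic <- n_syn
  res$config <- config
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Stability selection result\n")
  cat(sprintf("  %d feature(s) selected", length(x$selected)))
  if (length(x$selected)) {
    cat(":\n")
    for (k in x$selected)
      cat(sprintf("    %-40s mean |PC| = %.3f (%d/%d subsamples)\n", k,
                  x$mean_abs_pc[k], x$n_above[k], nrow(x$evidence$abs_pc)))
  } else cat("\n")
  invisible(x)
}
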