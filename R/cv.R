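# ---- scenarios ---------------------------------------------------------------

#' Scenario outcome labels
#'
#' The three prediction scenarios: `any` (GPV in any predisposition gene),
#' `brca` (GPV in BRCA1/2), `other` (GPV in another predisposition gene).
#'
#' @param cohort labeled `drabc_cohort`.
#' @param scenario `"any"`, `"brca"` or `"other"`.
#' @return 0/1 integer vector.
#' @export
scenario_labels <- function(cohort, scenario = c("any", "brca", "other")) {
  scenario <- match.arg(scenario)
  stopifnot(has_labels(cohort))
  switch(scenario,
         any = as.integer(cohort$group != "non_carrier"),
         brca = as.integer(cohort$group %in% c("brca1", "brca2")),
         other = as.integer(cohort$group %in% c("other_hrr", "other_cpg")))
}

scenario_column <- function(scenario)
  c(any = "p_any", brca = "p_brca", other = "p_other")[[scenario]]

# AUC for one scenario of an ensemble on a cohort; NA when the scenario has
# a single class on this cohort
ensemble_auc <- function(model, cohort, scenario) {
  y <- scenario_labels(cohort, scenario)
  if (length(unique(y)) < 2L) return(NA_real_)
  pr <- predict(model, cohort)
  roc_auc(pr[[scenario_column(scenario)]], y)$auc
}

# ---- cross-validation --------------------------------------------------------

# stratified fold ids: within each carrier group, a seeded permutation is
# dealt round-robin over the k folds
stratified_folds <- function(group, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the ensemble
#'
#' Per fold: [train_ensemble()] on the remaining folds, AUC of the three
#' scenarios on the held-out fold. A fold without positives for a scenario
#' yields `NA` for that cell and is flagged.
#'
#' @param cohort labeled, complete `drabc_cohort`.
#' @param k number of folds (default 5).
#' @param seed integer seed controlling the fold assignment and training.
#' @param ... passed to [train_ensemble()] (e.g. `n_members`).
#' @return list: `folds` (assignment vector), `auc` (k x 3 matrix), and
#'   `mean_auc` (named, `NA` cells dropped).
#' @export
cross_validate <- function(cohort, k = 5L, seed = 1L, ...) {
  stopifnot(has_labels(cohort), k >= 2L)
  fold <- stratified_folds(cohort$group, k, seed)
  scen <- c("any", "brca", "other")
  auc <- matrix(NA_real_, k, 3L, dimnames = list(NULL, scen))
  for (f in seq_len(k)) {
    train <- subset_cohort(cohort, fold != f)
    test <- subset_cohort(cohort, fold == f)
    model <- train_ensemble(train, seed = as.integer(seed) + 1000L * f, ...)
    for (s in scen) auc[f, s] <- ensemble_auc(model, test, s)
  }
  list(folds = fold, auc = auc, mean_auc = colMeans(auc, na.rm = TRUE))
}

subset_cohort <- function(cohort, keep) {
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  out
}

# ---- feature ablation --------------------------------------------------------

#' Feature-block ablation
#'
#' Retrains the ensemble with a named feature block zeroed out (in both
#' training and evaluation encodings) and reports the test AUCs next to the
#' unablated baseline. Blocks are the `feature_groups` of the encoding spec
#' (`family_history`, `pathology`); the empty string `""` denotes the empty
#' ablation (baseline re-run).
#'
#' @param train,test labeled, complete `drabc_cohort`s.
#' @param feature_groups character vector of block names.
#' @param seed integer seed (shared across ablations so runs differ only by
#'   the zeroed block).
#' @param ... passed to [train_ensemble()].
#' @return data.frame: `ablation`, `scenario`, `auc`, `delta_vs_baseline`.
#' @export
ablate_features <- function(train, test,
                            feature_groups = c("family_history", "pathology"),
                            seed = 1L, ...) {
  spec <- encoding_spec()
  known <- names(spec$feature_groups)
  bad <- setdiff(setdiff(feature_groups, ""), known)
  if (length(bad))
    stop("unknown feature group(s): ", paste(bad, collapse = ", "),
         " (available: ", paste(known, collapse = ", "), ")")
  scen <- c("any", "brca", "other")
  run <- function(zero) {
    model <- train_ensemble(train, seed = seed, zero_features = zero, ...)
    vapply(scen, function(s) ensemble_auc(model, test, s), numeric(1))
  }
  base <- run(character(0))
  rows <- data.frame(ablation = "none", scenario = scen, auc = base,
                     delta_vs_baseline = 0)
  for (g in feature_groups) {
    a <- if (identical(g, "")) run(character(0)) else
      run(spec$feature_groups[[g]])
    rows <- rbind(rows, data.frame(
      ablation = if (identical(g, "")) "empty" else g,
      scenario = scen, auc = a, delta_vs_baseline = a - base))
  }
  rownames(rows) <- NULL
  rows
}
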