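# ---- feature encoding --------------------------------------------------------

#' The 25-feature encoding specification
#'
#' Defines the fixed numeric encoding that feeds the network's 25 input
#' neurons: standardized age at diagnosis (1), personal cancer-history flags
#' any/breast/ovarian (3), family-history flags breast/ovarian/pancreas/
#' male-breast/any (5), bilaterality (1), tumor size > 2 cm (1), grade II and
#' III indicators (2), IDC and DCIS histology indicators (2), ER/PR/AR/EGFR/
#' CK5-6 positivity (5), HER2 positive and HER2 uncertain indicators (2),
#' Ki67 > 30% (1), P53 gain-of-function (1), lymph-node positivity (1).
#' The all-reference patient (age = `age_center`, no history, unilateral,
#' size <= 2 cm, grade I, non-IDC/DCIS histology, all markers negative,
#' Ki67 low, P53 non-GoF, node-negative) encodes to the zero vector.
#'
#' `age_center`/`age_scale` are fixed from the training data by
#' [train_ensemble()] and serialized with the model so that validation
#' cohorts are encoded identically.
#'
#' @param age_center centering constant for age, years.
#' @param age_scale scaling constant for age, years (> 0).
#' @return An object of class `drabc_encoding`.
#' @export
encoding_spec <- function(age_center = 43.0, age_scale = 9.0) {
  stopifnot(is.numeric(age_scale), age_scale > 0)
  feature_order <- c(
    "age_std",
    "personal_any_cancer", "personal_breast_cancer", "personal_ovarian_cancer",
    "family_breast", "family_ovarian", "family_pancreas", "family_male_breast",
    "family_any",
    "bilateral",
    "size_gt2cm",
    "grade_ii", "grade_iii",
    "hist_idc", "hist_dcis",
    "er_positive", "pr_positive", "ar_positive", "egfr_positive",
    "ck56_positive",
    "her2_positive", "her2_uncertain",
    "ki67_high",
    "p53_gof",
    "nodes_positive")
  stopifnot(length(feature_order) == 25L)
  structure(list(
    feature_order = feature_order,
    age_center = age_center,
    age_scale = age_scale,
    # indicator definitions: encoded feature -> (column, level scoring 1)
    category_maps = list(
      size_gt2cm     = c(col = "tumor_size",  level = "gt2cm"),
      grade_ii       = c(col = "grade",       level = "ii"),
      grade_iii      = c(col = "grade",       level = "iii"),
      hist_idc       = c(col = "histology",   level = "idc"),
      hist_dcis      = c(col = "histology",   level = "dcis"),
      er_positive    = c(col = "er",          level = "positive"),
      pr_positive    = c(col = "pr",          level = "positive"),
      ar_positive    = c(col = "ar",          level = "positive"),
      egfr_positive  = c(col = "egfr",        level = "positive"),
      ck56_positive  = c(col = "ck5_6",       level = "positive"),
      her2_positive  = c(col = "her2",        level = "positive"),
      her2_uncertain = c(col = "her2",        level = "uncertain"),
      ki67_high      = c(col = "ki67",        level = "high"),
      p53_gof        = c(col = "p53",         level = "gof"),
      nodes_positive = c(col = "lymph_nodes", level = "positive")),
    required_flags = c("personal_any_cancer", "personal_breast_cancer",
                       "personal_ovarian_cancer", "bilateral"),
    required_categoricals = names(cohort_schema$categoricals),
    # ablation blocks (indices into feature_order)
    feature_groups = list(
      family_history = c("family_breast", "family_ovarian", "family_pancreas",
                         "family_male_breast", "family_any"),
      pathology = c("size_gt2cm", "grade_ii", "grade_iii", "hist_idc",
                    "hist_dcis", "er_positive", "pr_positive", "ar_positive",
                    "egfr_positive", "ck56_positive", "her2_positive",
                    "her2_uncertain", "ki67_high", "p53_gof",
                    "nodes_positive"))
  ), class = "drabc_encoding")
}

#' Encode a cohort as the network input matrix
#'
#' @param cohort a `drabc_cohort`, complete with respect to `spec`
#'   (see [is_complete()]); an unknown required level is an error.
#' @param spec an [encoding_spec()].
#' @return numeric matrix, one row per record, 25 named columns.
#' @export
encode_cohort <- function(cohort, spec = encoding_spec()) {
  stopifnot(inherits(spec, "drabc_encoding"))
  bad <- which(!is_complete(cohort, spec))
  if (length(bad))
    stop("record(s) incomplete with respect to the encoding spec: row ",
         paste(utils::head(bad, 5L), collapse = ", "))
  n <- nrow(cohort)
  X <- matrix(0, n, length(spec$feature_order),
              dimnames = list(cohort$patient_id, spec$feature_order))
  if (n == 0L) return(X)
  X[, "age_std"] <- (cohort$age_at_diagnosis - spec$age_center) / spec$age_scale
  for (f in c("personal_any_cancer", "personal_breast_cancer",
              "personal_ovarian_cancer", "family_breast", "family_ovarian",
              "family_pancreas", "family_male_breast", "family_any",
              "bilateral"))
    X[, f] <- as.numeric(cohort[[f]])
  for (f in names(spec$category_maps)) {
    m <- spec$category_maps[[f]]
    X[, f] <- as.numeric(cohort[[m[["col"]]]] == m[["level"]])
  }
  X
}

#' Encode a single patient record
#' @param record one-row `drabc_cohort` (or coercible data.frame).
#' @param spec an [encoding_spec()].
#' @return numeric vector of length 25.
#' @export
encode_features <- function(record, spec = encoding_spec()) {
  if (!inherits(record, "drabc_cohort")) record <- as_cohort(record)
  stopifnot(nrow(record) == 1L)
  drop(encode_cohort(record, spec))
}

# serialize/restore the encoding spec (stored inside the model container)
encoding_to_list <- function(spec) {
  list(feature_order = spec$feature_order, age_center = spec$age_center,
       age_scale = spec$age_scale)
}

encoding_from_list <- function(x) {
  spec <- encoding_spec(age_center = x$age_center, age_scale = x$age_scale)
  stopifnot(identical(spec$feature_order, unlist(x$feature_order,
                                                use.names = FALSE)))
  spec
}
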