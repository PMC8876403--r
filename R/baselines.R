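# ---- NCCN-style rule engine --------------------------------------------------

#' Default genetic-testing eligibility ruleset
#'
#' An editable encoding of the breast-cancer germline-testing indications
#' (guideline version 1.2020) that are expressible over the phenotype
#' record. Eligibility is the OR over rules; a rule touching an
#' unknown-valued field evaluates to FALSE for that record. The guideline
#' clause requiring two or more breast-cancer-affected relatives is not
#' expressible over a single family-history flag and is omitted (the
#' family-history flag still enters the 46-50 rule), so real-cohort
#' eligibility counts are approximated, not reproduced.
#'
#' @return object of class `drabc_ruleset`: list of rules, each
#'   `list(name, text, predicate)` where `predicate(cohort)` returns a
#'   logical vector.
#' @export
default_nccn_rules <- function() {
  rule <- function(name, text, predicate)
    list(name = name, text = text, predicate = predicate)
  false_if_na <- function(x) !is.na(x) & x
  rules <- list(
    rule("early_onset", "diagnosed at age <= 45",
         function(d) d$age_at_diagnosis <= 45),
    rule("age_46_50_second_criterion",
         paste("diagnosed 46-50 with a second primary (bilateral disease or",
               "previous breast cancer), a close relative with breast,",
               "ovarian, pancreatic or prostate cancer, or unknown family",
               "history"),
         function(d) d$age_at_diagnosis > 45 & d$age_at_diagnosis <= 50 &
           (false_if_na(d$bilateral == 1L) |
              false_if_na(d$personal_breast_cancer == 1L) |
              false_if_na(d$family_breast == 1L) |
              false_if_na(d$family_ovarian == 1L) |
              false_if_na(d$family_pancreas == 1L) |
              false_if_na(d$family_prostate == 1L) |
              is.na(d$family_any))),
    rule("tnbc_le_60", "triple-negative breast cancer diagnosed at <= 60",
         function(d) false_if_na(d$tnbc == 1L) & d$age_at_diagnosis <= 60),
    rule("family_ovarian_pancreatic_male_breast",
         paste("any age with a close relative with ovarian, pancreatic or",
               "male breast cancer"),
         function(d) false_if_na(d$family_ovarian == 1L) |
           false_if_na(d$family_pancreas == 1L) |
           false_if_na(d$family_male_breast == 1L)),
    rule("personal_ovarian", "personal history of ovarian cancer",
         function(d) false_if_na(d$personal_ovarian_cancer == 1L)),
    rule("bilateral_with_family_history",
         "bilateral breast cancer with any family cancer history",
         function(d) false_if_na(d$bilateral == 1L) &
           false_if_na(d$family_any == 1L)))
  structure(list(rules = rules, version_tag = "nccn-like-1.2020"),
            class = "drabc_ruleset")
}

#' Guideline eligibility
#'
#' TRUE when any rule of the ruleset fires. The per-record fired-rule
#' matrix is attached as attribute `"fired"` for audit.
#'
#' @param cohort a `drabc_cohort`.
#' @param rules a ruleset from [default_nccn_rules()].
#' @return logical vector with attribute `fired` (records x rules).
#' @export
nccn_eligible <- function(cohort, rules = default_nccn_rules()) {
  stopifnot(inherits(rules, "drabc_ruleset"))
  fired <- vapply(rules$rules,
                  function(r) {
                    v <- r$predicate(cohort)
                    v[is.na(v)] <- FALSE   # unknown field => rule silent
                    v
                  },
                  logical(nrow(cohort)))
  if (nrow(cohort) == 1L) fired <- matrix(fired, nrow = 1L)
  colnames(fired) <- vapply(rules$rules, `[[`, "", "name")
  structure(rowSums(fired) > 0, fired = fired)
}

#' Expanded eligibility: guideline OR diagnosis at <= 65
#'
#' @inheritParams nccn_eligible
#' @param age_cutoff expansion age, default 65.
#' @return logical vector (a superset of [nccn_eligible()]).
#' @export
nccn_expanded <- function(cohort, rules = default_nccn_rules(),
                          age_cutoff = 65) {
  as.logical(nccn_eligible(cohort, rules)) | cohort$age_at_diagnosis <= age_cutoff
}

# ---- reconstructed baselines -------------------------------------------------

# age bins shared by the baseline variable subsets (aligned with the rule
# cutpoints)
age_bin <- function(age)
  cut(age, breaks = c(-Inf, 40, 50, 65, Inf),
      labels = c("le40", "41_50", "51_65", "gt65"))

# design matrix for a named variable subset; variables are either encoded
# feature names or "age_class"
baseline_design <- function(cohort, subset) {
  spec <- encoding_spec()
  enc <- NULL
  cols <- list()
  for (v in subset) {
    if (v == "age_class") {
      ab <- age_bin(cohort$age_at_diagnosis)
      m <- stats::model.matrix(~ ab)[, -1, drop = FALSE]
      colnames(m) <- sub("^ab", "age_", colnames(m))
      cols[[v]] <- m
    } else if (v %in% spec$feature_order) {
      if (is.null(enc)) enc <- encode_cohort(cohort, spec)
      cols[[v]] <- matrix(enc[, v], ncol = 1, dimnames = list(NULL, v))
    } else stop("unknown baseline variable: ", v)
  }
  if (!length(cols)) return(matrix(numeric(0), nrow(cohort), 0))
  do.call(cbind, cols)
}

#' Default baseline variable subsets
#'
#' Reconstruction-style variable lists for the four classical carrier-risk
#' models: the two logistic reconstructions use family history (+ personal
#' factors), the two Bayes reconstructions use family history and age bins,
#' with the BOADICEA-like variant adding pathology (its distinguishing
#' feature). All overridable.
#' @return named list of character vectors.
#' @export
baseline_subsets <- function() {
  list(
    myriad_like = c("age_class", "family_breast", "family_ovarian"),
    penn2_like = c("age_class", "family_breast", "family_ovarian",
                   "bilateral", "personal_ovarian_cancer"),
    brcapro_like = c("age_class", "family_breast", "family_ovarian",
                     "family_male_breast"),
    boadicea_like = c("age_class", "family_breast", "family_ovarian",
                      "family_male_breast", "er_positive", "pr_positive",
                      "her2_positive", "grade_ii", "grade_iii"))
}

#' Logistic-regression baseline
#'
#' Maximum-likelihood logistic fit of a scenario target on a variable
#' subset. On (quasi-)separation the fit falls back to a ridge-penalized
#' logistic regression (glmnet, alpha = 0, lambda = 1e-3) and is flagged.
#'
#' @param cohort labeled, complete `drabc_cohort`.
#' @param subset variable names (encoded features and/or `"age_class"`);
#'   empty subset gives the intercept-only model.
#' @param target `"any"` or `"brca"` scenario.
#' @return object of class `drabc_logistic` with `coef`, `separation`,
#'   `converged`.
#' @export
fit_logistic_baseline <- function(cohort, subset,
                                  target = c("any", "brca")) {
  target <- match.arg(target)
  y <- scenario_labels(cohort, target)
  X <- baseline_design(cohort, subset)
  if (ncol(X) == 0) {
    fit <- glm(y ~ 1, family = binomial())
    return(structure(list(subset = subset, target = target,
                          coef = coef(fit), separation = FALSE,
                          converged = TRUE, family = "logistic"),
                     class = "drabc_logistic"))
  }
  fit <- suppressWarnings(glm(y ~ X, family = binomial()))
  separation <- !fit$converged || any(abs(coef(fit)[-1]) > 15)
  if (separation) {
    Xr <- if (ncol(X) == 1L) cbind(X, `.pad` = 0) else X  # glmnet needs >= 2
    rf <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    beta <- c(rf$a0, as.numeric(rf$beta))[seq_len(ncol(X) + 1L)]
  } else beta <- as.numeric(coef(fit))
  names(beta) <- c("(Intercept)", colnames(X))
  structure(list(subset = subset, target = target, coef = beta,
                 separation = separation,
                 converged = separation || fit$converged,
                 family = "logistic"),
            class = "drabc_logistic")
}

#' @export
predict.drabc_logistic <- function(object, cohort, ...) {
  X <- baseline_design(cohort, object$subset)
  eta <- object$coef[1] + if (ncol(X)) drop(X %*% object$coef[-1]) else 0
  sigmoid(eta)
}

#' Naive-Bayes baseline
#'
#' Class prior plus per-variable class-conditional tables (binary encoded
#' features and/or binned age) with add-`smooth` smoothing; the posterior
#' follows Bayes' theorem under conditional independence.
#'
#' @param cohort labeled, complete `drabc_cohort`.
#' @param subset variable names as in [fit_logistic_baseline()].
#' @param target `"any"` or `"brca"`.
#' @param smooth additive smoothing count (default 1; 0 disables).
#' @param prior optional class-1 prior overriding the sample prevalence.
#' @return object of class `drabc_nb`.
#' @export
fit_naive_bayes_baseline <- function(cohort, subset,
                                     target = c("any", "brca"),
                                     smooth = 1, prior = NULL) {
  target <- match.arg(target)
  y <- scenario_labels(cohort, target)
  vars <- nb_variables(cohort, subset)
  tables <- lapply(vars, function(v) {
    lev <- levels(v)
    t1 <- vapply(lev, function(l) sum(v == l & y == 1L), numeric(1))
    t0 <- vapply(lev, function(l) sum(v == l & y == 0L), numeric(1))
    rbind(class0 = (t0 + smooth) / sum(t0 + smooth),
          class1 = (t1 + smooth) / sum(t1 + smooth))
  })
  structure(list(subset = subset, target = target, tables = tables,
                 prior = prior %||% mean(y), family = "naive_bayes"),
            class = "drabc_nb")
}

# categorical view of the baseline variables (binary features as factors)
nb_variables <- function(cohort, subset) {
  spec <- encoding_spec()
  out <- list()
  for (v in subset) {
    if (v == "age_class") {
      out[[v]] <- age_bin(cohort$age_at_diagnosis)
    } else if (v %in% spec$feature_order) {
      out[[v]] <- factor(encode_cohort(cohort, spec)[, v], levels = c(0, 1))
    } else stop("unknown baseline variable: ", v)
  }
  out
}

#' @export
predict.drabc_nb <- function(object, cohort, ...) {
  vars <- nb_variables(cohort, object$subset)
  log1 <- log(object$prior) + numeric(nrow(cohort))
  log0 <- log(1 - object$prior) + numeric(nrow(cohort))
  for (v in names(object$tables)) {
    tab <- object$tables[[v]]
    idx <- match(as.character(vars[[v]]), colnames(tab))
    log1 <- log1 + log(tab["class1", idx])
    log0 <- log0 + log(tab["class0", idx])
  }
  1 / (1 + exp(log0 - log1))
}

# ---- model comparison --------------------------------------------------------

#' Score a model on a cohort for one scenario
#'
#' Common scoring interface used by [compare_models()]: implemented for the
#' ensemble, the two reconstructed baselines, plain numeric score vectors
#' and scoring functions `f(cohort)`.
#'
#' @param model a supported model object.
#' @param cohort a `drabc_cohort`.
#' @param scenario `"any"`, `"brca"` or `"other"`.
#' @return numeric score per record.
#' @export
model_scores <- function(model, cohort, scenario = "any") {
  if (inherits(model, "drabc_ensemble"))
    predict(model, cohort)[[scenario_column(scenario)]]
  else if (inherits(model, c("drabc_logistic", "drabc_nb")))
    predict(model, cohort)
  else if (is.function(model)) model(cohort)
  else if (is.numeric(model)) {
    stopifnot(length(model) == nrow(cohort))
    model
  } else stop("unsupported model object of class ",
              paste(class(model), collapse = "/"))
}

#' Compare risk models on one cohort and scenario
#'
#' Per model: midrank AUC with a DeLong 95% interval, confusion metrics and
#' Youden index at the model's threshold, and the paired DeLong test
#' against the reference model (the first in the list by default).
#' Thresholds: an ensemble uses its trained scenario cutoff; other models
#' use `thresholds[[name]]` when supplied, else the Youden-optimal
#' threshold on this cohort (flagged in the `threshold_rule` column).
#'
#' @param models named list of model objects (see [model_scores()]).
#' @param cohort labeled `drabc_cohort`.
#' @param scenario `"any"`, `"brca"` or `"other"`.
#' @param reference name (or index) of the reference model.
#' @param thresholds optional named numeric thresholds.
#' @return data.frame of class `drabc_eval`, one row per model.
#' @export
compare_models <- function(models, cohort, scenario = "any", reference = 1L,
                           thresholds = list()) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)) || any(names(models) == ""))
    stop("models must be a fully named list")
  y <- scenario_labels(cohort, scenario)
  if (length(unique(y)) < 2L)
    stop("scenario '", scenario, "' has a single class on this cohort")
  scores <- lapply(models, model_scores, cohort = cohort, scenario = scenario)
  ref_name <- if (is.numeric(reference)) names(models)[reference] else reference

  rows <- lapply(names(models), function(nm) {
    s <- scores[[nm]]
    ci <- delong_ci(s, y)
    if (!is.null(thresholds[[nm]])) {
      tau <- thresholds[[nm]]; rule <- "supplied"
    } else if (inherits(models[[nm]], "drabc_ensemble")) {
      tau <- as.numeric(models[[nm]]$thresholds[[
        c(any = "tau_any", brca = "tau_brca", other = "tau_other")[[scenario]]]])
      rule <- "model"
    } else {
      ra <- roc_auc(s, y)
      j <- ra$roc$tpr - ra$roc$fpr
      tau <- ra$roc$threshold[which.max(j)]
      rule <- "youden"
    }
    cm <- confusion_metrics(two_by_two(s >= tau, y))
    dl <- delong_test(s, scores[[ref_name]], y)
    data.frame(model = nm, auc = ci$auc, auc_lo = ci$lo, auc_hi = ci$hi,
               threshold = tau, threshold_rule = rule,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               accuracy = cm$accuracy, youden = cm$youden,
               delta_auc_vs_ref = dl$delta_auc, z_vs_ref = dl$z,
               p_vs_ref = dl$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref_name
  attr(out, "scenario") <- scenario
  class(out) <- c("drabc_eval", "data.frame")
  out
}
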