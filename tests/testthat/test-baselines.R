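# relabel a cohort's carrier groups from a 0/1 vector (brca1 as carrier)
relabel <- function(cohort, y) {
  df <- as.data.frame(cohort)
  df$group <- ifelse(y == 1L, "brca1", "non_carrier")
  df$variant_status <- ifelse(y == 1L, "pathogenic", "no_variant")
  as_cohort(df)
}

test_that("logistic baseline recovers known coefficients (simulation)", {
  subset <- c("family_breast", "family_ovarian", "bilateral")
  beta <- c(-2, 1.2, 0.8, 0.6)
  covered <- 0L; total <- 0L
  reps <- 20L
  for (r in seq_len(reps)) {
    co <- generate_cohort(5000, seed = 100 + r)
    X <- drabc:::baseline_design(co, subset)
    set.seed(200 + r)
    y <- rbinom(nrow(X), 1, plogis(beta[1] + drop(X %*% beta[-1])))
    fit <- fit_logistic_baseline(relabel(co, y), subset, target = "brca")
    g <- glm(y ~ X, family = binomial())
    ci <- suppressMessages(confint.default(g))
    covered <- covered + sum(ci[, 1] <= beta & beta <= ci[, 2])
    total <- total + length(beta)
    # and our fit equals the glm fit when there is no separation
    expect_equal(unname(fit$coef), unname(coef(g)), tolerance = 1e-8)
  }
  # per-coefficient 95% Wald coverage over 20 replicates x 4 coefficients
  expect_gte(covered / total, 0.90)
})

test_that("logistic baseline degenerate cases", {
  co <- generate_cohort(400, seed = 71)
  # empty subset: intercept-only, predicting the prevalence for everyone
  fit <- fit_logistic_baseline(co, character(0), target = "any")
  pr <- predict(fit, co)
  expect_equal(unique(round(pr, 12)),
               round(mean(scenario_labels(co, "any")), 12))

  # perfectly separable data: ridge fallback flagged, still near-perfect AUC
  y <- as.integer(co$family_breast == 1L)
  sep <- fit_logistic_baseline(relabel(co, y), "family_breast",
                               target = "brca")
  expect_true(sep$separation)
  expect_gt(roc_auc(predict(sep, co), y)$auc, 0.99)
})

test_that("naive Bayes reproduces hand-computed posteriors", {
  # carriers: 8/10 feature-positive; non-carriers: 2/10; prior 0.5
  y <- c(rep(1L, 10), rep(0L, 10))
  f <- c(rep(1L, 8), rep(0L, 2), rep(1L, 2), rep(0L, 8))
  rows <- lapply(seq_along(y), function(i)
    make_record(patient_id = sprintf("B%02d", i), family_breast = f[i],
                family_any = f[i]))
  co <- relabel(as_cohort(do.call(rbind, rows)), y)
  fit <- fit_naive_bayes_baseline(co, "family_breast", target = "brca",
                                  smooth = 0, prior = 0.5)
  pos <- predict(fit, co)[1]            # a feature-positive record
  neg <- predict(fit, co)[9]            # a feature-negative record
  expect_equal(unname(pos), 0.8)        # 0.8*0.5 / (0.8*0.5 + 0.2*0.5)
  expect_equal(unname(neg), 0.2)

  # posteriors over the two classes sum to 1 by construction
  expect_equal(unname(pos + (1 - pos)), 1)
})

test_that("class-independent features leave the posterior at the prior", {
  y <- rep(c(1L, 0L), each = 10)
  f <- rep(c(1L, 0L), 10)               # same rate in both classes
  rows <- lapply(seq_along(y), function(i)
    make_record(patient_id = sprintf("C%02d", i), family_ovarian = f[i],
                family_any = f[i]))
  co <- relabel(as_cohort(do.call(rbind, rows)), y)
  fit <- fit_naive_bayes_baseline(co, "family_ovarian", target = "brca",
                                  smooth = 0, prior = 0.3)
  expect_equal(unique(round(predict(fit, co), 12)), 0.3)
})

test_that("two-feature posterior factorizes into sequential updates", {
  set.seed(81)
  co <- generate_cohort(800, seed = 81)
  subset <- c("family_breast", "bilateral")
  fit2 <- fit_naive_bayes_baseline(co, subset, target = "any", smooth = 1)
  # sequential oracle: apply Bayes feature by feature on the odds scale
  odds <- fit2$prior / (1 - fit2$prior)
  spec <- encoding_spec()
  X <- encode_cohort(co, spec)
  for (v in subset) {
    tab <- fit2$tables[[v]]
    lr <- tab["class1", match(as.character(X[, v]), colnames(tab))] /
      tab["class0", match(as.character(X[, v]), colnames(tab))]
    odds <- odds * lr
  }
  expect_equal(unname(predict(fit2, co)), unname(odds / (1 + odds)),
               tolerance = 1e-12)
})

test_that("compare_models: self-comparison, row count, threshold rules", {
  co <- generate_cohort(500, seed = 91)
  sub <- baseline_subsets()
  models <- list(
    nb = fit_naive_bayes_baseline(co, sub$brcapro_like, target = "any"),
    lo = fit_logistic_baseline(co, sub$myriad_like, target = "any"))
  out <- compare_models(models, co, scenario = "any", reference = "nb")
  expect_equal(nrow(out), 2L)
  expect_equal(out$p_vs_ref[out$model == "nb"], 1)   # model vs itself
  expect_equal(out$delta_auc_vs_ref[out$model == "nb"], 0)
  expect_true(all(out$youden ==
                    out$sensitivity + out$specificity - 1))
  expect_error(compare_models(list(models[[1]]), co), "named")
})

test_that("pathology-blind models lose to pathology-aware ones when only
           pathology separates the classes", {
  tab <- pathology_only_table()
  deltas <- vapply(1:3, function(s) {
    co <- generate_cohort(2500, tab, seed = 300 + s)
    fam <- fit_naive_bayes_baseline(
      co, c("family_breast", "family_ovarian", "family_male_breast"),
      target = "any")
    path <- fit_logistic_baseline(
      co, c("er_positive", "pr_positive", "her2_positive", "grade_ii",
            "grade_iii", "ki67_high"), target = "any")
    y <- scenario_labels(co, "any")
    roc_auc(predict(path, co), y)$auc - roc_auc(predict(fam, co), y)$auc
  }, numeric(1))
  expect_gt(median(deltas), 0.05)
})
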