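# ---- synthetic cohort generator ---------------------------------------------

#' Generate a synthetic cohort
#'
#' Samples patients with the genotype-conditional phenotype structure of a
#' [default_frequency_table()]: the carrier group is multinomial in the
#' prevalences; age at diagnosis is Normal(mean_g, sd_g) truncated at 18
#' years (re-draw on violation) and rounded to 2 decimals; every flag and
#' categorical feature is drawn independently from its group-conditional
#' distribution -- with one exception: ER, PR and HER2 are drawn *jointly* so
#' that the derived triple-negative rate matches the group's published TNBC
#' rate while preserving the three marginals (see the methods vignette for
#' the construction; if the target rate is outside the feasible Frechet
#' bounds it is clipped and a warning is raised).
#'
#' Because features are conditionally independent given the group (the
#' published table provides marginals only), synthetic class separability
#' can exceed a real cohort's; green downstream tests certify the pipeline,
#' not clinical performance.
#'
#' @param n number of patients (>= 0).
#' @param table a `drabc_freq_table`.
#' @param seed integer; identical `(n, table, seed)` give identical cohorts.
#' @param missing_rate per-feature probability of masking a value as unknown
#'   (default 0 = fully observed), used to exercise the exclusion filter.
#' @param vus_rate probability that a record's `variant_status` is downgraded
#'   to `vus_only` (default 0).
#' @param id_prefix patient-id prefix.
#' @return A labeled `drabc_cohort`.
#' @export
generate_cohort <- function(n, table = default_frequency_table(), seed = 1L,
                            missing_rate = 0, vus_rate = 0,
                            id_prefix = "SYN") {
  stopifnot(inherits(table, "drabc_freq_table"), n >= 0,
            missing_rate >= 0, missing_rate <= 1, vus_rate >= 0, vus_rate <= 1)
  set.seed(as.integer(seed))
  groups <- table$groups
  g <- sample(groups, n, replace = TRUE, prob = table$prevalences)

  df <- data.frame(patient_id = sprintf("%s%06d", id_prefix, seq_len(n)),
                   stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
  # truncated-normal age, redraw below 18
  age <- rnorm(n, table$age_mean[g], table$age_sd[g])
  while (any(bad <- age < 18))
    age[bad] <- rnorm(sum(bad), table$age_mean[g[bad]], table$age_sd[g[bad]])
  df$age_at_diagnosis <- round(age, 2)

  for (f in rownames(table$flags))
    df[[f]] <- rbinom(n, 1L, table$flags[f, g])

  sample_level <- function(simplex) {
    # one categorical draw per record from its group's simplex
    u <- runif(n)
    cum <- apply(simplex, 2, cumsum)           # levels x groups
    lev <- rownames(simplex)
    out <- character(n)
    for (grp in groups) {
      sel <- g == grp
      if (!any(sel)) next
      out[sel] <- lev[findInterval(u[sel], c(0, cum[, grp]),
                                   rightmost.closed = TRUE)]
    }
    out
  }
  for (f in setdiff(names(table$categoricals), c("er", "pr", "her2")))
    df[[f]] <- sample_level(table$categoricals[[f]])

  eph <- sample_er_pr_her2(n, g, table)
  df$er <- eph$er; df$pr <- eph$pr; df$her2 <- eph$her2

  df$group <- g
  df$variant_status <- ifelse(g == "non_carrier", "no_variant", "pathogenic")
  if (vus_rate > 0) {
    vus <- runif(n) < vus_rate
    df$variant_status[vus] <- "vus_only"
  }
  if (missing_rate > 0) {
    for (f in rownames(table$flags))
      df[[f]][runif(n) < missing_rate] <- NA_integer_
    for (f in names(table$categoricals))
      df[[f]][runif(n) < missing_rate] <- "unknown"
  }
  as_cohort(df, provenance = sprintf("synthetic(seed=%d)", as.integer(seed)))
}

# Joint (ER, PR, HER2) draw matching the three marginals and the group TNBC
# rate. HER2 is drawn from its 3-level marginal; (ER, PR) from a 2x2 joint
# whose both-negative cell q_g solves t_g = q_g * P(HER2- | g) under
# (ER,PR) independent of HER2, clipped to the Frechet bounds
# [max(0, pE + pP - 1), min(pE, pP)] with a warning when clipping changes it.
sample_er_pr_her2 <- function(n, g, table) {
  groups <- table$groups
  her2_m <- table$categoricals$her2
  er_neg <- table$categoricals$er["negative", ]
  pr_neg <- table$categoricals$pr["negative", ]
  q <- table$tnbc / her2_m["negative", ]
  lo <- pmax(0, er_neg + pr_neg - 1)
  hi <- pmin(er_neg, pr_neg)
  clipped <- q < lo - 1e-12 | q > hi + 1e-12
  if (any(clipped))
    warning("TNBC target infeasible for group(s) ",
            paste(groups[clipped], collapse = ", "),
            "; clipped to the Frechet bound")
  q <- pmin(pmax(q, lo), hi)

  er <- pr <- her2 <- character(n)
  for (grp in groups) {
    sel <- which(g == grp)
    if (!length(sel)) next
    her2[sel] <- sample(rownames(her2_m), length(sel), replace = TRUE,
                        prob = her2_m[, grp])
    cells <- c(nn = q[[grp]],
               np = er_neg[[grp]] - q[[grp]],
               pn = pr_neg[[grp]] - q[[grp]],
               pp = 1 - er_neg[[grp]] - pr_neg[[grp]] + q[[grp]])
    cell <- sample(names(cells), length(sel), replace = TRUE, prob = cells)
    er[sel] <- ifelse(substr(cell, 1, 1) == "n", "negative", "positive")
    pr[sel] <- ifelse(substr(cell, 2, 2) == "n", "negative", "positive")
  }
  list(er = er, pr = pr, her2 = her2)
}

# ---- cohort summary ----------------------------------------------------------

#' Summarize a labeled cohort by carrier group
#'
#' Recreates the structure of a class-conditional characteristics table:
#' per group, age mean +/- SD and per-feature counts/proportions over known
#' values, with each carrier group tested against non-carriers (equal
#' variance t-test for age; Pearson chi-square, or Fisher's exact test when
#' any expected cell is below 5, for proportions; all two-sided).
#'
#' @param cohort labeled `drabc_cohort`.
#' @return list of class `drabc_summary` with data.frames `age`
#'   (group, n, mean, sd, p) and `features` (feature, level, group, count,
#'   denom, prop, p, test).
#' @export
summarize_cohort <- function(cohort) {
  stopifnot(has_labels(cohort))
  groups <- carrier_groups()
  present <- intersect(groups, unique(cohort$group))
  ref <- cohort$group == "non_carrier"

  age <- do.call(rbind, lapply(groups, function(grp) {
    sel <- cohort$group == grp
    p <- NA_real_
    if (grp != "non_carrier" && sum(sel) >= 2 && sum(ref) >= 2 &&
        (sd(cohort$age_at_diagnosis[sel]) > 0 ||
         sd(cohort$age_at_diagnosis[ref]) > 0))
      p <- t.test(cohort$age_at_diagnosis[sel], cohort$age_at_diagnosis[ref],
                  var.equal = TRUE)$p.value
    data.frame(group = grp, n = sum(sel),
               mean = if (any(sel)) mean(cohort$age_at_diagnosis[sel]) else NA,
               sd = if (sum(sel) > 1) sd(cohort$age_at_diagnosis[sel]) else NA,
               p = p)
  }))

  rows <- list()
  add_binary <- function(feature, level, yes, known) {
    # yes/known: logical vectors over records (known = value observed)
    for (grp in groups) {
      sel <- cohort$group == grp & known
      cnt <- sum(yes & sel); den <- sum(sel)
      p <- NA_real_; test <- NA_character_
      if (grp != "non_carrier") {
        rsel <- ref & known
        tab <- matrix(c(cnt, den - cnt, sum(yes & rsel),
                        sum(rsel) - sum(yes & rsel)), 2, byrow = TRUE)
        if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
          expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
          if (any(expct < 5)) {
            p <- fisher.test(tab)$p.value; test <- "fisher"
          } else {
            p <- chisq.test(tab, correct = FALSE)$p.value; test <- "chisq"
          }
        }
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        feature = feature, level = level, group = grp, count = cnt,
        denom = den, prop = if (den > 0) cnt / den else NA_real_,
        p = p, test = test)
    }
  }

  for (f in cohort_schema$flags)
    add_binary(f, "1", yes = !is.na(cohort[[f]]) & cohort[[f]] == 1L,
               known = !is.na(cohort[[f]]))
  for (f in names(cohort_schema$categoricals)) {
    known <- cohort[[f]] != "unknown"
    for (lev in cohort_schema$categoricals[[f]])
      add_binary(f, lev, yes = cohort[[f]] == lev, known = known)
  }
  add_binary("tnbc", "1", yes = !is.na(cohort$tnbc) & cohort$tnbc == 1L,
             known = !is.na(cohort$tnbc))

  structure(list(age = age, features = do.call(rbind, rows),
                 groups_present = present),
            class = "drabc_summary")
}

#' @export
print.drabc_summary <- function(x, ...) {
  cat("<drabc_summary>\n")
  print(x$age, row.names = FALSE)
  cat(sprintf("  %d feature/level/group rows in $features\n",
              nrow(x$features)))
  invisible(x)
}
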