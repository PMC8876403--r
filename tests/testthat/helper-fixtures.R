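# Programmatic fixtures: no data files, everything built in code.

# One complete patient row; override any field. Defaults are the
# "all-reference" patient (encodes to the zero vector at age_center = 43,
# see ?encoding_spec).
make_record <- function(patient_id = "P1", age_at_diagnosis = 43, ...) {
  rec <- list(
    patient_id = patient_id, age_at_diagnosis = age_at_diagnosis,
    personal_any_cancer = 0L, personal_breast_cancer = 0L,
    personal_ovarian_cancer = 0L,
    family_breast = 0L, family_ovarian = 0L, family_pancreas = 0L,
    family_prostate = 0L, family_esophageal = 0L, family_laryngeal = 0L,
    family_leukemia = 0L, family_male_breast = 0L, family_any = 0L,
    bilateral = 0L,
    tumor_size = "le2cm", histology = "lobular", grade = "i",
    er = "negative", pr = "negative", ar = "negative",
    her2 = "negative", ki67 = "low", egfr = "negative", ck5_6 = "negative",
    p53 = "wildtype", lymph_nodes = "negative",
    variant_status = "no_variant", group = "non_carrier")
  over <- list(...)
  rec[names(over)] <- over
  as.data.frame(rec, stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows))
    if (is.null(rows[[i]]$patient_id) || rows[[i]]$patient_id == "P1")
      rows[[i]]$patient_id <- sprintf("P%d", i)
  as_cohort(do.call(rbind, rows), provenance = "fixture")
}

# n_carrier carriers (group spread over brca1/brca2/other_cpg) embedded in a
# cohort of n records; used for split/fold arithmetic tests
labeled_toy_cohort <- function(n, n_carrier, seed = 1) {
  set.seed(seed)
  groups <- c(rep("brca1", ceiling(n_carrier / 2)),
              rep("brca2", floor(n_carrier / 2)),
              rep("non_carrier", n - n_carrier))
  rows <- lapply(seq_len(n), function(i)
    make_record(patient_id = sprintf("T%03d", i),
                age_at_diagnosis = round(runif(1, 25, 70), 2),
                group = groups[i],
                variant_status = if (groups[i] == "non_carrier")
                  "no_variant" else "pathogenic"))
  as_cohort(do.call(rbind, rows), provenance = "fixture")
}

# frequency table in which carrier groups differ from non-carriers ONLY in
# pathology features (age, history flags and bilaterality copied from the
# non-carrier column) -- the generative truth for the ablation-direction test
pathology_only_table <- function() {
  tab <- default_frequency_table()
  tab$age_mean[] <- tab$age_mean[["non_carrier"]]
  tab$age_sd[] <- tab$age_sd[["non_carrier"]]
  history <- c(grep("^personal_|^family_", rownames(tab$flags), value = TRUE),
               "bilateral")
  for (f in history) tab$flags[f, ] <- tab$flags[f, "non_carrier"]
  tab
}
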