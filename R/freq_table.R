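# ---- genotype-conditional frequency table -----------------------------------

#' Default genotype-conditional frequency table
#'
#' Per-carrier-group generative parameters for the synthetic cohort:
#' group prevalences, age-at-diagnosis mean/SD, per-flag probabilities and
#' per-categorical probability simplexes, plus the group TNBC rates used to
#' couple the ER/PR/HER2 draws. Values are the published class-conditional
#' cohort frequencies (proportions computed within each group's known-value
#' denominator; rows with no unknown mass use the full group size).
#'
#' Group sizes behind the table: 2347 phenotyped non-carriers, 131 BRCA1,
#' 132 BRCA2, 43 other-HRR and 26 other-CPG carriers; prevalences are taken
#' over all 2928 tested patients (332 carriers, 11.3%), assigning the
#' VUS-only patients' mass to the non-carrier group.
#'
#' @return An object of class `drabc_freq_table`.
#' @export
default_frequency_table <- function() {
  groups <- carrier_groups()
  n <- c(non_carrier = 2347, brca1 = 131, brca2 = 132,
         other_hrr = 43, other_cpg = 26)

  flag_counts <- rbind(
    personal_any_cancer     = c(113, 16, 18, 3, 2),
    personal_breast_cancer  = c(47, 14, 10, 1, 1),
    personal_ovarian_cancer = c(8, 1, 3, 0, 0),
    family_breast           = c(254, 54, 43, 7, 4),
    family_ovarian          = c(18, 19, 1, 0, 1),
    family_pancreas         = c(34, 4, 2, 4, 1),
    family_prostate         = c(10, 0, 0, 0, 0),
    family_esophageal       = c(82, 7, 3, 2, 1),
    family_laryngeal        = c(12, 2, 2, 0, 1),
    family_leukemia         = c(13, 1, 3, 0, 1),
    family_male_breast      = c(2, 0, 4, 0, 0),
    family_any              = c(726, 85, 71, 15, 12),
    bilateral               = c(52, 15, 11, 1, 1))
  colnames(flag_counts) <- groups
  flags <- sweep(flag_counts, 2, n, "/")

  cat_counts <- list(
    tumor_size = rbind(le2cm = c(1099, 51, 62, 18, 15),
                       gt2cm = c(899, 60, 56, 20, 7)),
    histology = rbind(idc       = c(1825, 122, 114, 38, 21),
                      dcis      = c(184, 0, 7, 2, 2),
                      lobular   = c(45, 1, 3, 1, 1),
                      mucinous  = c(45, 0, 2, 1, 0),
                      medullary = c(11, 2, 2, 0, 0),
                      other     = c(34, 2, 1, 0, 1)),
    grade = rbind(i   = c(139, 0, 2, 0, 0),
                  ii  = c(1004, 26, 67, 26, 10),
                  iii = c(587, 85, 35, 8, 6)),
    er = rbind(positive = c(1592, 34, 107, 30, 19),
               negative = c(612, 94, 22, 12, 6)),
    pr = rbind(positive = c(1571, 35, 107, 32, 18),
               negative = c(631, 93, 21, 10, 7)),
    ar = rbind(positive = c(710, 15, 33, 10, 11),
               negative = c(175, 50, 13, 8, 2)),
    her2 = rbind(positive  = c(507, 2, 6, 0, 7),
                 negative  = c(1317, 120, 103, 37, 17),
                 uncertain = c(342, 3, 18, 4, 2)),
    ki67 = rbind(low  = c(1254, 21, 74, 23, 16),
                 high = c(852, 98, 52, 17, 8)),
    egfr = rbind(positive = c(467, 72, 23, 9, 6),
                 negative = c(1026, 24, 75, 22, 11)),
    ck5_6 = rbind(positive = c(309, 61, 16, 10, 3),
                  negative = c(1382, 46, 89, 26, 20)),
    p53 = rbind(gof      = c(605, 46, 39, 10, 5),
                lof      = c(227, 33, 6, 4, 6),
                wildtype = c(629, 21, 55, 20, 7)),
    lymph_nodes = rbind(positive = c(892, 43, 75, 21, 14),
                        negative = c(1151, 76, 44, 16, 7)))
  categoricals <- lapply(cat_counts, function(m) {
    colnames(m) <- groups
    sweep(m, 2, colSums(m), "/")
  })

  new_frequency_table(
    prevalences = c(non_carrier = 2596, brca1 = 131, brca2 = 132,
                    other_hrr = 43, other_cpg = 26) / 2928,
    age_mean = c(non_carrier = 43.4, brca1 = 39.1, brca2 = 40.8,
                 other_hrr = 41.2, other_cpg = 40.5),
    age_sd = c(non_carrier = 9.1, brca1 = 8.4, brca2 = 8.0,
               other_hrr = 9.1, other_cpg = 7.6),
    flags = flags,
    categoricals = categoricals,
    tnbc = c(non_carrier = 303 / 2347, brca1 = 82 / 131, brca2 = 15 / 132,
             other_hrr = 8 / 43, other_cpg = 4 / 26))
}

#' Construct and validate a frequency table
#'
#' @param prevalences named probability vector over the five carrier groups,
#'   summing to 1.
#' @param age_mean,age_sd named numeric vectors per group (years; `age_sd` > 0).
#' @param flags matrix of flag probabilities, flags x groups.
#' @param categoricals named list of level x group probability-simplex
#'   matrices (each column sums to 1).
#' @param tnbc named vector of group triple-negative rates, used to couple
#'   the joint ER/PR/HER2 draw.
#' @return `drabc_freq_table`.
#' @export
new_frequency_table <- function(prevalences, age_mean, age_sd, flags,
                                categoricals, tnbc) {
  groups <- carrier_groups()
  stopifnot(identical(names(prevalences), groups),
            abs(sum(prevalences) - 1) < 1e-9,
            all(prevalences >= 0),
            all(age_sd > 0),
            identical(colnames(flags), groups),
            all(flags >= 0 & flags <= 1))
  for (nm in names(categoricals)) {
    m <- categoricals[[nm]]
    stopifnot(identical(colnames(m), groups), all(m >= 0 & m <= 1))
    if (any(abs(colSums(m) - 1) > 1e-9))
      stop("categorical simplex '", nm, "' does not sum to 1")
  }
  stopifnot(all(tnbc >= 0 & tnbc <= 1))
  structure(list(groups = groups, prevalences = prevalences,
                 age_mean = age_mean, age_sd = age_sd, flags = flags,
                 categoricals = categoricals, tnbc = tnbc),
            class = "drabc_freq_table")
}

#' @export
print.drabc_freq_table <- function(x, ...) {
  cat("<drabc_freq_table> prevalences:",
      paste(sprintf("%s=%.4f", names(x$prevalences), x$prevalences),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a frequency table (JSON)
#'
#' @param x a `drabc_freq_table`.
#' @param path file path.
#' @return `write_frequency_table` returns `path`; `read_frequency_table`
#'   returns the table.
#' @export
write_frequency_table <- function(x, path) {
  stopifnot(inherits(x, "drabc_freq_table"))
  payload <- list(prevalences = as.list(x$prevalences),
                  age_mean = as.list(x$age_mean),
                  age_sd = as.list(x$age_sd),
                  flags = mat_to_list(x$flags),
                  categoricals = lapply(x$categoricals, mat_to_list),
                  tnbc = as.list(x$tnbc))
  atomic_write(path, function(tmp)
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = I(17)))
  invisible(path)
}

#' @rdname write_frequency_table
#' @export
read_frequency_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_frequency_table(
    prevalences = unlist(x$prevalences),
    age_mean = unlist(x$age_mean), age_sd = unlist(x$age_sd),
    flags = list_to_mat(x$flags),
    categoricals = lapply(x$categoricals, list_to_mat),
    tnbc = unlist(x$tnbc))
}

mat_to_list <- function(m)
  lapply(seq_len(nrow(m)), function(i) as.list(m[i, , drop = TRUE])) |>
    setNames(rownames(m))

list_to_mat <- function(l) {
  m <- do.call(rbind, lapply(l, unlist))
  m[, carrier_groups(), drop = FALSE]
}
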