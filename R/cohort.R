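#' @useDynLib drabc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom predict pnorm qnorm var sd cov t.test
#'   chisq.test fisher.test binomial coef glm setNames
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# ---- schema ------------------------------------------------------------------

#' Cohort schema
#'
#' Column names, level sets and carrier-group labels of the cohort table.
#' A cohort is a `data.frame` of class `drabc_cohort` with one row per
#' patient. Binary flags are stored as integer 0/1 (`NA` = unknown),
#' categorical fields as lowercase character tokens with an explicit
#' `"unknown"` level.
#'
#' @format A named list with elements `flags`, `categoricals` (named list of
#'   level vectors, excluding `"unknown"`), `groups`, and `columns` (full
#'   column order of the CSV schema).
#' @export
cohort_schema <- local({
  flags <- c("personal_any_cancer", "personal_breast_cancer",
             "personal_ovarian_cancer",
             "family_breast", "family_ovarian", "family_pancreas",
             "family_prostate", "family_esophageal", "family_laryngeal",
             "family_leukemia", "family_male_breast", "family_any",
             "bilateral")
  categoricals <- list(
    tumor_size  = c("le2cm", "gt2cm"),
    histology   = c("idc", "dcis", "lobular", "mucinous", "medullary", "other"),
    grade       = c("i", "ii", "iii"),
    er          = c("positive", "negative"),
    pr          = c("positive", "negative"),
    ar          = c("positive", "negative"),
    her2        = c("positive", "negative", "uncertain"),
    ki67        = c("low", "high"),
    egfr        = c("positive", "negative"),
    ck5_6       = c("positive", "negative"),
    p53         = c("gof", "lof", "wildtype"),
    lymph_nodes = c("positive", "negative")
  )
  groups <- c("non_carrier", "brca1", "brca2", "other_hrr", "other_cpg")
  columns <- c("patient_id", "age_at_diagnosis", flags, names(categoricals),
               "tnbc", "variant_status", "group")
  list(flags = flags, categoricals = categoricals, groups = groups,
       columns = columns)
})

carrier_groups <- function() cohort_schema$groups
variant_statuses <- function() c("no_variant", "pathogenic", "vus_only",
                                 "untested")

# Derive the triple-negative flag from ER/PR/HER2; NA when any of the three
# is unknown (the derivation is only defined on known values).
derive_tnbc <- function(er, pr, her2) {
  ifelse(er == "unknown" | pr == "unknown" | her2 == "unknown", NA_integer_,
         as.integer(er == "negative" & pr == "negative" & her2 == "negative"))
}

#' Construct a cohort
#'
#' Validates a patient table against the cohort schema and returns a
#' `drabc_cohort`. The `tnbc` column, if absent, is derived from ER/PR/HER2;
#' if present it is checked against the derivation wherever all three markers
#' are known.
#'
#' @param df data.frame following [cohort_schema] (`group`/`variant_status`
#'   may be absent for prediction-only use).
#' @param provenance source tag stored as an attribute.
#' @return A `drabc_cohort` data.frame.
#' @export
as_cohort <- function(df, provenance = "user") {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- setdiff(cohort_schema$columns,
                  c("tnbc", "variant_status", "group"))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort is missing mandatory column(s): ", paste(miss, collapse = ", "))

  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         df$patient_id[duplicated(df$patient_id)][1L])
  df$age_at_diagnosis <- as.numeric(df$age_at_diagnosis)
  if (nrow(df) && any(!is.finite(df$age_at_diagnosis) |
                      df$age_at_diagnosis <= 0))
    stop("age_at_diagnosis must be a positive number for every record (row ",
         which(!is.finite(df$age_at_diagnosis) | df$age_at_diagnosis <= 0)[1L],
         ")")

  for (f in cohort_schema$flags) {
    v <- df[[f]]
    if (is.logical(v)) v <- as.integer(v)
    v <- suppressWarnings(as.integer(as.character(v)))
    bad <- !is.na(v) & !(v %in% c(0L, 1L))
    if (any(bad)) stop("flag column '", f, "' must be 0/1/blank (row ",
                       which(bad)[1L], ")")
    df[[f]] <- v
  }
  for (f in names(cohort_schema$categoricals)) {
    v <- tolower(trimws(as.character(df[[f]])))
    v[is.na(v) | v == ""] <- "unknown"
    ok <- c(cohort_schema$categoricals[[f]], "unknown")
    bad <- !(v %in% ok)
    if (any(bad)) stop("column '", f, "': unknown level '", v[bad][1L],
                       "' (row ", which(bad)[1L], ")")
    df[[f]] <- v
  }

  tnbc <- derive_tnbc(df$er, df$pr, df$her2)
  if (!is.null(df$tnbc)) {
    given <- suppressWarnings(as.integer(as.character(df$tnbc)))
    chk <- !is.na(tnbc) & !is.na(given) & given != tnbc
    if (any(chk)) stop("tnbc column contradicts ER/PR/HER2 at row ",
                       which(chk)[1L])
  }
  df$tnbc <- tnbc

  if (is.null(df$variant_status)) {
    df$variant_status <- NA_character_
  } else {
    v <- tolower(trimws(as.character(df$variant_status)))
    v[is.na(v) | v == ""] <- NA_character_
    bad <- !is.na(v) & !(v %in% variant_statuses())
    if (any(bad)) stop("bad variant_status '", v[bad][1L], "' (row ",
                       which(bad)[1L], ")")
    df$variant_status <- v
  }
  if (is.null(df$group)) {
    df$group <- NA_character_
  } else {
    g <- tolower(trimws(as.character(df$group)))
    g[is.na(g) | g == ""] <- NA_character_
    bad <- !is.na(g) & !(g %in% carrier_groups())
    if (any(bad)) stop("bad carrier group '", g[bad][1L], "' (row ",
                       which(bad)[1L], ")")
    df$group <- g
  }
  # default variant_status from the label when labels are present
  fill <- is.na(df$variant_status) & !is.na(df$group)
  df$variant_status[fill] <-
    ifelse(df$group[fill] == "non_carrier", "no_variant", "pathogenic")

  df <- df[, cohort_schema$columns]
  rownames(df) <- NULL
  structure(df, class = c("drabc_cohort", "data.frame"),
            provenance = provenance)
}

#' @export
print.drabc_cohort <- function(x, ...) {
  cat(sprintf("<drabc_cohort> %d patients (provenance: %s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  if (has_labels(x)) {
    tb <- table(factor(x$group, levels = carrier_groups()))
    cat("  groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  } else cat("  unlabeled\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Does a cohort carry carrier labels?
#' @param cohort a `drabc_cohort`.
#' @return TRUE when every record has a carrier group.
#' @export
has_labels <- function(cohort) nrow(cohort) > 0 && !anyNA(cohort$group)

#' Hierarchical label encoding
#'
#' Maps the five-group carrier label onto the two binary targets of the
#' hierarchical model: `y_any` (1 for any carrier) and `y_brca` (1 for a
#' BRCA1/2 carrier, 0 for another-CPG carrier, `NA` -- undefined -- for
#' non-carriers, whose second-stage term is masked in the loss).
#'
#' @param group character vector of carrier groups.
#' @return data.frame with columns `y_any`, `y_brca`.
#' @export
carrier_targets <- function(group) {
  stopifnot(all(group %in% carrier_groups()))
  y_any <- as.integer(group != "non_carrier")
  y_brca <- ifelse(y_any == 0L, NA_integer_,
                   as.integer(group %in% c("brca1", "brca2")))
  data.frame(y_any = y_any, y_brca = y_brca)
}

# ---- CSV i/o -----------------------------------------------------------------

#' Read a cohort CSV
#'
#' Comma-separated, UTF-8, `.` decimal; blank cells and the literal
#' `"unknown"` both map to the field's unknown level. Header matching is
#' case-insensitive.
#'
#' @param path CSV file.
#' @param label_mode `"optional"` (default) or `"required"`; with
#'   `"required"` an unlabeled record is an error.
#' @return A `drabc_cohort`.
#' @export
load_cohort <- function(path, label_mode = c("optional", "required")) {
  label_mode <- match.arg(label_mode)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  cohort <- as_cohort(df, provenance = path)
  if (label_mode == "required" && !has_labels(cohort))
    stop("label_mode = 'required' but ", sum(is.na(cohort$group)),
         " record(s) have no carrier group")
  cohort
}

#' Write a cohort CSV
#' @param cohort a `drabc_cohort`.
#' @param path output file (written atomically).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  atomic_write(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE, na = ""))
  invisible(path)
}

# write via temp file + rename so a failure leaves no partial output
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {   # cross-device fallback
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# ---- completeness & exclusions ----------------------------------------------

#' Record completeness with respect to an encoding spec
#'
#' A record is complete when its age is finite, none of the flags required by
#' the spec (which always include every family-history flag) is `NA`, and no
#' required categorical field is `"unknown"`.
#'
#' @param cohort a `drabc_cohort`.
#' @param spec an [encoding_spec()].
#' @return logical vector, one entry per record.
#' @export
is_complete <- function(cohort, spec = encoding_spec()) {
  ok <- is.finite(cohort$age_at_diagnosis)
  for (f in union(spec$required_flags,
                  grep("^family_", cohort_schema$flags, value = TRUE)))
    ok <- ok & !is.na(cohort[[f]])
  for (f in spec$required_categoricals)
    ok <- ok & cohort[[f]] != "unknown"
  ok
}

#' Apply the model-construction exclusion filters
#'
#' Removes (1) patients whose genetic test found only variants of uncertain
#' significance and (2) patients with incomplete clinical information or
#' family cancer history. A record qualifying for both is counted once,
#' under the VUS reason.
#'
#' @param cohort labeled `drabc_cohort`.
#' @param spec encoding spec defining the required fields.
#' @return list with elements `cohort` (retained records) and `report`
#'   (named counts: `vus`, `incomplete`, `retained`).
#' @export
apply_exclusions <- function(cohort, spec = encoding_spec()) {
  stopifnot(has_labels(cohort) || nrow(cohort) == 0)
  vus <- !is.na(cohort$variant_status) & cohort$variant_status == "vus_only"
  incomplete <- !is_complete(cohort, spec) & !vus
  keep <- !vus & !incomplete
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  list(cohort = out,
       report = c(vus = sum(vus), incomplete = sum(incomplete),
                  retained = sum(keep)))
}

# ---- stratified split --------------------------------------------------------

#' Stratified train/test split
#'
#' Disjoint partition preserving the five-group proportions. Rounding rule:
#' the first part receives `floor(fraction * n)` records in total,
#' allocated over carrier groups by the largest-remainder method starting
#' from `floor(fraction * n_g)` per group, so every group lands within one
#' record of its proportional share. Members are chosen by a seeded
#' permutation within each group.
#'
#' @param cohort labeled `drabc_cohort`.
#' @param fraction proportion assigned to the first part, in (0, 1).
#' @param seed integer seed; identical seeds give identical splits.
#' @return list of two `drabc_cohort`s (`train`, `test`).
#' @export
stratified_split <- function(cohort, fraction, seed) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  stopifnot(has_labels(cohort))
  set.seed(as.integer(seed))
  groups <- intersect(carrier_groups(), unique(cohort$group))
  n_g <- vapply(groups, function(g) sum(cohort$group == g), integer(1))
  base <- floor(fraction * n_g)
  rem <- fraction * n_g - base
  extra <- floor(fraction * nrow(cohort)) - sum(base)
  if (extra > 0) {
    bump <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[bump] <- base[bump] + 1L
  }
  take <- logical(nrow(cohort))
  for (i in seq_along(groups)) {
    idx <- which(cohort$group == groups[i])
    take[idx[sample.int(length(idx))][seq_len(base[i])]] <- TRUE
  }
  split_one <- function(keep) {
    out <- cohort[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "provenance") <- attr(cohort, "provenance")
    class(out) <- class(cohort)
    out
  }
  list(train = split_one(take), test = split_one(!take))
}
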