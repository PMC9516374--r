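# Cohort data model: reading, validation, schema, and history assembly.

outcome_cols <- function() {
  c("hba1c_t0", "hba1c_t6", "hba1c_t12", "eq5d_t0", "eq5d_t6", "eq5d_t12")
}

rec_cols <- function() {
  c(paste0("s1_", rec_types()), paste0("s2_", rec_types()))
}

required_cols <- function() c("patient_id", outcome_cols(), rec_cols())

#' Build or infer a cohort schema
#'
#' The schema describes the covariate columns of a cohort table: everything
#' that is not the patient id, an outcome column (`hba1c_*`, `eq5d_*`) or a
#' recommendation-count column (`s1_*`, `s2_*`). Each covariate has a type
#' (`numeric` or `categorical`) and a timepoint: `baseline` covariates enter
#' the stage-1 history, `month6` covariates (names ending in `_t6`) enter the
#' stage-2 history only. Columns ending in `_t12` are post-horizon and are
#' never used as features.
#'
#' @param data a data.frame to infer from, or `NULL` to describe explicitly.
#' @param covariates optional data.frame with columns name, type, timepoint
#'   overriding inference.
#' @return data.frame of class `qc_schema` with columns name, type, timepoint.
#' @export
cohort_schema <- function(data = NULL, covariates = NULL) {
  if (is.null(covariates)) {
    stopifnot(!is.null(data))
    nm <- setdiff(names(data), required_cols())
    nm <- nm[!endsWith(nm, "_t12")]
    covariates <- data.frame(
      name = nm,
      type = vapply(nm, function(v)
        if (is.numeric(data[[v]])) "numeric" else "categorical", character(1)),
      timepoint = ifelse(endsWith(nm, "_t6"), "month6", "baseline"),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "type", "timepoint") %in% names(covariates)),
            all(covariates$type %in% c("numeric", "categorical")),
            all(covariates$timepoint %in% c("baseline", "month6")))
  rownames(covariates) <- NULL
  structure(covariates, class = c("qc_schema", "data.frame"))
}

new_cohort <- function(data, schema) {
  structure(data, schema = schema, class = c("qc_cohort", "data.frame"))
}

#' Read a cohort from a delimited text file
#'
#' Expects a header row with the required columns: `patient_id`, the six
#' outcome columns (`hba1c_t0/t6/t12`, `eq5d_t0/t6/t12`), the 18
#' recommendation-count columns (`s1_<type>`, `s2_<type>` for the 9 types of
#' [rec_types()]), plus any covariate columns. Patients missing any of the six
#' outcome values, with a nonpositive HbA1c, or with unparseable required
#' fields are excluded (the reward is undefined without them); the exclusion
#' count is logged. Covariate missingness is passed through as `NA`.
#'
#' @param path path to a comma- (default) or tab-delimited UTF-8 text file.
#' @param schema optional [cohort_schema()]; inferred from the file if `NULL`.
#'   When supplied, covariate columns named in the schema must be present.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`.tsv`/`.tab` = tab, otherwise comma).
#' @return a `qc_cohort` data.frame with a `schema` attribute and a `dropped`
#'   attribute (named integer vector of exclusion counts by reason).
#' @export
read_cohort <- function(path, schema = NULL, sep = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing <- setdiff(required_cols(), names(raw))
  if (length(missing))
    stop("cohort file is missing required columns: ",
         paste(missing, collapse = ", "))
  if (!is.null(schema)) {
    miss_cov <- setdiff(schema$name, names(raw))
    if (length(miss_cov))
      stop("cohort file is missing schema covariates: ",
           paste(miss_cov, collapse = ", "))
  }
  for (v in c(outcome_cols(), rec_cols()))
    raw[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  raw$patient_id <- as.character(raw$patient_id)

  dropped <- c(missing_outcome = 0L, nonpositive_hba1c = 0L, bad_counts = 0L)
  bad_out <- !stats::complete.cases(raw[, outcome_cols()])
  hb <- as.matrix(raw[, c("hba1c_t0", "hba1c_t6", "hba1c_t12")])
  bad_hb <- !bad_out & apply(hb <= 0, 1, any)
  cm <- as.matrix(raw[, rec_cols()])
  bad_cnt <- !bad_out & !bad_hb & apply(is.na(cm), 1, any)
  dropped["missing_outcome"] <- sum(bad_out)
  dropped["nonpositive_hba1c"] <- sum(bad_hb)
  dropped["bad_counts"] <- sum(bad_cnt)
  keep <- !(bad_out | bad_hb | bad_cnt)
  if (any(!keep))
    qc_log("read_cohort: excluded ", sum(!keep), " of ", nrow(raw),
           " rows (missing_outcome=", dropped[1], ", nonpositive_hba1c=",
           dropped[2], ", bad_counts=", dropped[3], ")", level = "warn")
  data <- raw[keep, , drop = FALSE]
  rownames(data) <- NULL
  if (is.null(schema)) schema <- cohort_schema(data)
  out <- new_cohort(data, schema)
  attr(out, "dropped") <- dropped
  out
}

#' Construct a cohort from an in-memory data.frame
#'
#' For cohorts built programmatically (simulation, tests). Checks the required
#' columns are present and attaches a schema.
#'
#' @param data data.frame with the required cohort columns.
#' @param schema optional [cohort_schema()]; inferred when `NULL`.
#' @return a `qc_cohort`.
#' @export
as_cohort <- function(data, schema = NULL) {
  missing <- setdiff(required_cols(), names(data))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  data$patient_id <- as.character(data$patient_id)
  if (is.null(schema)) schema <- cohort_schema(data)
  new_cohort(as.data.frame(data), schema)
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: writing then re-reading yields an identical
#' cohort table.
#'
#' @param cohort a `qc_cohort` (or compatible data.frame).
#' @param path output path; `.tsv` extension selects tab separation.
#' @param sep optional separator override.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path)) "\t" else ","
  atomic_write(function(tmp)
    utils::write.table(as.data.frame(cohort), tmp, sep = sep,
                       row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8"),
    path)
}

#' Validate a cohort and report rule violations
#'
#' Reporting only; the cohort is returned unchanged. Rules: duplicate patient
#' ids, nonpositive HbA1c values, negative recommendation counts, non-integer
#' recommendation counts, missing outcome values.
#'
#' @param cohort a cohort data.frame.
#' @return list of class `qc_validation` with per-rule violation counts and
#'   `n_patients`; serializes directly to JSON.
#' @export
validate_cohort <- function(cohort) {
  cm <- as.matrix(cohort[, intersect(rec_cols(), names(cohort)), drop = FALSE])
  hb <- as.matrix(cohort[, intersect(c("hba1c_t0", "hba1c_t6", "hba1c_t12"),
                                     names(cohort)), drop = FALSE])
  out <- cohort[, intersect(outcome_cols(), names(cohort)), drop = FALSE]
  rep <- list(
    n_patients = nrow(cohort),
    duplicate_id = sum(duplicated(cohort$patient_id)),
    nonpositive_hba1c = sum(hb <= 0, na.rm = TRUE),
    negative_count = sum(cm < 0, na.rm = TRUE),
    noninteger_count = sum(cm != round(cm), na.rm = TRUE),
    missing_outcome = sum(!stats::complete.cases(out))
  )
  structure(rep, class = "qc_validation")
}

#' @export
print.qc_validation <- function(x, ...) {
  cat("Cohort validation (n =", x$n_patients, "patients)\n")
  for (nm in setdiff(names(x), "n_patients"))
    cat(sprintf("  %-18s %d\n", nm, x[[nm]]))
  invisible(x)
}

# ordinal-encode one categorical column against a manifest entry;
# unseen categories map to the designated code 0, NA stays NA
encode_categorical <- function(values, categories) {
  code <- match(as.character(values), categories)
  unseen <- is.na(code) & !is.na(values)
  if (any(unseen)) {
    qc_log("assemble_histories: ", sum(unseen),
           " value(s) outside the encoding manifest mapped to the unseen code",
           level = "warn")
    code[unseen] <- 0L
  }
  code
}

#' Assemble per-stage history feature matrices
#'
#' Stage-1 features are the baseline covariates (numeric as-is, categoricals
#' ordinal-encoded in lexicographic category order). Stage-2 features append
#' the encoded stage-1 action (focus ordinal + intensity binary) and the
#' 6-month covariates, so the stage-2 history strictly contains the stage-1
#' history plus the stage-1 action. The encoding manifest is deterministic and
#' returned for reuse at prediction time; categories absent from the manifest
#' map to a designated unseen code (0) with a logged warning.
#'
#' @param cohort a cohort data.frame with a schema attribute (see
#'   [read_cohort()]).
#' @param actions shaped actions data.frame from [shape_actions()] (stage-1
#'   rows are required).
#' @param manifest optional encoding manifest from a previous call (named list
#'   of category vectors); fit from the cohort when `NULL`.
#' @return list of class `qc_histories`: `stage1` and `stage2` numeric
#'   matrices (same patient order), `manifest`, `patient_id`.
#' @export
assemble_histories <- function(cohort, actions, manifest = NULL) {
  schema <- attr(cohort, "schema")
  if (is.null(schema)) schema <- cohort_schema(cohort)
  cats <- schema$name[schema$type == "categorical"]
  if (is.null(manifest))
    manifest <- lapply(stats::setNames(nm = cats), function(v)
      sort(unique(as.character(cohort[[v]][!is.na(cohort[[v]])]))))

  col_of <- function(v) {
    if (v %in% names(manifest)) encode_categorical(cohort[[v]], manifest[[v]])
    else as.numeric(cohort[[v]])
  }
  base_vars <- schema$name[schema$timepoint == "baseline"]
  m6_vars <- schema$name[schema$timepoint == "month6"]
  stage1 <- vapply(base_vars, col_of, numeric(nrow(cohort)))
  if (nrow(cohort) == 1L)
    stage1 <- matrix(stage1, nrow = 1, dimnames = list(NULL, base_vars))

  a1 <- actions[actions$stage == 1, ]
  a1 <- a1[match(cohort$patient_id, a1$patient_id), ]
  if (any(is.na(a1$focus))) stop("stage-1 actions missing for some patients")
  a1_enc <- encode_action(a1$focus, a1$intensity)
  m6 <- if (length(m6_vars)) {
    mm <- vapply(m6_vars, col_of, numeric(nrow(cohort)))
    if (nrow(cohort) == 1L) mm <- matrix(mm, nrow = 1, dimnames = list(NULL, m6_vars))
    mm
  } else NULL
  stage2 <- cbind(stage1, a1_focus = a1_enc[, "a_focus"],
                  a1_high = a1_enc[, "a_high"])
  if (!is.null(m6)) stage2 <- cbind(stage2, m6)
  structure(list(stage1 = stage1, stage2 = stage2, manifest = manifest,
                 patient_id = cohort$patient_id),
            class = "qc_histories")
}
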