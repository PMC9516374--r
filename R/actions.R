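#' The nine coaching-recommendation types
#'
#' Canonical column suffixes for the per-stage recommendation counts, in the
#' order used throughout the package. Counts appear in cohort tables as
#' `s1_<type>` and `s2_<type>`.
#'
#' @return character vector of length 9.
#' @export
rec_types <- function() {
  c("diet", "exercise", "behavior_mod",
    "med_adherence", "med_adjust", "glucose_monitor",
    "psych_support", "case_mgmt", "system_nav")
}

#' @noRd
focus_levels <- function() {
  c("behavior_modification_education", "case_management_monitoring",
    "psychological_support", "general")
}

#' @noRd
intensity_levels <- function() c("low", "high")

# fixed expert grouping of the 9 recommendation types into 3 focus categories
default_category_map <- function() {
  list(
    behavior_modification_education = c("diet", "exercise", "behavior_mod"),
    case_management_monitoring = c("med_adherence", "med_adjust",
                                   "glucose_monitor", "case_mgmt", "system_nav"),
    psychological_support = "psych_support"
  )
}

#' Enumerate the shaped action space
#'
#' The 8 shaped actions (4 focus categories x 2 intensity levels) in canonical
#' order: focus categories in their listed order, `low` before `high` within a
#' focus. The canonical order defines deterministic tie-breaking everywhere an
#' argmax over actions is taken.
#'
#' @return data.frame with columns `focus` and `intensity` (both factors) and
#'   8 rows.
#' @export
action_levels <- function() {
  grid <- expand.grid(intensity = intensity_levels(), focus = focus_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("focus", "intensity")]
  grid$focus <- factor(grid$focus, levels = focus_levels())
  grid$intensity <- factor(grid$intensity, levels = intensity_levels())
  rownames(grid) <- NULL
  grid
}

# integer id 1..8 in canonical order
action_id <- function(focus, intensity) {
  f <- match(as.character(focus), focus_levels())
  i <- match(as.character(intensity), intensity_levels())
  (f - 1L) * 2L + i
}

action_from_id <- function(id) {
  action_levels()[id, , drop = FALSE]
}

# numeric encoding used as regressor features: ordinal focus code + binary intensity
encode_action <- function(focus, intensity) {
  cbind(a_focus = match(as.character(focus), focus_levels()),
        a_high = as.numeric(as.character(intensity) == "high"))
}

#' Shaping configuration
#'
#' Parameters of the action-space shaping rule: the fixed 9-to-3 grouping of
#' recommendation types, the dominance ratio a category must reach over each
#' other category to define the coaching focus, and the intensity threshold
#' (the cohort median of per-patient per-stage recommendation totals, fit from
#' data when `NULL`).
#'
#' @param dominance_ratio positive number, >= 1; a focus category must have at
#'   least `dominance_ratio` times as many recommendations as each other
#'   category (default 2).
#' @param intensity_median nonnegative number or `NULL` (fit from data).
#' @param category_map named list mapping the 3 focus categories to the 9
#'   recommendation types; each type must appear exactly once.
#' @return object of class `shaping_config`.
#' @export
shaping_config <- function(dominance_ratio = 2, intensity_median = NULL,
                           category_map = default_category_map()) {
  stopifnot(is.numeric(dominance_ratio), dominance_ratio >= 1)
  if (!is.null(intensity_median))
    stopifnot(is.numeric(intensity_median), intensity_median >= 0)
  members <- sort(unlist(category_map, use.names = FALSE))
  if (!identical(members, sort(rec_types())))
    stop("category_map must cover all 9 recommendation types exactly once")
  structure(list(dominance_ratio = dominance_ratio,
                 intensity_median = intensity_median,
                 category_map = category_map),
            class = "shaping_config")
}

#' Group recommendation counts into the three focus categories
#'
#' @param counts named numeric vector (or 1-row data.frame) with one
#'   nonnegative count per recommendation type, or a matrix/data.frame with
#'   one column per type (names from [rec_types()]).
#' @param config a [shaping_config()].
#' @return matrix with one column per focus category; totals are preserved.
#' @export
categorize_recommendations <- function(counts, config = shaping_config()) {
  m <- if (is.matrix(counts) || is.data.frame(counts)) as.matrix(counts)
       else matrix(counts, nrow = 1, dimnames = list(NULL, names(counts)))
  missing <- setdiff(rec_types(), colnames(m))
  if (length(missing)) stop("missing recommendation types: ",
                            paste(missing, collapse = ", "))
  if (any(m < 0, na.rm = TRUE)) stop("recommendation counts must be nonnegative")
  out <- vapply(config$category_map,
                function(members) rowSums(m[, members, drop = FALSE]),
                numeric(nrow(m)))
  if (nrow(m) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(config$category_map)))
  out
}

#' Classify the coaching focus from the three category counts
#'
#' A category is the focus iff its count is at least `dominance_ratio` times
#' each other category's count and strictly positive; otherwise (including
#' all-zero stages and non-unique winners) the focus is `general`.
#'
#' @param category_counts numeric vector of 3 counts (ordered as the category
#'   map) or a matrix with 3 columns.
#' @param config a [shaping_config()].
#' @return factor with levels from the 4 focus categories.
#' @export
classify_focus <- function(category_counts, config = shaping_config()) {
  m <- if (is.matrix(category_counts)) category_counts else
    matrix(category_counts, nrow = 1)
  r <- config$dominance_ratio
  lab <- apply(m, 1, function(cc) {
    win <- which(vapply(seq_along(cc), function(j)
      cc[j] > 0 && all(cc[j] >= r * cc[-j]), logical(1)))
    if (length(win) == 1L) names(config$category_map)[win] else "general"
  })
  factor(lab, levels = focus_levels())
}

#' Classify coaching intensity from the total recommendation count
#'
#' Totals strictly above the median threshold are `high`; totals at or below
#' it are `low` (ties map to `low`).
#'
#' @param total_count nonnegative numeric vector of per-stage totals.
#' @param config a [shaping_config()] with `intensity_median` set.
#' @return factor with levels `low`, `high`.
#' @export
classify_intensity <- function(total_count, config) {
  if (is.null(config$intensity_median))
    stop("intensity_median is not set; fit it with shape_actions()")
  factor(ifelse(total_count > config$intensity_median, "high", "low"),
         levels = intensity_levels())
}

# per-patient per-stage counts matrix from a cohort data.frame
stage_counts <- function(cohort, stage) {
  cols <- paste0("s", stage, "_", rec_types())
  m <- as.matrix(cohort[, cols, drop = FALSE])
  colnames(m) <- rec_types()
  m
}

#' Shape raw recommendation counts into per-stage actions
#'
#' Applies the full shaping rule to every patient and stage: groups the 9
#' recommendation types into 3 focus categories, applies the dominance rule
#' for focus, and thresholds the per-stage total at the cohort median for
#' intensity. When `config$intensity_median` is `NULL` it is fit as the median
#' of per-patient totals pooled over both stages (one threshold for the whole
#' cohort, reproducing the single cohort-level median).
#'
#' @param cohort a cohort data.frame (see [read_cohort()]).
#' @param config a [shaping_config()].
#' @return list with `actions` (data.frame: patient_id, stage, focus,
#'   intensity, total), the fitted `config`, and `summary` (per-stage counts
#'   of patients in each focus-by-intensity cell).
#' @export
shape_actions <- function(cohort, config = shaping_config()) {
  totals <- lapply(1:2, function(s) rowSums(stage_counts(cohort, s)))
  if (is.null(config$intensity_median)) {
    config$intensity_median <- stats::median(unlist(totals))
    qc_log("fitted intensity median: ", config$intensity_median, level = "debug")
  }
  rows <- lapply(1:2, function(s) {
    cats <- categorize_recommendations(stage_counts(cohort, s), config)
    data.frame(patient_id = cohort$patient_id, stage = s,
               focus = classify_focus(cats, config),
               intensity = classify_intensity(totals[[s]], config),
               total = totals[[s]], stringsAsFactors = FALSE)
  })
  actions <- do.call(rbind, rows)
  rownames(actions) <- NULL
  list(actions = actions, config = config, summary = action_table(actions))
}

#' Tabulate shaped actions by stage
#'
#' The intervention-options summary: number of patients assigned each
#' focus-by-intensity action in each stage.
#'
#' @param actions the `actions` data.frame from [shape_actions()].
#' @return data.frame with columns focus, intensity, stage1_n, stage2_n.
#' @export
action_table <- function(actions) {
  al <- action_levels()
  n1 <- integer(nrow(al)); n2 <- integer(nrow(al))
  for (k in seq_len(nrow(al))) {
    sel <- actions$focus == al$focus[k] & actions$intensity == al$intensity[k]
    n1[k] <- sum(sel & actions$stage == 1)
    n2[k] <- sum(sel & actions$stage == 2)
  }
  cbind(al, stage1_n = n1, stage2_n = n2)
}
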