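# Column contracts for the three component tables. Extra ego columns are
# allowed (covariates carried from a host survey); tie and nomination columns
# are fixed.
.ego_required_cols <- c("ego_id", "sex")
.ego_known_cols <- c("ego_id", "sex", "tobacco_use", "bodyweight_class", "city")

.tie_cols <- c("ego_id", "position", "alter_label", "alter_sex", "relationship",
               "residence", "talk_own_health_freq", "talk_alter_health_freq",
               "contacted_14d", "snack_days_14d", "meal_days_14d",
               "exercised_14d", "walked_tasks_14d", "meal_prep_shop_14d",
               "tobacco_co_use_14d", "alter_tobacco_use",
               "alter_bodyweight_vs_ego")

.nom_cols <- c("ego_id", "emergency_contact_pos", "health_problem_pos",
               "overwhelmed_contact_pos")

.day_count_cols <- c("snack_days_14d", "meal_days_14d")

#' Assemble a survey dataset
#'
#' A `survey_dataset` bundles the three tables produced by an egocentric
#' roster instrument — one row per respondent (ego), one row per nominated
#' ego-alter tie, and one row per ego for the network-level nominations
#' (emergency contact, health-problem contact, contact when overwhelmed) —
#' together with the codebook in force.
#'
#' Ties are ordered by closeness: `position` 1 is the alter the ego named
#' first ("the person you are closest to"), and positions within an ego must
#' form a contiguous run 1, 2, ... up to the nomination cap.
#'
#' @param egos Tibble with at least `ego_id` and `sex` (`"female"`/`"male"`);
#'   optional `tobacco_use` (logical), `bodyweight_class`, `city`, and any
#'   further covariate columns.
#' @param ties Tibble with one row per nominated alter; see the package
#'   vignette for the full column contract. Missing columns are added as `NA`.
#' @param nominations Tibble with `ego_id` and the three nomination position
#'   columns (`NA` = no choice made). Egos absent from the table are treated
#'   as having made no nominations.
#' @param codebook An [default_codebook()] object.
#' @param check If `TRUE` (default), stop when [validate_dataset()] reports
#'   violations.
#' @return An object of class `survey_dataset`.
#' @export
#' @examples
#' ds <- survey_dataset(
#'   egos = tibble::tibble(ego_id = "e1", sex = "female"),
#'   ties = tibble::tibble(ego_id = "e1", position = 1L,
#'                         relationship = "husband", alter_sex = "male")
#' )
#' network_size(ds$ties)
survey_dataset <- function(egos, ties = NULL, nominations = NULL,
                           codebook = default_codebook(), check = TRUE) {
  stopifnot(inherits(codebook, "ego_codebook"))
  egos <- tibble::as_tibble(egos)
  missing_cols <- setdiff(.ego_required_cols, names(egos))
  if (length(missing_cols)) {
    stop("ego table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(ties)) {
    ties <- tibble::tibble(ego_id = egos$ego_id[0])
  }
  ties <- tibble::as_tibble(ties)
  if (!"ego_id" %in% names(ties)) stop("tie table lacks `ego_id`")
  for (col in setdiff(.tie_cols, names(ties))) {
    ties[[col]] <- if (col %in% c("position")) NA_integer_ else NA
  }
  ties <- ties[.tie_cols]
  ties$position <- as.integer(ties$position)
  for (col in .day_count_cols) ties[[col]] <- as.integer(ties[[col]])
  for (col in c("contacted_14d", "exercised_14d", "walked_tasks_14d",
                "meal_prep_shop_14d", "tobacco_co_use_14d",
                "alter_tobacco_use")) {
    ties[[col]] <- as.logical(ties[[col]])
  }
  for (col in c("ego_id", "alter_label", "alter_sex", "relationship",
                "residence", "talk_own_health_freq",
                "talk_alter_health_freq", "alter_bodyweight_vs_ego")) {
    ties[[col]] <- as.character(ties[[col]])
  }
  egos$ego_id <- as.character(egos$ego_id)
  egos$sex <- as.character(egos$sex)
  if ("tobacco_use" %in% names(egos)) {
    egos$tobacco_use <- as.logical(egos$tobacco_use)
  }
  for (col in intersect(c("bodyweight_class", "city"), names(egos))) {
    egos[[col]] <- as.character(egos[[col]])
  }
  ties <- dplyr::arrange(ties, .data$ego_id, .data$position)

  if (is.null(nominations)) {
    nominations <- tibble::tibble(ego_id = character(0),
                                  emergency_contact_pos = integer(0),
                                  health_problem_pos = integer(0),
                                  overwhelmed_contact_pos = integer(0))
  }
  nominations <- tibble::as_tibble(nominations)
  if (!"ego_id" %in% names(nominations)) stop("nomination table lacks `ego_id`")
  for (col in setdiff(.nom_cols, names(nominations))) {
    nominations[[col]] <- NA_integer_
  }
  nominations <- nominations[.nom_cols]
  nominations$ego_id <- as.character(nominations$ego_id)
  for (col in .nom_cols[-1]) {
    nominations[[col]] <- as.integer(nominations[[col]])
  }

  ds <- structure(
    list(egos = egos, ties = ties, nominations = nominations,
         codebook = codebook),
    class = "survey_dataset"
  )
  if (check) {
    report <- validate_dataset(ds)
    if (nrow(report)) {
      stop("invalid survey dataset (", nrow(report), " violation(s)); first: ",
           report$rule[1], " - ", report$detail[1],
           ". Run validate_dataset() for the full report.")
    }
  }
  ds
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat("<survey_dataset>\n")
  cat("  egos:", nrow(x$egos), "  ties:", nrow(x$ties),
      "  nominations:", nrow(x$nominations), "\n")
  cat("  nomination cap:", x$codebook$nomination_cap, "\n")
  invisible(x)
}

.violation <- function(ego_id, rule, detail) {
  tibble::tibble(ego_id = as.character(ego_id), rule = rule, detail = detail)
}

#' Validate a survey dataset
#'
#' Checks every schema invariant and returns the complete list of violations
#' rather than stopping at the first: unique ego identifiers, non-missing ego
#' sex, ties and nominations joining to existing egos, unique and contiguous
#' closeness positions starting at 1, the nomination cap, day counts within
#' 0-14, known relationship / residence / bodyweight / talk-frequency codes,
#' and nomination positions referring to existing ties.
#'
#' The function never mutates its input and is idempotent; an empty report
#' means the dataset is valid.
#'
#' @param dataset A `survey_dataset` (or a bare list with `egos`, `ties`,
#'   `nominations`, `codebook` — used internally before construction).
#' @return A tibble with columns `ego_id`, `rule`, `detail`; zero rows if
#'   valid.
#' @seealso [write_validation_report()] to serialise the report as JSON lines.
#' @export
validate_dataset <- function(dataset) {
  egos <- dataset$egos
  ties <- dataset$ties
  noms <- dataset$nominations
  cb <- dataset$codebook
  out <- list()

  dup <- unique(egos$ego_id[duplicated(egos$ego_id)])
  if (length(dup)) {
    out[[length(out) + 1L]] <- .violation(dup, "duplicate_ego_id",
                                          "ego_id appears more than once")
  }
  bad_sex <- egos$ego_id[is.na(egos$sex) | !egos$sex %in% c("female", "male")]
  if (length(bad_sex)) {
    out[[length(out) + 1L]] <- .violation(bad_sex, "missing_ego_sex",
                                          "sex must be 'female' or 'male'")
  }

  orphan <- unique(ties$ego_id[!ties$ego_id %in% egos$ego_id])
  if (length(orphan)) {
    out[[length(out) + 1L]] <- .violation(orphan, "orphan_tie",
                                          "tie references unknown ego_id")
  }

  by_ego <- split(ties$position, ties$ego_id)
  for (id in names(by_ego)) {
    pos <- by_ego[[id]]
    if (anyNA(pos)) {
      out[[length(out) + 1L]] <- .violation(id, "missing_position",
                                            "tie has no closeness position")
      next
    }
    if (anyDuplicated(pos)) {
      out[[length(out) + 1L]] <- .violation(
        id, "duplicate_position",
        paste0("positions ", paste(sort(pos), collapse = ","))
      )
    } else if (!identical(sort(pos), seq_along(pos))) {
      out[[length(out) + 1L]] <- .violation(
        id, "position_gap",
        paste0("positions ", paste(sort(pos), collapse = ","),
               " are not contiguous from 1")
      )
    }
    if (length(pos) > cb$nomination_cap) {
      out[[length(out) + 1L]] <- .violation(
        id, "over_cap",
        paste0(length(pos), " ties exceed the cap of ", cb$nomination_cap)
      )
    }
  }

  for (col in .day_count_cols) {
    v <- ties[[col]]
    bad <- !is.na(v) & (v < 0L | v > 14L)
    if (any(bad)) {
      out[[length(out) + 1L]] <- .violation(
        ties$ego_id[bad], "day_count_range",
        paste0(col, " = ", v[bad], " outside [0, 14]")
      )
    }
  }

  unknown_rel <- !is.na(ties$relationship) &
    !ties$relationship %in% cb$codes$code
  if (any(unknown_rel)) {
    out[[length(out) + 1L]] <- .violation(
      ties$ego_id[unknown_rel], "unknown_relationship",
      paste0("code '", ties$relationship[unknown_rel], "' not in codebook")
    )
  }
  .check_levels <- function(col, levels, rule) {
    v <- ties[[col]]
    bad <- !is.na(v) & !v %in% levels
    if (any(bad)) {
      out[[length(out) + 1L]] <<- .violation(
        ties$ego_id[bad], rule, paste0(col, " = '", v[bad], "' not in codebook")
      )
    }
  }
  .check_levels("residence", cb$residence_levels, "unknown_residence")
  .check_levels("alter_bodyweight_vs_ego", cb$bodyweight_levels,
                "unknown_bodyweight_code")
  .check_levels("talk_own_health_freq", cb$talk_freq_levels,
                "unknown_talk_level")
  .check_levels("talk_alter_health_freq", cb$talk_freq_levels,
                "unknown_talk_level")
  .check_levels("alter_sex", c("female", "male"), "unknown_alter_sex")

  orphan_nom <- unique(noms$ego_id[!noms$ego_id %in% egos$ego_id])
  if (length(orphan_nom)) {
    out[[length(out) + 1L]] <- .violation(orphan_nom, "orphan_nomination",
                                          "nomination references unknown ego_id")
  }
  dup_nom <- unique(noms$ego_id[duplicated(noms$ego_id)])
  if (length(dup_nom)) {
    out[[length(out) + 1L]] <- .violation(dup_nom, "duplicate_nomination_row",
                                          "ego has multiple nomination rows")
  }
  sizes <- vapply(by_ego, length, integer(1))
  for (col in .nom_cols[-1]) {
    v <- noms[[col]]
    n_ties <- sizes[noms$ego_id]
    n_ties[is.na(n_ties)] <- 0L
    bad <- !is.na(v) & (v < 1L | v > n_ties)
    if (any(bad)) {
      out[[length(out) + 1L]] <- .violation(
        noms$ego_id[bad], "nomination_position",
        paste0(col, " = ", v[bad], " does not refer to a nominated alter")
      )
    }
  }

  if (!length(out)) {
    return(tibble::tibble(ego_id = character(0), rule = character(0),
                          detail = character(0)))
  }
  dplyr::bind_rows(out)
}

#' Write a validation report as JSON lines
#'
#' One JSON object per violation, with fields `ego_id`, `rule`, `detail`.
#'
#' @param report Tibble from [validate_dataset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  lines <- vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Pseudonymize alter labels
#'
#' Alter names are collected only to anchor the interview; no measure needs
#' them. This one-way pass replaces each label with a stable token derived
#' from its ego and position, so a dataset can be shared without free-text
#' names.
#'
#' @param dataset A `survey_dataset`.
#' @return The dataset with `alter_label` replaced by `"<ego_id>-A<position>"`.
#' @export
pseudonymize_alters <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  dataset$ties$alter_label <- paste0(dataset$ties$ego_id, "-A",
                                     dataset$ties$position)
  dataset
}
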