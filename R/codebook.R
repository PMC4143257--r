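#' Relationship code list for ego-alter rosters
#'
#' The default code list covers the relationship labels used by roster
#' instruments of the name-generator type fielded in South Asian health
#' surveys: spouses, blood kin, in-laws, and the three non-kin categories
#' (friend, workmate, neighbor), plus a catch-all `other`.
#'
#' Each code carries a three-way class (`class3`): `male-relative`,
#' `female-relative`, `non-relative`, or `other`, and, where the label itself
#' fixes the alter's sex (husband, daughter, ...), the implied alter sex.
#'
#' @return A tibble with columns `code`, `class3`, `implied_sex`
#'   (`"female"`, `"male"`, or `NA` for unsexed codes) and `spouse`
#'   (logical; husband/wife).
#' @export
#' @examples
#' relationship_codes()
relationship_codes <- function() {
  tibble::tribble(
    ~code,              ~class3,           ~implied_sex, ~spouse,
    "husband",          "male-relative",   "male",       TRUE,
    "son",              "male-relative",   "male",       FALSE,
    "son-in-law",       "male-relative",   "male",       FALSE,
    "father",           "male-relative",   "male",       FALSE,
    "brother",          "male-relative",   "male",       FALSE,
    "father-in-law",    "male-relative",   "male",       FALSE,
    "brother-in-law",   "male-relative",   "male",       FALSE,
    "cousin-male",      "male-relative",   "male",       FALSE,
    "uncle",            "male-relative",   "male",       FALSE,
    "nephew",           "male-relative",   "male",       FALSE,
    "wife",             "female-relative", "female",     TRUE,
    "daughter",         "female-relative", "female",     FALSE,
    "daughter-in-law",  "female-relative", "female",     FALSE,
    "mother",           "female-relative", "female",     FALSE,
    "sister",           "female-relative", "female",     FALSE,
    "sister-in-law",    "female-relative", "female",     FALSE,
    "mother-in-law",    "female-relative", "female",     FALSE,
    "cousin-female",    "female-relative", "female",     FALSE,
    "aunt",             "female-relative", "female",     FALSE,
    "niece",            "female-relative", "female",     FALSE,
    "friend",           "non-relative",    NA,           FALSE,
    "workmate",         "non-relative",    NA,           FALSE,
    "neighbor",         "non-relative",    NA,           FALSE,
    "other",            "other",           NA,           FALSE
  )
}

#' Build a survey codebook
#'
#' The codebook bundles the code lists and the classification policy in force
#' for a dataset: the relationship code list and its grouping, the nomination
#' cap of the name generator, the ordered response scale for the two
#' health-talk items, the residence and relative-bodyweight code lists, the
#' activity domains counted by tie multiplexity, and how the `other`
#' relationship class is pooled when relationships are dichotomised into
#' relative vs non-relative.
#'
#' @param other_is_relative Logical; whether ties coded `other` count as
#'   relatives in the relative/non-relative dichotomy. Default `TRUE`: summing
#'   a roster sample in which relatives plus `other` ties reproduce the
#'   published relative-tie totals requires pooling `other` with relatives.
#' @param nomination_cap Maximum number of alters the name generator accepts
#'   (default 5).
#' @param talk_freq_levels Ordered response scale (weakest first) for the
#'   "how often do you speak to ... about health" items.
#' @param residence_levels Code list for alter residence relative to the ego.
#' @param bodyweight_levels Code list for ego-perceived alter bodyweight
#'   relative to the ego.
#' @param activity_domains Named activity domains counted by
#'   [tie_multiplexity()].
#' @param codes Relationship code list as returned by [relationship_codes()];
#'   supply a modified tibble to adapt the instrument.
#' @return An object of class `ego_codebook`.
#' @export
#' @examples
#' cb <- default_codebook()
#' cb$nomination_cap
default_codebook <- function(other_is_relative = TRUE,
                             nomination_cap = 5L,
                             talk_freq_levels = c("never", "rarely",
                                                  "sometimes", "often"),
                             residence_levels = c("same household",
                                                  "same city", "other"),
                             bodyweight_levels = c("less", "similar", "more"),
                             activity_domains = c("communication", "snacks",
                                                  "meals", "exercise",
                                                  "walking_tasks",
                                                  "meal_prep_shop",
                                                  "tobacco_co_use",
                                                  "health_talk"),
                             codes = relationship_codes()) {
  stopifnot(is.logical(other_is_relative), length(other_is_relative) == 1L,
            is.numeric(nomination_cap), nomination_cap >= 1L)
  required <- c("code", "class3", "implied_sex", "spouse")
  if (!all(required %in% names(codes))) {
    stop("`codes` must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(codes$code)) stop("duplicate relationship codes")
  bad <- setdiff(unique(codes$class3),
                 c("male-relative", "female-relative", "non-relative", "other"))
  if (length(bad)) stop("unknown class3 value(s): ", paste(bad, collapse = ", "))
  structure(
    list(
      codes = tibble::as_tibble(codes),
      other_is_relative = other_is_relative,
      nomination_cap = as.integer(nomination_cap),
      talk_freq_levels = talk_freq_levels,
      residence_levels = residence_levels,
      bodyweight_levels = bodyweight_levels,
      activity_domains = activity_domains
    ),
    class = "ego_codebook"
  )
}

#' @export
print.ego_codebook <- function(x, ...) {
  cat("<ego_codebook>\n")
  cat("  relationship codes:", nrow(x$codes), "\n")
  cat("  nomination cap:", x$nomination_cap, "\n")
  cat("  'other' pooled with relatives:", x$other_is_relative, "\n")
  cat("  activity domains:", length(x$activity_domains), "\n")
  invisible(x)
}

#' Classify relationship codes
#'
#' `relationship_class()` maps relationship codes to their three-way class
#' (`male-relative`, `female-relative`, `non-relative`, `other`);
#' `is_relative()` applies the codebook's dichotomisation policy on top of it.
#'
#' @param relationship Character vector of relationship codes.
#' @param codebook An [default_codebook()] object.
#' @return `relationship_class()`: character vector of class3 labels (`NA` for
#'   unknown codes). `is_relative()`: logical vector.
#' @export
relationship_class <- function(relationship, codebook = default_codebook()) {
  codebook$codes$class3[match(relationship, codebook$codes$code)]
}

#' @rdname relationship_class
#' @export
is_relative <- function(relationship, codebook = default_codebook()) {
  cls <- relationship_class(relationship, codebook)
  out <- cls %in% c("male-relative", "female-relative")
  if (codebook$other_is_relative) out <- out | cls %in% "other"
  out[is.na(cls)] <- NA
  out
}

#' Read and write codebooks as YAML
#'
#' The on-disk form is plain YAML so an adapted instrument can ship its own
#' code lists alongside its data.
#'
#' @param path File path.
#' @param codebook An `ego_codebook` object.
#' @return `read_codebook()` returns an `ego_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  codes <- tibble::as_tibble(do.call(rbind.data.frame, lapply(raw$codes, function(r) {
    data.frame(code = r$code, class3 = r$class3,
               implied_sex = if (is.null(r$implied_sex)) NA_character_ else r$implied_sex,
               spouse = isTRUE(r$spouse), stringsAsFactors = FALSE)
  })))
  default_codebook(
    other_is_relative = isTRUE(raw$other_is_relative),
    nomination_cap = raw$nomination_cap,
    talk_freq_levels = unlist(raw$talk_freq_levels),
    residence_levels = unlist(raw$residence_levels),
    bodyweight_levels = unlist(raw$bodyweight_levels),
    activity_domains = unlist(raw$activity_domains),
    codes = codes
  )
}

#' @rdname read_codebook
#' @export
write_codebook <- function(codebook, path) {
  stopifnot(inherits(codebook, "ego_codebook"))
  out <- list(
    codes = lapply(seq_len(nrow(codebook$codes)), function(i) {
      r <- codebook$codes[i, ]
      list(code = r$code, class3 = r$class3,
           implied_sex = if (is.na(r$implied_sex)) NULL else r$implied_sex,
           spouse = r$spouse)
    }),
    other_is_relative = codebook$other_is_relative,
    nomination_cap = codebook$nomination_cap,
    talk_freq_levels = as.list(codebook$talk_freq_levels),
    residence_levels = as.list(codebook$residence_levels),
    bodyweight_levels = as.list(codebook$bodyweight_levels),
    activity_domains = as.list(codebook$activity_domains)
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
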