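# Proportion of TRUE among known (non-NA) values; NA_real_ when no value is
# known — "undefined" is a value, not an error.
.prop_known <- function(x) {
  known <- !is.na(x)
  if (!any(known)) return(NA_real_)
  mean(x[known])
}

#' Personal network size
#'
#' The number of alters the ego nominated, out of the instrument's possible
#' nominations (default cap 5). Egos who nominated nobody have size 0.
#'
#' @param ties Tibble of the ego's ties (rows of a `survey_dataset$ties`
#'   belonging to one ego).
#' @return Integer count.
#' @export
#' @examples
#' network_size(tibble::tibble(ego_id = "e", position = 1:3))
network_size <- function(ties) {
  nrow(ties)
}

#' Network exposure to an attribute
#'
#' The proportion of reported network members exhibiting an attribute, out of
#' all reported network members with a known value. Alters whose value is
#' unknown are excluded from numerator and denominator alike; the measure is
#' undefined (`NA`) when no alter has a known value.
#'
#' @param ties Tibble of one ego's ties.
#' @param attribute Either the name of a logical tie column (e.g.
#'   `"alter_tobacco_use"`) or a predicate function mapping the tie tibble to
#'   a logical vector (`NA` = unknown).
#' @return Proportion in `[0, 1]`, or `NA` if undefined.
#' @export
#' @examples
#' ties <- tibble::tibble(alter_tobacco_use = c(TRUE, FALSE, FALSE, NA))
#' network_exposure(ties, "alter_tobacco_use")  # 1/3
network_exposure <- function(ties, attribute) {
  vals <- if (is.function(attribute)) {
    attribute(ties)
  } else {
    if (!attribute %in% names(ties)) {
      stop("unknown tie attribute: ", attribute)
    }
    ties[[attribute]]
  }
  .prop_known(as.logical(vals))
}

#' Network homogeneity
#'
#' The proportion of alters (with a known value) sharing the ego's own value
#' of an attribute. Three attributes have instrument-defined semantics:
#'
#' * `"sex"` — alter of the same sex as the ego;
#' * `"city"` — alter residing in the same city as the ego, i.e. residence
#'   coded `same household` or `same city` rather than `other`;
#' * `"bodyweight"` — the item is already self-referent ("compared to your
#'   own weight"), so a match is `alter_bodyweight_vs_ego == "similar"`.
#'
#' Any other attribute is matched literally between `ego[[attribute]]` and
#' the tie column `paste0("alter_", attribute)`.
#'
#' @param ego One-row tibble (or named list) for the ego.
#' @param ties Tibble of the ego's ties.
#' @param attribute Attribute name (see Details).
#' @param codebook An [default_codebook()] object (used for the residence
#'   code list).
#' @return Proportion in `[0, 1]`, or `NA` if no alter has a known value.
#' @export
#' @examples
#' ego <- tibble::tibble(ego_id = "e", sex = "female")
#' ties <- tibble::tibble(alter_sex = c("female", "female", "male", "male"))
#' network_homogeneity(ego, ties, "sex")  # 0.5
network_homogeneity <- function(ego, ties, attribute,
                                codebook = default_codebook()) {
  if (attribute == "sex") {
    if (is.na(ego$sex[1])) stop("ego value missing for attribute 'sex'")
    match <- ties$alter_sex == ego$sex[1]
  } else if (attribute == "city") {
    same_city_codes <- setdiff(codebook$residence_levels, "other")
    match <- ifelse(is.na(ties$residence), NA,
                    ties$residence %in% same_city_codes)
  } else if (attribute == "bodyweight") {
    match <- ifelse(is.na(ties$alter_bodyweight_vs_ego), NA,
                    ties$alter_bodyweight_vs_ego == "similar")
  } else {
    if (!attribute %in% names(ego) || is.na(ego[[attribute]][1])) {
      stop("ego value missing for attribute '", attribute, "'")
    }
    col <- paste0("alter_", attribute)
    if (!col %in% names(ties)) stop("no tie column ", col)
    match <- ties[[col]] == ego[[attribute]][1]
  }
  .prop_known(match)
}

#' Tie diversity of a personal network
#'
#' Two summaries of relationship-type composition: the share of ties that are
#' relatives (`pct_family`, under the codebook's dichotomisation policy) and
#' the number of distinct tie types present (`n_tie_types`). Tie types follow
#' the kin-vs-non-kin framing of diversity: all kin codes pool into a single
#' `kin` type, while each non-kin code (friend, workmate, neighbor, other)
#' counts as its own type — so a roster of husband, son, friend, neighbor
#' spans 3 types.
#'
#' @param ties Tibble of one ego's ties.
#' @param codebook An [default_codebook()] object.
#' @return A list with `pct_family` (proportion, `NA` for an empty roster)
#'   and `n_tie_types` (integer).
#' @export
#' @examples
#' ties <- tibble::tibble(relationship = c("husband", "son", "friend",
#'                                         "neighbor"))
#' network_diversity(ties)  # pct_family 0.5, n_tie_types 3
network_diversity <- function(ties, codebook = default_codebook()) {
  if (!nrow(ties)) {
    return(list(pct_family = NA_real_, n_tie_types = 0L))
  }
  rel <- is_relative(ties$relationship, codebook)
  list(
    pct_family = .prop_known(rel),
    n_tie_types = length(unique(.diversity_type(ties$relationship, codebook)))
  )
}

# Tie-type space for diversity: kin pooled, each non-kin code distinct.
# Unknown codes yield no type.
.diversity_type <- function(relationship, codebook) {
  cls <- relationship_class(relationship, codebook)
  kin <- cls %in% c("male-relative", "female-relative")
  out <- ifelse(kin, "kin", relationship)
  out[is.na(cls)] <- NA
  out[!is.na(out)]
}

#' Per-tie strength summary
#'
#' Combines the instrument's three operationalizations of tie strength:
#' closeness rank (the nomination order, 1 = closest), intimacy (whether the
#' tie was chosen as the emergency contact, the health-problem contact, or
#' the contact when feeling overwhelmed), and 14-day contact frequency
#' (shared snack + meal days and the binary activity indicators).
#'
#' @param ties Tibble of one ego's ties.
#' @param nominations One-row tibble of the ego's network-level nominations
#'   (or `NULL` for none).
#' @return A tibble with one row per tie: `ego_id`, `position`, `rank`,
#'   `is_emergency_contact`, `is_health_contact`, `is_overwhelmed_contact`,
#'   `contact_days_14d`, `contacted_14d`.
#' @export
tie_strength <- function(ties, nominations = NULL) {
  pos <- ties$position
  .flag <- function(col) {
    if (is.null(nominations) || !nrow(nominations)) return(rep(FALSE, length(pos)))
    p <- nominations[[col]][1]
    if (is.na(p)) return(rep(FALSE, length(pos)))
    if (!p %in% pos) stop("nomination ", col, " = ", p,
                          " refers to a non-existent position")
    pos == p
  }
  snack <- ifelse(is.na(ties$snack_days_14d), 0L, ties$snack_days_14d)
  meal <- ifelse(is.na(ties$meal_days_14d), 0L, ties$meal_days_14d)
  tibble::tibble(
    ego_id = ties$ego_id,
    position = pos,
    rank = pos,
    is_emergency_contact = .flag("emergency_contact_pos"),
    is_health_contact = .flag("health_problem_pos"),
    is_overwhelmed_contact = .flag("overwhelmed_contact_pos"),
    contact_days_14d = snack + meal,
    contacted_14d = ties$contacted_14d
  )
}

#' Tie multiplexity
#'
#' The number of distinct activity domains a dyad spanned in the 14-day
#' recall window. The default codebook counts eight domains: in-person /
#' phone / SMS / email communication, shared snacks (> 0 days), shared meals
#' (> 0 days), exercise, walking or small tasks outside the home, meal
#' preparation or grocery shopping, tobacco co-use, and health talk (either
#' talk item above the scale's lowest level). Unknown responses count as not
#' engaged.
#'
#' @param ties Tibble of ties (any number of egos; vectorised by row).
#' @param codebook An [default_codebook()] object; its `activity_domains`
#'   entry fixes which domains are counted.
#' @return Integer vector, one count per tie, each in
#'   `[0, length(activity_domains)]`.
#' @export
#' @examples
#' tie <- tibble::tibble(snack_days_14d = 3L, meal_days_14d = 5L,
#'                       exercised_14d = TRUE)
#' tie_multiplexity(survey_dataset(
#'   tibble::tibble(ego_id = "e", sex = "female"),
#'   dplyr::mutate(tie, ego_id = "e", position = 1L)
#' )$ties)  # 3
tie_multiplexity <- function(ties, codebook = default_codebook()) {
  f <- function(x) !is.na(x) & x
  never <- codebook$talk_freq_levels[1]
  talk <- function(col) !is.na(ties[[col]]) & ties[[col]] != never
  engaged <- list(
    communication = f(ties$contacted_14d),
    snacks = !is.na(ties$snack_days_14d) & ties$snack_days_14d > 0L,
    meals = !is.na(ties$meal_days_14d) & ties$meal_days_14d > 0L,
    exercise = f(ties$exercised_14d),
    walking_tasks = f(ties$walked_tasks_14d),
    meal_prep_shop = f(ties$meal_prep_shop_14d),
    tobacco_co_use = f(ties$tobacco_co_use_14d),
    health_talk = talk("talk_own_health_freq") | talk("talk_alter_health_freq")
  )
  active <- engaged[intersect(codebook$activity_domains, names(engaged))]
  if (!length(active)) return(rep(0L, nrow(ties)))
  as.integer(Reduce(`+`, active))
}

# Relative-status (per policy) of the tie at a nominated position; NA when no
# position was nominated.
.relative_at <- function(ties, pos, codebook) {
  if (is.na(pos) || !pos %in% ties$position) return(NA)
  is_relative(ties$relationship[ties$position == pos], codebook)
}

# Position of the most frequent snack partner: highest snack_days_14d, ties
# broken by closeness (lower position wins); NA when all counts are 0/unknown.
.top_snack_position <- function(ties) {
  snack <- ifelse(is.na(ties$snack_days_14d), 0L, ties$snack_days_14d)
  if (!length(snack) || max(snack) == 0L) return(NA_integer_)
  ord <- order(-snack, ties$position)
  ties$position[ord[1]]
}

#' Compute all measures for one ego
#'
#' Composes the per-ego measures into one row: network size, exposures
#' (tobacco), homogeneities (sex, city, bodyweight), diversity (family share
#' and distinct tie types), the relative-status of the first-named alter, of
#' the health-problem contact, and of the most frequent snack partner, and
#' the mean tie multiplexity. Proportions are undefined (`NA`) exactly when
#' their denominator is zero.
#'
#' @param dataset A valid `survey_dataset`.
#' @param ego_id Ego identifier present in the dataset.
#' @param health_contact_item Which network-level nomination stands for "the
#'   primary contact for a health concern": `"health_problem"` (default) or
#'   `"emergency"`.
#' @return A one-row tibble of class fields; see Details.
#' @export
ego_measures <- function(dataset, ego_id,
                         health_contact_item = c("health_problem",
                                                 "emergency")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  health_contact_item <- match.arg(health_contact_item)
  if (!ego_id %in% dataset$egos$ego_id) stop("unknown ego_id: ", ego_id)
  ego <- dataset$egos[dataset$egos$ego_id == ego_id, ]
  ties <- dataset$ties[dataset$ties$ego_id == ego_id, ]
  noms <- dataset$nominations[dataset$nominations$ego_id == ego_id, ]
  cb <- dataset$codebook

  div <- network_diversity(ties, cb)
  nom_col <- switch(health_contact_item,
                    health_problem = "health_problem_pos",
                    emergency = "emergency_contact_pos")
  health_pos <- if (nrow(noms)) noms[[nom_col]][1] else NA_integer_

  tibble::tibble(
    ego_id = ego_id,
    network_size = network_size(ties),
    exposure_tobacco = network_exposure(ties, "alter_tobacco_use"),
    homogeneity_sex = if (nrow(ties)) {
      network_homogeneity(ego, ties, "sex", cb)
    } else NA_real_,
    homogeneity_city = network_homogeneity(ego, ties, "city", cb),
    homogeneity_bodyweight = network_homogeneity(ego, ties, "bodyweight", cb),
    pct_family = div$pct_family,
    n_tie_types = div$n_tie_types,
    first_named_relative = .relative_at(ties, if (nrow(ties)) 1L else NA_integer_, cb),
    health_contact_relative = .relative_at(ties, health_pos, cb),
    top_snack_partner_relative = .relative_at(ties, .top_snack_position(ties), cb),
    mean_multiplexity = if (nrow(ties)) mean(tie_multiplexity(ties, cb)) else NA_real_
  )
}

#' Compute measures for every ego in a dataset
#'
#' Vectorised over egos (grouped computation over the tie table), so it
#' scales to simulated samples of tens of thousands of egos; it agrees
#' measure-for-measure with [ego_measures()] applied ego by ego.
#'
#' @inheritParams ego_measures
#' @return A tibble with one row per ego, in ego-table order; columns as in
#'   [ego_measures()].
#' @export
all_ego_measures <- function(dataset,
                             health_contact_item = c("health_problem",
                                                     "emergency")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  health_contact_item <- match.arg(health_contact_item)
  cb <- dataset$codebook
  egos <- dataset$egos
  ties <- dataset$ties
  nom_col <- switch(health_contact_item,
                    health_problem = "health_problem_pos",
                    emergency = "emergency_contact_pos")

  same_city_codes <- setdiff(cb$residence_levels, "other")
  t <- ties
  t$ego_sex <- egos$sex[match(t$ego_id, egos$ego_id)]
  t$m_sex <- ifelse(is.na(t$alter_sex), NA, t$alter_sex == t$ego_sex)
  t$m_city <- ifelse(is.na(t$residence), NA, t$residence %in% same_city_codes)
  t$m_bw <- ifelse(is.na(t$alter_bodyweight_vs_ego), NA,
                   t$alter_bodyweight_vs_ego == "similar")
  t$rel <- is_relative(t$relationship, cb)
  t$cls <- relationship_class(t$relationship, cb)
  t$dtype <- ifelse(t$cls %in% c("male-relative", "female-relative"),
                    "kin", t$relationship)
  t$dtype[is.na(t$cls)] <- NA
  t$mux <- tie_multiplexity(t, cb)
  t$snack0 <- ifelse(is.na(t$snack_days_14d), 0L, t$snack_days_14d)

  per <- dplyr::summarise(
    dplyr::group_by(t, .data$ego_id),
    network_size = dplyr::n(),
    exposure_tobacco = .prop_known(.data$alter_tobacco_use),
    homogeneity_sex = .prop_known(.data$m_sex),
    homogeneity_city = .prop_known(.data$m_city),
    homogeneity_bodyweight = .prop_known(.data$m_bw),
    pct_family = .prop_known(.data$rel),
    n_tie_types = length(unique(.data$dtype[!is.na(.data$dtype)])),
    first_named_relative = .data$rel[.data$position == 1L][1],
    top_snack_partner_relative = if (max(.data$snack0) == 0L) NA else {
      .data$rel[order(-.data$snack0, .data$position)[1]]
    },
    mean_multiplexity = mean(.data$mux),
    .groups = "drop"
  )

  out <- dplyr::left_join(egos["ego_id"], per, by = "ego_id")
  out$network_size[is.na(out$network_size)] <- 0L
  out$network_size <- as.integer(out$network_size)
  out$n_tie_types[is.na(out$n_tie_types)] <- 0L
  out$n_tie_types <- as.integer(out$n_tie_types)

  hp <- dataset$nominations[[nom_col]][
    match(egos$ego_id, dataset$nominations$ego_id)]
  tie_key <- paste(t$ego_id, t$position)
  out$health_contact_relative <- t$rel[match(paste(egos$ego_id, hp), tie_key)]

  out[c("ego_id", "network_size", "exposure_tobacco", "homogeneity_sex",
        "homogeneity_city", "homogeneity_bodyweight", "pct_family",
        "n_tie_types", "first_named_relative", "health_contact_relative",
        "top_snack_partner_relative", "mean_multiplexity")]
}
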