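#' Configuration for the synthetic survey generator
#'
#' Bundles every distribution the generator samples from. The defaults are
#' calibrated once to the New Delhi reference sample ([delhi_reference()]):
#' 208 egos, 50.5% women, the published network-size frequency distribution,
#' the published per-position tie-type composition, exercise-partner rates of
#' 8% among relative ties and 17% among non-relative ties, alter tobacco
#' prevalence mirroring the sample's own by-sex prevalence (39% men, 3%
#' women), and 90% of alters residing in the ego's city. Laws the published
#' tables do not constrain (day-count distributions, talk-frequency scale,
#' nomination-position weights) are explicit fields here so adaptations can
#' redefine them; the package vignette discusses each choice.
#'
#' @param n_egos Number of respondents to simulate (>= 1).
#' @param p_female Probability an ego is female.
#' @param size_pmf Probabilities over network sizes `0:nomination_cap`
#'   (default proportional to the reference frequency counts 7, 8, 12, 56,
#'   45, 80).
#' @param tie_type_pmf_by_position Matrix of tie-type probabilities, one
#'   column per nomination position (rows named by relationship code);
#'   default proportional to the reference per-position composition.
#'   Positions beyond the last column reuse the last column.
#' @param p_exercise_given_relative,p_exercise_given_nonrelative Probability
#'   a tie is an exercise partner, by relative class.
#' @param p_alter_tobacco_by_sex Named vector `c(female = , male = )` of
#'   alter tobacco-use probabilities.
#' @param p_same_city Probability an alter resides in the ego's city (same
#'   household or same city rather than `other`).
#' @param p_household_given_relative,p_household_given_nonrelative Of the
#'   same-city mass, the share living in the ego's household, by class.
#' @param p_alter_female_unsexed Probability an alter with an unsexed
#'   relationship code (friend, workmate, neighbor, other) is female.
#' @param p_ego_tobacco_by_sex Named vector of ego tobacco-use probabilities.
#' @param bodyweight_probs Probabilities over the perceived-bodyweight codes
#'   `less`, `similar`, `more`.
#' @param activity_rates Named list of 14-day activity parameters:
#'   `contacted`, binomial day-count rates `snack_relative`,
#'   `snack_nonrelative`, `meal_relative`, `meal_nonrelative`, Bernoulli
#'   rates `walked_relative`, `walked_nonrelative`, `meal_prep_relative`,
#'   `meal_prep_nonrelative`, `tobacco_co_use_given_user`,
#'   `tobacco_co_use_given_nonuser`, and `talk_freq_probs` over the
#'   codebook's talk scale.
#' @param nomination_decay Nomination-position weights are proportional to
#'   `nomination_decay^-(position)`: closer alters are likelier choices for
#'   the three network-level items.
#' @param nomination_relative_boost Multiplicative preference for relative
#'   ties when drawing the three network-level nominations; together with the
#'   position decay this reproduces the reference sample's 91% share of
#'   relatives among primary health contacts.
#' @param p_no_nomination Probability a network-level item is left
#'   unanswered.
#' @param prob_tol Tolerance for probability vectors summing to 1.
#' @param seed Master RNG seed (integer).
#' @param codebook An [default_codebook()] object.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_egos = 208L,
                             p_female = 105 / 208,
                             size_pmf = NULL,
                             tie_type_pmf_by_position = NULL,
                             p_exercise_given_relative = 0.08,
                             p_exercise_given_nonrelative = 0.17,
                             p_alter_tobacco_by_sex = c(female = 0.03,
                                                        male = 0.39),
                             p_same_city = 0.9,
                             p_household_given_relative = 0.6,
                             p_household_given_nonrelative = 0.02,
                             p_alter_female_unsexed = 0.5,
                             p_ego_tobacco_by_sex = c(female = 0.03,
                                                      male = 0.39),
                             bodyweight_probs = c(less = 0.35,
                                                  similar = 0.31,
                                                  more = 0.34),
                             activity_rates = list(
                               contacted = 0.9,
                               snack_relative = 0.25,
                               snack_nonrelative = 0.18,
                               meal_relative = 0.35,
                               meal_nonrelative = 0.05,
                               walked_relative = 0.30,
                               walked_nonrelative = 0.20,
                               meal_prep_relative = 0.30,
                               meal_prep_nonrelative = 0.05,
                               tobacco_co_use_given_user = 0.25,
                               tobacco_co_use_given_nonuser = 0.01,
                               talk_freq_probs = c(0.1, 0.2, 0.3, 0.4)
                             ),
                             nomination_decay = 2,
                             nomination_relative_boost = 2.5,
                             p_no_nomination = 0.015,
                             prob_tol = 1e-6,
                             seed = 1L,
                             codebook = default_codebook()) {
  ref <- delhi_reference()
  if (is.null(size_pmf)) {
    size_pmf <- ref$size_frequencies$full / sum(ref$size_frequencies$full)
  }
  if (is.null(tie_type_pmf_by_position)) {
    m <- as.matrix(ref$tie_composition_pct[paste0("pct_pos", 1:5)])
    rownames(m) <- ref$tie_composition_pct$code
    tie_type_pmf_by_position <- sweep(m, 2, colSums(m), "/")
  }
  cfg <- structure(
    list(n_egos = as.integer(n_egos), p_female = p_female,
         size_pmf = size_pmf,
         tie_type_pmf_by_position = tie_type_pmf_by_position,
         p_exercise_given_relative = p_exercise_given_relative,
         p_exercise_given_nonrelative = p_exercise_given_nonrelative,
         p_alter_tobacco_by_sex = p_alter_tobacco_by_sex,
         p_same_city = p_same_city,
         p_household_given_relative = p_household_given_relative,
         p_household_given_nonrelative = p_household_given_nonrelative,
         p_alter_female_unsexed = p_alter_female_unsexed,
         p_ego_tobacco_by_sex = p_ego_tobacco_by_sex,
         bodyweight_probs = bodyweight_probs,
         activity_rates = activity_rates,
         nomination_decay = nomination_decay,
         nomination_relative_boost = nomination_relative_boost,
         p_no_nomination = p_no_nomination,
         prob_tol = prob_tol,
         seed = as.integer(seed),
         codebook = codebook),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Stops before any sampling if a probability vector does not sum to 1
#' (within `prob_tol`), a probability lies outside `[0, 1]`, or `n_egos < 1`.
#'
#' @param config A `generator_config`.
#' @return `config`, invisibly.
#' @export
validate_generator_config <- function(config) {
  if (config$n_egos < 1L) stop("n_egos must be >= 1")
  tol <- config$prob_tol
  .pmf <- function(p, what) {
    if (any(is.na(p)) || any(p < 0) || abs(sum(p) - 1) > tol) {
      stop("invalid probability vector for ", what,
           " (sums to ", format(sum(p)), ")")
    }
  }
  .pmf(config$size_pmf, "size_pmf")
  if (length(config$size_pmf) != config$codebook$nomination_cap + 1L) {
    stop("size_pmf must cover sizes 0..", config$codebook$nomination_cap)
  }
  for (j in seq_len(ncol(config$tie_type_pmf_by_position))) {
    .pmf(config$tie_type_pmf_by_position[, j],
         paste0("tie_type_pmf_by_position[, ", j, "]"))
  }
  unknown <- setdiff(rownames(config$tie_type_pmf_by_position),
                     config$codebook$codes$code)
  if (length(unknown)) {
    stop("tie-type pmf rows not in codebook: ", paste(unknown, collapse = ", "))
  }
  .pmf(config$bodyweight_probs, "bodyweight_probs")
  .pmf(config$activity_rates$talk_freq_probs, "talk_freq_probs")
  probs <- c(config$p_female, config$p_exercise_given_relative,
             config$p_exercise_given_nonrelative,
             config$p_alter_tobacco_by_sex, config$p_same_city,
             config$p_household_given_relative,
             config$p_household_given_nonrelative,
             config$p_alter_female_unsexed, config$p_ego_tobacco_by_sex,
             config$p_no_nomination)
  if (any(probs < 0 | probs > 1)) stop("a probability lies outside [0, 1]")
  invisible(config)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>", x$n_egos, "egos, seed", x$seed, "\n")
  cat("  E[network size] =",
      round(sum((seq_along(x$size_pmf) - 1L) * x$size_pmf), 3), "\n")
  invisible(x)
}

#' Generate a synthetic survey dataset
#'
#' Draws a complete, valid `survey_dataset` from a [generator_config()].
#' Generation is reproducible and parallel-safe: one pseudo-random substream
#' per ego, each substream seeded from the master seed, so the same seed and
#' config always yield byte-identical data. Spouse codes are drawn
#' consistently with ego sex (husband ties only for female egos, wife ties
#' only for male egos); alter sex is implied by sexed relationship codes and
#' Bernoulli otherwise.
#'
#' @param config A `generator_config`.
#' @return A valid `survey_dataset`.
#' @export
#' @examples
#' ds <- generate_dataset(generator_config(n_egos = 20, seed = 42))
#' nrow(validate_dataset(ds)) # 0
generate_dataset <- function(config) {
  validate_generator_config(config)
  cb <- config$codebook
  cap <- cb$nomination_cap
  ar <- config$activity_rates
  pmf <- config$tie_type_pmf_by_position
  codes <- rownames(pmf)
  code_info <- cb$codes[match(codes, cb$codes$code), ]
  rel_by_code <- stats::setNames(is_relative(codes, cb), codes)
  sex_by_code <- stats::setNames(code_info$implied_sex, codes)
  n <- config$n_egos

  set.seed(config$seed)
  ego_seeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)

  ego_sex <- character(n)
  ego_tob <- logical(n)
  ego_rows <- vector("list", n)
  tie_rows <- vector("list", n)
  nom_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(ego_seeds[i])
    id <- sprintf("ego%06d", i)
    sex <- if (stats::runif(1) < config$p_female) "female" else "male"
    tob <- stats::runif(1) < config$p_ego_tobacco_by_sex[[sex]]
    size <- sample.int(length(config$size_pmf), 1L,
                       prob = config$size_pmf) - 1L
    ego_sex[i] <- sex
    ego_tob[i] <- tob

    if (size > 0L) {
      pos <- seq_len(size)
      code <- vapply(pos, function(p) {
        codes[sample.int(length(codes), 1L,
                         prob = pmf[, min(p, ncol(pmf))])]
      }, character(1))
      # spouse consistency with ego sex
      code[code == "husband" & sex == "male"] <- "wife"
      code[code == "wife" & sex == "female"] <- "husband"
      rel <- unname(rel_by_code[code])
      a_sex <- unname(sex_by_code[code])
      unsexed <- is.na(a_sex)
      if (any(unsexed)) {
        a_sex[unsexed] <- ifelse(
          stats::runif(sum(unsexed)) < config$p_alter_female_unsexed,
          "female", "male")
      }
      p_house <- ifelse(rel, config$p_household_given_relative,
                        config$p_household_given_nonrelative)
      u <- stats::runif(size)
      residence <- ifelse(
        u > config$p_same_city, "other",
        ifelse(stats::runif(size) < p_house, "same household", "same city"))
      a_tob <- stats::runif(size) <
        config$p_alter_tobacco_by_sex[a_sex]
      bw <- names(config$bodyweight_probs)[
        vapply(pos, function(p) {
          sample.int(length(config$bodyweight_probs), 1L,
                     prob = config$bodyweight_probs)
        }, integer(1))]
      snack_rate <- ifelse(rel, ar$snack_relative, ar$snack_nonrelative)
      meal_rate <- ifelse(rel, ar$meal_relative, ar$meal_nonrelative)
      tie_rows[[i]] <- list(
        ego_id = rep(id, size),
        position = pos,
        alter_label = paste0(id, "-A", pos),
        alter_sex = a_sex,
        relationship = code,
        residence = residence,
        talk_own_health_freq = cb$talk_freq_levels[
          vapply(pos, function(p) sample.int(length(cb$talk_freq_levels), 1L,
                                             prob = ar$talk_freq_probs),
                 integer(1))],
        talk_alter_health_freq = cb$talk_freq_levels[
          vapply(pos, function(p) sample.int(length(cb$talk_freq_levels), 1L,
                                             prob = ar$talk_freq_probs),
                 integer(1))],
        contacted_14d = stats::runif(size) < ar$contacted,
        snack_days_14d = stats::rbinom(size, 14L, snack_rate),
        meal_days_14d = stats::rbinom(size, 14L, meal_rate),
        exercised_14d = stats::runif(size) <
          ifelse(rel, config$p_exercise_given_relative,
                 config$p_exercise_given_nonrelative),
        walked_tasks_14d = stats::runif(size) <
          ifelse(rel, ar$walked_relative, ar$walked_nonrelative),
        meal_prep_shop_14d = stats::runif(size) <
          ifelse(rel, ar$meal_prep_relative, ar$meal_prep_nonrelative),
        tobacco_co_use_14d = stats::runif(size) <
          ifelse(a_tob & tob, ar$tobacco_co_use_given_user,
                 ar$tobacco_co_use_given_nonuser),
        alter_tobacco_use = a_tob,
        alter_bodyweight_vs_ego = bw
      )
      w <- config$nomination_decay^-(pos) *
        config$nomination_relative_boost^rel
      nom <- vapply(1:3, function(k) {
        if (stats::runif(1) < config$p_no_nomination) return(NA_integer_)
        pos[sample.int(size, 1L, prob = w)]
      }, integer(1))
      nom_rows[[i]] <- list(ego_id = id, emergency_contact_pos = nom[1],
                            health_problem_pos = nom[2],
                            overwhelmed_contact_pos = nom[3])
    }
    ego_rows[[i]] <- id
  }

  egos <- tibble::tibble(
    ego_id = unlist(ego_rows),
    sex = ego_sex,
    tobacco_use = ego_tob,
    bodyweight_class = NA_character_,
    city = "Delhi"
  )
  .bind <- function(rows) {
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows)) return(NULL)
    cols <- names(rows[[1]])
    out <- lapply(cols, function(cl) unlist(lapply(rows, `[[`, cl),
                                            use.names = FALSE))
    names(out) <- cols
    tibble::as_tibble(out)
  }
  ties <- .bind(tie_rows)
  nominations <- .bind(nom_rows)
  survey_dataset(egos, ties, nominations, codebook = cb)
}

#' Closed-form expectations under a generator configuration
#'
#' Quantities implied analytically by a [generator_config()], used to check
#' the generator against the law of large numbers: the expected network size
#' and the expected pooled share of relative ties (weights: the probability a
#' nomination slot is occupied).
#'
#' @param config A `generator_config`.
#' @return A list with `mean_size` and `pct_relative_ties` (0-100 scale).
#' @export
generator_expectations <- function(config) {
  cap <- config$codebook$nomination_cap
  sizes <- seq_along(config$size_pmf) - 1L
  mean_size <- sum(sizes * config$size_pmf)
  # P(slot p occupied) = P(size >= p)
  w <- vapply(seq_len(cap), function(p) sum(config$size_pmf[sizes >= p]),
              numeric(1))
  pmf <- config$tie_type_pmf_by_position
  rel <- is_relative(rownames(pmf), config$codebook)
  rel_by_pos <- vapply(seq_len(cap), function(p) {
    sum(pmf[rel, min(p, ncol(pmf))])
  }, numeric(1))
  list(mean_size = mean_size,
       pct_relative_ties = 100 * sum(w * rel_by_pos) / sum(w))
}

#' Recover generator parameters from a dataset
#'
#' Estimates the recoverable subset of [generator_config()] from a dataset by
#' running the package's own measurement pipeline: the network-size pmf (from
#' the size frequency distribution), the ego sex split, the pooled tie-type
#' shares (via [tie_composition()]), the conditional exercise-partner
#' probabilities (via [dyadic_features()]), and alter tobacco prevalence by
#' alter sex. Used as the generator's acceptance surface: estimates from a
#' generated dataset converge to the configured parameters as `n_egos` grows.
#'
#' @param dataset A valid `survey_dataset`.
#' @return A list with `n_egos`, `p_female`, `size_pmf` (named by size),
#'   `tie_type_shares` (named by code, proportions of all ties),
#'   `pct_relative_ties`, `p_exercise_given_relative`,
#'   `p_exercise_given_nonrelative`, and `p_alter_tobacco_by_sex`.
#' @export
recover_parameters <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cap <- dataset$codebook$nomination_cap
  n <- nrow(dataset$egos)
  per_ego <- as.integer(table(factor(dataset$ties$ego_id,
                                     levels = dataset$egos$ego_id)))
  sizes <- tabulate(factor(per_ego, levels = 0:cap), nbins = cap + 1L)
  comp <- tie_composition(dataset)
  dy <- dyadic_features(dataset)
  ties <- dataset$ties
  known_tob <- !is.na(ties$alter_tobacco_use) & !is.na(ties$alter_sex)
  p_tob <- vapply(c(female = "female", male = "male"), function(s) {
    v <- ties$alter_tobacco_use[known_tob & ties$alter_sex == s]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  rel_share <- sum(comp$by_class$n_all[
    comp$by_class$class3 %in% c("male-relative", "female-relative",
                                if (dataset$codebook$other_is_relative) "other")
  ]) / comp$total_ties

  list(
    n_egos = n,
    p_female = mean(dataset$egos$sex == "female"),
    size_pmf = stats::setNames(sizes / n, 0:cap),
    tie_type_shares = stats::setNames(comp$by_type$n_all / comp$total_ties,
                                      comp$by_type$relationship),
    pct_relative_ties = 100 * rel_share,
    p_exercise_given_relative =
      dy$exercise$pct[dy$exercise$class == "relative"] / 100,
    p_exercise_given_nonrelative =
      dy$exercise$pct[dy$exercise$class == "non-relative"] / 100,
    p_alter_tobacco_by_sex = p_tob
  )
}
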