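#' Reference tabulations from the New Delhi egocentric network sample
#'
#' Published sample-level tabulations from an egocentric social-network
#' module fielded among 208 adults in New Delhi, India (up to 5 alters per
#' respondent, ordered by closeness; 780 ties in total). No respondent-level
#' microdata are distributed; these marginal tables are what the synthetic
#' generator's defaults are calibrated to and what the package's worked
#' examples recompute.
#'
#' @return A list:
#' \describe{
#'   \item{size_frequencies}{Tibble of the network-size distribution:
#'     `size` (0-5) and ego counts `full`, `women`, `men`.}
#'   \item{tie_composition_pct}{Tibble of tie-type percentages: `code`,
#'     `class3`, `pct_all` (of 780 ties), `pct_pos1` ... `pct_pos5` (of the
#'     positional denominators).}
#'   \item{position_n}{Positional tie denominators (positions 1-5).}
#'   \item{strongest_ties}{Relative / non-relative counts of first-named
#'     alters, primary health contacts, and most frequent snack partners
#'     (ego-level).}
#'   \item{exercise_ties}{Counts of exercised-with ties among relative and
#'     non-relative ties.}
#' }
#' @export
#' @examples
#' ref <- delhi_reference()
#' sum(ref$size_frequencies$full)   # 208 respondents
#' sum(ref$position_n)              # 780 ties
delhi_reference <- function() {
  size_frequencies <- tibble::tibble(
    size = 0:5,
    full = c(7L, 8L, 12L, 56L, 45L, 80L),
    women = c(4L, 3L, 8L, 18L, 19L, 53L),
    men = c(3L, 5L, 4L, 38L, 26L, 27L)
  )

  tie_composition_pct <- tibble::tribble(
    ~code,             ~pct_all, ~pct_pos1, ~pct_pos2, ~pct_pos3, ~pct_pos4, ~pct_pos5,
    "husband",             10.1,      28.4,       1.6,       6.1,       4.8,       2.5,
    "son",                 11.2,       4.0,      17.6,      12.2,       9.6,      13.8,
    "son-in-law",           0.3,       0.0,       0.0,       0.0,       0.8,       1.3,
    "father",               2.1,       2.0,       2.1,       2.8,       0.8,       2.5,
    "brother",              9.0,       3.0,      10.4,      13.3,      10.4,       8.8,
    "father-in-law",        0.3,       0.5,       0.5,       0.0,       0.0,       0.0,
    "brother-in-law",       2.7,       2.0,       2.6,       4.4,       3.2,       0.0,
    "cousin-male",          1.0,       1.0,       0.5,       1.7,       0.0,       2.5,
    "uncle",                0.8,       1.5,       0.5,       1.1,       0.0,       0.0,
    "nephew",               0.4,       0.0,       0.5,       0.6,       0.8,       0.0,
    "wife",                10.6,      30.4,       4.2,       5.5,       1.6,       2.5,
    "daughter",             8.5,       5.0,       9.8,       9.9,       9.6,       8.8,
    "daughter-in-law",      2.2,       0.0,       1.0,       2.8,       4.0,       6.3,
    "mother",               6.0,       5.0,       8.8,       7.2,       3.2,       3.8,
    "sister",               6.9,       4.5,       8.3,       6.6,       8.8,       7.5,
    "sister-in-law",        5.3,       2.0,       4.2,       3.9,      11.2,      10.0,
    "mother-in-law",        0.9,       0.0,       2.6,       0.0,       0.0,       2.5,
    "cousin-female",        0.9,       0.0,       0.5,       1.7,       2.4,       0.0,
    "aunt",                 0.3,       0.0,       0.0,       0.0,       0.0,       2.5,
    "niece",                0.5,       0.0,       0.5,       0.6,       0.8,       1.3,
    "friend",              12.7,       8.0,      14.5,      13.4,      18.4,      10.0,
    "workmate",             1.0,       0.5,       1.0,       0.6,       1.6,       2.5,
    "neighbor",             4.6,       2.0,       6.7,       5.0,       3.2,       7.5,
    "other",                1.9,       0.5,       1.6,       1.1,       4.8,       3.8
  )
  tie_composition_pct <- tibble::add_column(
    tie_composition_pct,
    class3 = relationship_class(tie_composition_pct$code),
    .after = "code")

  strongest_ties <- tibble::tibble(
    feature = c("first_named", "health_contact", "snack_partner"),
    n_relative = c(180L, 181L, 178L),
    n_nonrelative = c(21L, 17L, 17L)
  )

  exercise_ties <- tibble::tibble(
    class = c("relative", "non-relative"),
    n_exercised = c(51L, 24L),
    n_ties = c(637L, 143L)
  )

  list(
    size_frequencies = size_frequencies,
    tie_composition_pct = tie_composition_pct,
    position_n = c(201L, 193L, 181L, 125L, 80L),
    strongest_ties = strongest_ties,
    exercise_ties = exercise_ties
  )
}

#' Expand a network-size frequency table into a dataset
#'
#' Turns a published frequency distribution of network size into a concrete
#' `survey_dataset` whose egos reproduce that distribution exactly — the
#' standard device for re-deriving a table's means, SDs, and percentages when
#' only the frequency column is printed. Tie attributes other than position
#' are filler (`relationship = "other"`), so only size-based summaries of the
#' expansion are meaningful.
#'
#' @param freq Data frame with columns `size` (integer, 0 to the cap) and
#'   `n` (ego count at that size); an optional `sex` column assigns group
#'   labels (recycled per row), default `"female"`.
#' @param codebook An [default_codebook()] object.
#' @return A valid `survey_dataset` with `sum(freq$n)` egos.
#' @export
#' @examples
#' ds <- expand_size_frequencies(data.frame(size = c(0, 5), n = c(1, 2)))
#' nrow(ds$egos)  # 3
#' nrow(ds$ties)  # 10
expand_size_frequencies <- function(freq, codebook = default_codebook()) {
  freq <- tibble::as_tibble(freq)
  stopifnot(all(c("size", "n") %in% names(freq)),
            all(freq$size >= 0), all(freq$size <= codebook$nomination_cap),
            all(freq$n >= 0))
  if (!"sex" %in% names(freq)) freq$sex <- "female"
  sizes <- rep(freq$size, freq$n)
  sexes <- rep(freq$sex, freq$n)
  n_egos <- length(sizes)
  ids <- sprintf("ego%05d", seq_len(n_egos))
  egos <- tibble::tibble(ego_id = ids, sex = sexes)
  ties <- tibble::tibble(
    ego_id = rep(ids, sizes),
    position = unlist(lapply(sizes, seq_len), use.names = FALSE),
    relationship = "other"
  )
  survey_dataset(egos, ties, codebook = codebook)
}
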