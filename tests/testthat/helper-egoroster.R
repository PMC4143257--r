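# Fixture builders shared across test files. All fixtures are built in code.

# Two egos, three ties, one nomination row: the smallest fully-featured
# dataset.
tiny_dataset <- function(codebook = default_codebook()) {
  egos <- tibble::tibble(
    ego_id = c("e1", "e2"),
    sex = c("female", "male"),
    tobacco_use = c(FALSE, TRUE)
  )
  ties <- tibble::tibble(
    ego_id = c("e1", "e1", "e2"),
    position = c(1L, 2L, 1L),
    alter_sex = c("male", "female", "female"),
    relationship = c("husband", "daughter", "friend"),
    residence = c("same household", "same household", "other"),
    contacted_14d = c(TRUE, TRUE, FALSE),
    snack_days_14d = c(3L, 0L, 1L),
    meal_days_14d = c(7L, 7L, 0L),
    exercised_14d = c(FALSE, FALSE, TRUE),
    alter_tobacco_use = c(TRUE, FALSE, NA)
  )
  noms <- tibble::tibble(
    ego_id = "e1",
    emergency_contact_pos = 1L,
    health_problem_pos = 2L,
    overwhelmed_contact_pos = 1L
  )
  survey_dataset(egos, ties, noms, codebook)
}

# Seeded, realistic random dataset via the package generator.
random_dataset <- function(seed, n_egos = 40) {
  generate_dataset(generator_config(n_egos = n_egos, seed = seed))
}

# A random roster of alters with known/unknown logical attribute, for
# enumeration oracles. Returns a bare tie tibble for one ego.
random_roster <- function(seed) {
  set.seed(seed)
  n <- sample(0:5, 1)
  tibble::tibble(
    ego_id = rep("e", n),
    position = seq_len(n),
    alter_sex = sample(c("female", "male"), n, replace = TRUE),
    alter_tobacco_use = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
    snack_days_14d = sample(0:14, n, replace = TRUE)
  )
}

expect_dataset_equal <- function(a, b) {
  expect_equal(as.data.frame(a$egos), as.data.frame(b$egos))
  expect_equal(as.data.frame(a$ties), as.data.frame(b$ties))
  expect_equal(as.data.frame(a$nominations), as.data.frame(b$nominations))
}
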