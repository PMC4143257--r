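test_that("network size counts nominations and handles empty rosters", {
  expect_identical(network_size(tibble::tibble(position = 1:3)), 3L)
  expect_identical(network_size(tibble::tibble(position = integer(0))), 0L)
})

test_that("exposure is the share of alters with the attribute among known values", {
  five <- tibble::tibble(alter_tobacco_use = c(TRUE, rep(FALSE, 4)))
  expect_equal(network_exposure(five, "alter_tobacco_use"), 0.2)
  all3 <- tibble::tibble(alter_tobacco_use = rep(TRUE, 3))
  expect_equal(network_exposure(all3, "alter_tobacco_use"), 1.0)
  # unknowns leave numerator and denominator
  mix <- tibble::tibble(alter_tobacco_use = c(TRUE, NA, FALSE, NA))
  expect_equal(network_exposure(mix, "alter_tobacco_use"), 0.5)
  # undefined exactly when no alter has a known value
  expect_true(is.na(network_exposure(
    tibble::tibble(alter_tobacco_use = c(NA, NA)), "alter_tobacco_use")))
  expect_true(is.na(network_exposure(
    tibble::tibble(alter_tobacco_use = logical(0)), "alter_tobacco_use")))
})

test_that("exposure equals brute-force enumeration on random rosters", {
  for (seed in 1:300) {
    roster <- random_roster(seed)
    got <- network_exposure(roster, "alter_tobacco_use")
    # oracle: explicit counting loop
    n_true <- 0L; n_known <- 0L
    for (i in seq_len(nrow(roster))) {
      v <- roster$alter_tobacco_use[i]
      if (!is.na(v)) {
        n_known <- n_known + 1L
        if (v) n_true <- n_true + 1L
      }
    }
    want <- if (n_known == 0L) NA_real_ else n_true / n_known
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("exposure to A and to not-A sum to 1 when all values are known", {
  for (seed in 1:50) {
    roster <- random_roster(seed)
    roster <- roster[!is.na(roster$alter_tobacco_use), ]
    if (!nrow(roster)) next
    a <- network_exposure(roster, "alter_tobacco_use")
    not_a <- network_exposure(roster, function(t) !t$alter_tobacco_use)
    expect_equal(a + not_a, 1)
  }
})

test_that("homogeneity matches the ego's value and errors when it is missing", {
  ego <- tibble::tibble(ego_id = "e", sex = "female")
  ties <- tibble::tibble(alter_sex = c("female", "female", "male", "male"))
  expect_equal(network_homogeneity(ego, ties, "sex"), 0.5)
  one <- tibble::tibble(alter_sex = "female")
  expect_equal(network_homogeneity(ego, one, "sex"), 1.0)
  expect_error(
    network_homogeneity(tibble::tibble(ego_id = "e", sex = NA), ties, "sex"),
    "'sex'")

  # bodyweight item is self-referent: match = "similar"
  bw <- tibble::tibble(alter_bodyweight_vs_ego = c("less", "similar", NA))
  expect_equal(network_homogeneity(ego, bw, "bodyweight"), 0.5)
  # same-city: same household or same city, not "other"
  res <- tibble::tibble(residence = c("same household", "same city", "other"))
  expect_equal(network_homogeneity(ego, res, "city"), 2 / 3)
})

test_that("homogeneity is invariant under joint relabeling of attribute values", {
  swap <- c(female = "male", male = "female")
  for (seed in 1:100) {
    roster <- random_roster(seed)
    for (ego_sex in c("female", "male")) {
      ego <- tibble::tibble(ego_id = "e", sex = ego_sex)
      before <- network_homogeneity(ego, roster, "sex")
      ego2 <- tibble::tibble(ego_id = "e", sex = unname(swap[ego_sex]))
      roster2 <- roster
      roster2$alter_sex <- unname(swap[roster$alter_sex])
      expect_equal(network_homogeneity(ego2, roster2, "sex"), before)
    }
  }
})

test_that("homogeneity coincides with exposure to the shares-ego-value predicate", {
  for (seed in 1:50) {
    roster <- random_roster(seed)
    ego <- tibble::tibble(ego_id = "e", sex = "female")
    expect_equal(
      network_homogeneity(ego, roster, "sex"),
      network_exposure(roster, function(t) t$alter_sex == "female"))
  }
})

test_that("diversity reports family share and distinct tie types", {
  ties <- tibble::tibble(relationship = c("husband", "son", "friend",
                                          "neighbor"))
  d <- network_diversity(ties)
  expect_equal(d$pct_family, 0.5)
  # husband + son pool into one kin type; friend and neighbor are distinct
  expect_identical(d$n_tie_types, 3L)
  kin <- tibble::tibble(relationship = c("mother", "sister", "brother"))
  expect_equal(network_diversity(kin)$pct_family, 1.0)
  empty <- tibble::tibble(relationship = character(0))
  expect_true(is.na(network_diversity(empty)$pct_family))
  expect_identical(network_diversity(empty)$n_tie_types, 0L)
})

test_that("n_tie_types never exceeds network size", {
  for (seed in 1:50) {
    ds <- random_dataset(seed, n_egos = 10)
    m <- all_ego_measures(ds)
    expect_true(all(m$n_tie_types <= m$network_size))
  }
})

test_that("tie strength combines rank, intimacy flags, and contact frequency", {
  ds <- tiny_dataset()
  ties <- ds$ties[ds$ties$ego_id == "e1", ]
  noms <- ds$nominations[ds$nominations$ego_id == "e1", ]
  s <- tie_strength(ties, noms)
  expect_identical(s$rank, c(1L, 2L))
  expect_identical(s$is_emergency_contact, c(TRUE, FALSE))
  expect_identical(s$is_health_contact, c(FALSE, TRUE))
  expect_identical(s$is_overwhelmed_contact, c(TRUE, FALSE))
  expect_identical(s$contact_days_14d, c(10L, 7L))

  # a tie nominated for all three items carries all three flags
  all3 <- tibble::tibble(ego_id = "x", emergency_contact_pos = 1L,
                         health_problem_pos = 1L, overwhelmed_contact_pos = 1L)
  one_tie <- tibble::tibble(ego_id = "x", position = 1L,
                            snack_days_14d = NA_integer_,
                            meal_days_14d = NA_integer_,
                            contacted_14d = TRUE)
  s3 <- tie_strength(one_tie, all3)
  expect_true(all(s3$is_emergency_contact, s3$is_health_contact,
                  s3$is_overwhelmed_contact))

  expect_error(tie_strength(one_tie, dplyr::mutate(all3, health_problem_pos = 3L)),
               "non-existent")
})

test_that("closeness rank is a strict total order within every ego", {
  for (seed in c(3, 12)) {
    ds <- random_dataset(seed)
    for (id in unique(ds$ties$ego_id)) {
      s <- tie_strength(ds$ties[ds$ties$ego_id == id, ])
      expect_identical(sort(s$rank), seq_along(s$rank))
    }
  }
})

test_that("multiplexity counts distinct engaged activity domains", {
  base <- tibble::tibble(
    ego_id = "e", position = 1L, alter_label = NA, alter_sex = NA,
    relationship = NA, residence = NA,
    talk_own_health_freq = NA_character_,
    talk_alter_health_freq = NA_character_,
    contacted_14d = NA, snack_days_14d = NA_integer_,
    meal_days_14d = NA_integer_, exercised_14d = NA, walked_tasks_14d = NA,
    meal_prep_shop_14d = NA, tobacco_co_use_14d = NA, alter_tobacco_use = NA,
    alter_bodyweight_vs_ego = NA)
  expect_identical(tie_multiplexity(base), 0L)

  three <- dplyr::mutate(base, snack_days_14d = 3L, meal_days_14d = 5L,
                         exercised_14d = TRUE)
  expect_identical(tie_multiplexity(three), 3L)

  all8 <- dplyr::mutate(base, contacted_14d = TRUE, snack_days_14d = 1L,
                        meal_days_14d = 14L, exercised_14d = TRUE,
                        walked_tasks_14d = TRUE, meal_prep_shop_14d = TRUE,
                        tobacco_co_use_14d = TRUE,
                        talk_own_health_freq = "often")
  expect_identical(tie_multiplexity(all8), 8L)

  # health talk engages only above the scale's lowest level
  never <- dplyr::mutate(base, talk_own_health_freq = "never",
                         talk_alter_health_freq = "never")
  expect_identical(tie_multiplexity(never), 0L)

  # bounded by the configured number of domains
  for (seed in 1:20) {
    ds <- random_dataset(seed, n_egos = 5)
    mux <- tie_multiplexity(ds$ties)
    expect_true(all(mux >= 0 & mux <= 8))
  }
})

test_that("ego_measures composes the per-ego statistics", {
  ds <- tiny_dataset()
  m1 <- ego_measures(ds, "e1")
  expect_identical(m1$network_size, 2L)
  expect_equal(m1$exposure_tobacco, 0.5)
  expect_equal(m1$homogeneity_sex, 0.5)
  expect_equal(m1$pct_family, 1.0)
  expect_true(m1$first_named_relative)
  expect_true(m1$health_contact_relative)  # position 2 = daughter
  expect_true(m1$top_snack_partner_relative)  # husband, 3 snack days

  # ego whose only snack-sharing alter is a friend
  m2 <- ego_measures(ds, "e2")
  expect_false(m2$top_snack_partner_relative)
  expect_false(m2$first_named_relative)
  expect_true(is.na(m2$health_contact_relative))  # no nomination row

  expect_error(ego_measures(ds, "nobody"), "unknown ego_id")
})

test_that("an ego with zero alters has size 0 and undefined proportions", {
  ds <- survey_dataset(tibble::tibble(ego_id = "e0", sex = "male"))
  m <- ego_measures(ds, "e0")
  expect_identical(m$network_size, 0L)
  expect_true(is.na(m$exposure_tobacco))
  expect_true(is.na(m$homogeneity_sex))
  expect_true(is.na(m$pct_family))
  expect_identical(m$n_tie_types, 0L)
  expect_true(is.na(m$top_snack_partner_relative))
})

test_that("vectorised measures agree with measure-by-measure recomputation", {
  for (seed in c(5, 21)) {
    ds <- random_dataset(seed, n_egos = 25)
    fast <- all_ego_measures(ds)
    slow <- dplyr::bind_rows(lapply(ds$egos$ego_id,
                                    function(id) ego_measures(ds, id)))
    expect_equal(as.data.frame(fast), as.data.frame(slow))
  }
})

test_that("snack-partner tie-breaking prefers the closer alter", {
  egos <- tibble::tibble(ego_id = "e", sex = "female")
  ties <- tibble::tibble(ego_id = "e", position = 1:3,
                         relationship = c("friend", "husband", "son"),
                         snack_days_14d = c(4L, 4L, 2L))
  ds <- survey_dataset(egos, ties)
  # friend at position 1 wins the 4-day tie against husband at position 2
  expect_false(ego_measures(ds, "e")$top_snack_partner_relative)
})

test_that("measures are invariant under long/wide round-trips", {
  ds <- random_dataset(8)
  m0 <- all_ego_measures(ds)
  dir <- withr::local_tempdir()
  write_long(ds, dir)
  m_long <- all_ego_measures(read_long(file.path(dir, "ties.csv"),
                                       file.path(dir, "egos.csv"),
                                       file.path(dir, "nominations.csv")))
  m_wide <- all_ego_measures(from_wide(to_wide(ds)))
  expect_equal(as.data.frame(m0), as.data.frame(m_long))
  expect_equal(as.data.frame(m0), as.data.frame(m_wide))
})

test_that("pct_family ignores position order; tie rank does not", {
  egos <- tibble::tibble(ego_id = "e", sex = "female")
  ties <- tibble::tibble(ego_id = "e", position = 1:3,
                         relationship = c("husband", "friend", "sister"))
  perm <- dplyr::mutate(ties, relationship = relationship[c(2, 3, 1)])
  d1 <- network_diversity(ties)
  d2 <- network_diversity(perm)
  expect_equal(d1$pct_family, d2$pct_family)
  ds1 <- survey_dataset(egos, ties)
  ds2 <- survey_dataset(egos, perm)
  expect_true(ego_measures(ds1, "e")$first_named_relative)
  expect_false(ego_measures(ds2, "e")$first_named_relative)
})
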