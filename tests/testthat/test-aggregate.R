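# Dataset expanded from the reference network-size frequency distribution,
# with the published sex split.
reference_expansion <- function() {
  ref <- delhi_reference()$size_frequencies
  freq <- dplyr::bind_rows(
    tibble::tibble(size = ref$size, n = ref$women, sex = "female"),
    tibble::tibble(size = ref$size, n = ref$men, sex = "male"))
  expand_size_frequencies(freq)
}

test_that("expanding the reference size frequencies reproduces the printed table", {
  ds <- reference_expansion()
  s <- summarize_measures(ds, group_by = "sex")

  expect_identical(s$n$n_egos[s$n$group == "full"], 208L)
  expect_identical(s$n$n_egos[s$n$group == "female"], 105L)
  expect_identical(s$n$n_egos[s$n$group == "male"], 103L)
  # women + men = full sample
  expect_identical(sum(s$n$n_egos[s$n$group != "full"]), 208L)

  expect_equal(round_half_up(s$size$mean_full, 1), 3.8)
  expect_equal(round_half_up(s$size$sd_full, 1), 1.3)
  expect_equal(round_half_up(s$size$mean_female, 1), 3.9)
  expect_equal(round_half_up(s$size$sd_female, 1), 1.4)
  expect_equal(round_half_up(s$size$mean_male, 1), 3.6)
  expect_equal(round_half_up(s$size$sd_male, 1), 1.2)

  # frequency section re-derives the input counts exactly (identity)
  ref <- delhi_reference()$size_frequencies
  expect_identical(s$freq$n_full, ref$full)
  expect_identical(s$freq$n_female, ref$women)
  expect_identical(s$freq$n_male, ref$men)
  expect_equal(round_half_up(s$freq$pct_full, 1),
               c(3.4, 3.8, 5.8, 26.9, 21.6, 38.5))
  # counts sum to the group's ego count
  expect_identical(sum(s$freq$n_full), 208L)

  # the published between-sex differences are detectable at table precision
  expect_lt(s$size$p_value, 0.05)
  expect_lt(s$freq_p_value, 0.01)
})

test_that("a group of identical egos has SD zero", {
  ds <- expand_size_frequencies(tibble::tibble(size = 3, n = 10,
                                               sex = c("female")))
  s <- summarize_measures(ds)
  expect_equal(s$size$sd_full, 0)
  expect_equal(s$size$mean_full, 3)
})

test_that("grouping by a missing or incomplete field errors", {
  ds <- tiny_dataset()
  expect_error(summarize_measures(ds, group_by = "caste"), "caste")
  ds$egos$city <- c("Delhi", NA)
  expect_error(summarize_measures(ds, group_by = "city"), "missing")
})

test_that("composition means use egos with alters; undefined handling is explicit", {
  egos <- tibble::tibble(ego_id = c("a", "b", "c"),
                         sex = c("female", "female", "male"))
  ties <- tibble::tibble(
    ego_id = c("a", "a", "b"), position = c(1L, 2L, 1L),
    relationship = c("husband", "friend", "sister"),
    alter_sex = c("male", "female", "female"),
    alter_tobacco_use = c(TRUE, FALSE, NA))
  ds <- survey_dataset(egos, ties)
  s <- summarize_measures(ds)
  comp <- s$composition
  tob <- comp[comp$column == "exposure_tobacco", ]
  # ego b has no known alter tobacco value: dropped from the tobacco row
  expect_identical(tob$n_full, 1L)
  expect_equal(tob$mean_full, 50)
  s0 <- summarize_measures(ds, undefined = "zero")
  tob0 <- s0$composition[s0$composition$column == "exposure_tobacco", ]
  expect_identical(tob0$n_full, 2L)
  expect_equal(tob0$mean_full, 25)
  # family share over egos with >= 1 alter only
  fam <- comp[comp$column == "pct_family", ]
  expect_identical(fam$n_full, 2L)
  expect_equal(fam$mean_full, 75)
})

test_that("tie composition: single husband tie is 100% at position 1", {
  egos <- tibble::tibble(ego_id = "e", sex = "female")
  ties <- tibble::tibble(ego_id = "e", position = 1L, relationship = "husband")
  tc <- tie_composition(survey_dataset(egos, ties))
  expect_identical(tc$total_ties, 1L)
  row <- tc$by_type[tc$by_type$relationship == "husband", ]
  expect_equal(row$pct_all, 100)
  expect_equal(row$pct_pos1, 100)
  expect_identical(tc$position_n, c(1L, 0L, 0L, 0L, 0L))
})

test_that("full-network counts equal the sum of positional counts", {
  for (seed in c(6, 13)) {
    tc <- tie_composition(random_dataset(seed, n_egos = 60))
    pos_cols <- paste0("n_pos", 1:5)
    expect_identical(tc$by_type$n_all,
                     as.integer(rowSums(tc$by_type[pos_cols])))
    expect_identical(tc$total_ties, sum(tc$position_n))
    # percentages sum to 100 within each position with ties
    for (p in which(tc$position_n > 0)) {
      expect_equal(sum(tc$by_type[[paste0("pct_pos", p)]]), 100)
    }
    # class-group percentages equal the sum of their member types
    for (cl in tc$by_class$class3) {
      member_sum <- sum(tc$by_type$pct_all[tc$by_type$class3 == cl])
      expect_equal(tc$by_class$pct_all[tc$by_class$class3 == cl], member_sum)
    }
    # positional denominators never increase with position
    expect_true(all(diff(tc$position_n) <= 0))
  }
})

test_that("dyadic features use the published denominators and definitions", {
  # counts -> percentages as printed: 180/201 -> 90, 21/201 -> 10
  expect_equal(round_half_up(100 * 180 / 201), 90)
  dy <- dyadic_features(tiny_dataset())
  first <- dy$strongest[dy$strongest$feature == "first_named", ]
  expect_identical(first$n_relative, 1L)       # e1's husband
  expect_identical(first$n_nonrelative, 1L)    # e2's friend
  expect_identical(first$denominator, 2L)
  health <- dy$strongest[dy$strongest$feature == "health_contact", ]
  expect_identical(health$denominator, 1L)     # only e1 nominated
  expect_identical(health$n_relative, 1L)
  ex <- dy$exercise
  expect_identical(ex$n_ties[ex$class == "relative"], 2L)
  expect_identical(ex$n_exercised[ex$class == "relative"], 0L)
  expect_equal(ex$pct[ex$class == "non-relative"], 100)
})

test_that("an all-friends sample yields 0% relative rows", {
  egos <- tibble::tibble(ego_id = c("a", "b"), sex = "female")
  ties <- tibble::tibble(ego_id = c("a", "b"), position = 1L,
                         relationship = "friend",
                         snack_days_14d = 2L)
  ds <- survey_dataset(egos, ties)
  dy <- dyadic_features(ds)
  expect_true(all(dy$strongest$pct_relative[
    dy$strongest$feature %in% c("first_named", "snack_partner")] == 0))
})

test_that("chi-square matches the direct formula and rejects bad tables", {
  flat <- rbind(c(10, 10), c(10, 10))
  res <- chi_square_2xk(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  ident <- rbind(c(5, 10, 15), c(10, 20, 30))
  expect_equal(chi_square_2xk(ident)$statistic, 0)

  set.seed(42)
  for (i in 1:25) {
    tab <- matrix(sample(1:30, 6, replace = TRUE), nrow = 2)
    got <- chi_square_2xk(tab)
    # oracle: sum((O - E)^2 / E) with E from the margins
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$statistic, sum((tab - E)^2 / E))
    expect_equal(got$df, 2)
    expect_equal(got$p_value,
                 stats::pchisq(got$statistic, 2, lower.tail = FALSE))
  }

  expect_error(chi_square_2xk(rbind(c(0, 0), c(1, 2))), "zero marginal")
  expect_error(chi_square_2xk(matrix(1:3, nrow = 1)), "2x2")
  expect_error(chi_square_2xk(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

test_that("one-way ANOVA matches the sums-of-squares oracle and t^2 identity", {
  same <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- anova_oneway(same, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(30)
    grp <- sample(c("a", "b", "c"), 30, replace = TRUE)
    if (any(table(grp) < 2)) next
    got <- anova_oneway(x, grp)
    # oracle: explicit between/within sums of squares
    means <- tapply(x, grp, mean)
    ns <- tapply(x, grp, length)
    ssb <- sum(ns * (means - mean(x))^2)
    ssw <- sum((x - means[grp])^2)
    k <- length(means); n <- length(x)
    f <- (ssb / (k - 1)) / (ssw / (n - k))
    expect_equal(got$statistic, f)
    expect_equal(got$p_value, stats::pf(f, k - 1, n - k, lower.tail = FALSE))
  }

  # with two groups F is the square of the pooled-variance t statistic
  x <- rnorm(20); grp <- rep(c("a", "b"), 10)
  got <- anova_oneway(x, grp)
  tt <- stats::t.test(x ~ grp, var.equal = TRUE)
  expect_equal(got$statistic, unname(tt$statistic)^2)

  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("aggregate outputs are invariant to input row order", {
  ds <- random_dataset(11, n_egos = 30)
  set.seed(1)
  shuf <- survey_dataset(
    ds$egos[sample(nrow(ds$egos)), ],
    ds$ties[sample(nrow(ds$ties)), ],
    ds$nominations[sample(nrow(ds$nominations)), ],
    ds$codebook)
  s1 <- summarize_measures(ds)
  s2 <- summarize_measures(shuf)
  expect_equal(s1$size, s2$size)
  expect_equal(s1$freq, s2$freq)
  expect_equal(s1$composition, s2$composition)
  tc1 <- tie_composition(ds); tc2 <- tie_composition(shuf)
  expect_equal(tc1$by_type, tc2$by_type)
  dy1 <- dyadic_features(ds); dy2 <- dyadic_features(shuf)
  expect_equal(dy1$strongest, dy2$strongest)
  expect_equal(dy1$exercise, dy2$exercise)
})

test_that("p-values format in table style with <0.01 flooring", {
  expect_identical(format_p(c(0.674, 0.0301, 0.004, 0.0099)),
                   c("0.67", "0.03", "<0.01", "0.01"))
  expect_identical(format_p(0.996), "1.00")
})

test_that("round_half_up rounds halves away from zero at any precision", {
  expect_equal(round_half_up(3.75, 1), 3.8)
  expect_equal(round_half_up(3.65, 1), 3.7)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(-0.5), -1)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(89.55, 0), 90)
})
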