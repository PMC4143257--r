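#' Round half away from zero
#'
#' Published survey tables conventionally round 0.5 up; base R's `round()`
#' rounds half to even. Raw unrounded values are always retained in package
#' output — rounding is applied only at presentation time.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(3.75, 1)  # 3.8
#' round_half_up(0.5)      # 1
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Format a p-value in table style
#'
#' Two decimals, floored at `<0.01`.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  r <- round_half_up(p, 2)
  out <- sprintf("%.2f", r)
  out[!is.na(r) & r < 0.01] <- "<0.01"
  out[is.na(r)] <- NA_character_
  out
}

#' Pearson chi-square test for a contingency table
#'
#' Classical Pearson chi-square without continuity correction, as used for
#' comparing binary or categorical distributions between groups in sample
#' description tables.
#'
#' @param counts Matrix (or table) of non-negative integer counts with at
#'   least 2 rows and 2 columns and no zero row/column margin.
#' @return A list with `statistic`, `df`, and `p_value`.
#' @export
#' @examples
#' chi_square_2xk(rbind(c(10, 10), c(10, 10)))$statistic  # 0
chi_square_2xk <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("need at least a 2x2 table")
  }
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal row or column")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' One-way analysis of variance
#'
#' Classical one-way F test from between- and within-group sums of squares
#' (equal variances assumed), as used for comparing continuous measures
#' between groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length as `values`.
#' @return A list with `statistic` (F), `df1`, `df2`, and `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) {
    stop("every group needs at least 2 observations")
  }
  res <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(statistic = unname(res$statistic),
       df1 = unname(res$parameter[1]), df2 = unname(res$parameter[2]),
       p_value = unname(res$p.value))
}

# Measures summarised on the percent scale in the sample table, with the
# ego-level column backing each row.
.composition_measures <- c(
  "Percent of network who use tobacco" = "exposure_tobacco",
  "Percent of network same sex" = "homogeneity_sex",
  "Percent of network same bodyweight as self" = "homogeneity_bodyweight",
  "Percent of network in same city" = "homogeneity_city",
  "Percent of network family" = "pct_family"
)

#' Sample-level summary of network measures
#'
#' Builds the grouped sample-description table: mean (SD) of network size,
#' the frequency distribution of network size, and mean (SD) of the
#' composition measures (tobacco exposure; sex, bodyweight, and city
#' homogeneity; family share), for the full sample and within each level of a
#' grouping variable, with a between-group comparison per row (one-way ANOVA
#' for continuous measures, Pearson chi-square for the size distribution).
#'
#' Denominators follow survey practice: network size is averaged over *all*
#' egos, including those who nominated nobody, while composition measures —
#' which are undefined on an empty roster — are averaged over egos with at
#' least one alter. Egos whose measure is undefined (e.g. tobacco exposure
#' when no alter's tobacco use is known) are dropped from that row by
#' default; `undefined = "zero"` instead scores them 0.
#'
#' @param dataset A valid `survey_dataset`.
#' @param group_by Name of an ego column to group by (default `"sex"`);
#'   must be non-missing for every ego.
#' @param undefined How egos with undefined composition measures enter the
#'   group mean: `"drop"` (default) or `"zero"`.
#' @param measures Optional precomputed [all_ego_measures()] table.
#' @return An object of class `sample_summary`: a list with `n` (ego counts),
#'   `size` (mean/SD rows), `freq` (size distribution), `composition`
#'   (percent-scale mean/SD rows), each carrying per-group columns and a
#'   `p_value`.
#' @export
summarize_measures <- function(dataset, group_by = "sex",
                               undefined = c("drop", "zero"),
                               measures = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  undefined <- match.arg(undefined)
  if (!group_by %in% names(dataset$egos)) {
    stop("no ego column '", group_by, "' to group by")
  }
  g <- dataset$egos[[group_by]]
  if (anyNA(g)) stop("grouping field '", group_by, "' missing for some egos")
  if (is.null(measures)) measures <- all_ego_measures(dataset)
  measures$.group <- g[match(measures$ego_id, dataset$egos$ego_id)]
  cap <- dataset$codebook$nomination_cap
  levels_g <- sort(unique(as.character(g)))
  groups <- c("full", levels_g)

  split_rows <- c(list(full = measures),
                  lapply(stats::setNames(levels_g, levels_g),
                         function(l) measures[measures$.group == l, ]))

  n <- tibble::tibble(
    group = groups,
    n_egos = unname(vapply(split_rows, nrow, integer(1))),
    n_egos_composition = unname(vapply(split_rows, function(m) {
      sum(m$network_size > 0L)
    }, integer(1)))
  )

  size <- tibble::tibble(measure = "Number of members named")
  for (gr in groups) {
    m <- split_rows[[gr]]
    size[[paste0("mean_", gr)]] <- mean(m$network_size)
    size[[paste0("sd_", gr)]] <- stats::sd(m$network_size)
  }
  size$p_value <- if (length(levels_g) >= 2L) {
    tryCatch(anova_oneway(measures$network_size, measures$.group)$p_value,
             error = function(e) NA_real_)
  } else NA_real_

  freq <- tibble::tibble(size = 0:cap)
  for (gr in groups) {
    m <- split_rows[[gr]]
    cnt <- vapply(0:cap, function(k) sum(m$network_size == k), integer(1))
    freq[[paste0("n_", gr)]] <- cnt
    freq[[paste0("pct_", gr)]] <- 100 * cnt / max(nrow(m), 1L)
  }
  freq_p <- NA_real_
  if (length(levels_g) >= 2L) {
    counts <- t(as.matrix(freq[paste0("n_", levels_g)]))
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    if (ncol(counts) >= 2L) {
      freq_p <- tryCatch(chi_square_2xk(counts)$p_value,
                         error = function(e) NA_real_)
    }
  }

  comp <- tibble::tibble(measure = names(.composition_measures),
                         column = unname(.composition_measures))
  for (gr in groups) {
    m <- split_rows[[gr]][split_rows[[gr]]$network_size > 0L, ]
    stats_gr <- vapply(comp$column, function(col) {
      v <- m[[col]]
      if (undefined == "zero") v[is.na(v)] <- 0
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, NA_real_, 0))
      c(100 * mean(v), 100 * stats::sd(v), length(v))
    }, numeric(3))
    comp[[paste0("mean_", gr)]] <- unname(stats_gr[1, ])
    comp[[paste0("sd_", gr)]] <- unname(stats_gr[2, ])
    comp[[paste0("n_", gr)]] <- as.integer(unname(stats_gr[3, ]))
  }
  comp$p_value <- unname(vapply(comp$column, function(col) {
    if (length(levels_g) < 2L) return(NA_real_)
    m <- measures[measures$network_size > 0L, ]
    v <- m[[col]]
    if (undefined == "zero") v[is.na(v)] <- 0
    tryCatch(anova_oneway(v, m$.group)$p_value, error = function(e) NA_real_)
  }, numeric(1)))

  structure(
    list(group_by = group_by, groups = groups, n = n, size = size,
         freq = freq, freq_p_value = freq_p, composition = comp,
         undefined = undefined),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("<sample_summary> grouped by", x$group_by, "\n")
  cat("Egos:", paste(sprintf("%s=%d", x$n$group, x$n$n_egos), collapse = ", "),
      "\n\nNetwork size, M (SD):\n")
  for (gr in x$groups) {
    cat(sprintf("  %-8s %s (%s)\n", gr,
                format(round_half_up(x$size[[paste0("mean_", gr)]], 1), nsmall = 1),
                format(round_half_up(x$size[[paste0("sd_", gr)]], 1), nsmall = 1)))
  }
  cat("  p =", format_p(x$size$p_value), "\n")
  invisible(x)
}

#' Tie-type composition of the pooled networks
#'
#' Tabulates every relationship code's share of all reported ties and its
#' share within each nomination position (position 1 = first-named, closest).
#' The full-network denominator is the pooled tie count over all respondents;
#' each positional denominator is the number of ties at that position. Ties
#' with a missing relationship code are excluded from numerators and
#' denominators.
#'
#' @param dataset A valid `survey_dataset`.
#' @return An object of class `tie_composition`: list with `by_type` (one row
#'   per relationship code: `n_all`, `pct_all`, `n_pos<k>`, `pct_pos<k>`),
#'   `by_class` (the same aggregated over the male-relative / female-relative
#'   / non-relative / other classes), `position_n` (positional denominators),
#'   and `total_ties`.
#' @export
tie_composition <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cb <- dataset$codebook
  cap <- cb$nomination_cap
  ties <- dataset$ties[!is.na(dataset$ties$relationship), ]
  total <- nrow(ties)
  position_n <- vapply(seq_len(cap), function(p) sum(ties$position == p),
                       integer(1))

  .tab <- function(keys, universe) {
    by_type <- tibble::tibble(key = universe)
    cnt_all <- vapply(universe, function(k) sum(keys == k), integer(1),
                      USE.NAMES = FALSE)
    by_type$n_all <- cnt_all
    by_type$pct_all <- if (total) 100 * cnt_all / total else rep(NA_real_, length(universe))
    for (p in seq_len(cap)) {
      in_p <- ties$position == p
      cnt <- vapply(universe, function(k) sum(keys == k & in_p), integer(1),
                    USE.NAMES = FALSE)
      by_type[[paste0("n_pos", p)]] <- cnt
      by_type[[paste0("pct_pos", p)]] <- if (position_n[p]) {
        100 * cnt / position_n[p]
      } else rep(NA_real_, length(universe))
    }
    by_type
  }

  by_type <- .tab(ties$relationship, cb$codes$code)
  names(by_type)[1] <- "relationship"
  by_type <- tibble::add_column(
    by_type, class3 = relationship_class(by_type$relationship, cb),
    .after = "relationship")
  cls_universe <- c("male-relative", "female-relative", "non-relative", "other")
  by_class <- .tab(relationship_class(ties$relationship, cb), cls_universe)
  names(by_class)[1] <- "class3"

  structure(
    list(by_type = by_type, by_class = by_class,
         position_n = position_n, total_ties = total),
    class = "tie_composition"
  )
}

#' @export
print.tie_composition <- function(x, ...) {
  cat("<tie_composition>", x$total_ties, "ties; positions n =",
      paste(x$position_n, collapse = ", "), "\n")
  print(dplyr::mutate(x$by_class, dplyr::across(dplyr::starts_with("pct"),
                                                ~round_half_up(.x, 1))))
  invisible(x)
}

#' Dyadic features of ties: strongest ties and exercise partners
#'
#' Summarises, over the whole sample, who occupies the strongest-tie roles
#' and who the exercise partners are, split by relative vs non-relative
#' (under the codebook's dichotomisation policy):
#'
#' * first-named alter (closeness rank 1) — denominator: egos with >= 1 alter;
#' * primary contact for a health concern — denominator: egos who made that
#'   nomination;
#' * most frequent snack partner in the 14-day recall (highest shared-snack
#'   day count, ties broken by closeness) — denominator: egos with a defined
#'   top snack partner;
#' * ties with whom the respondent exercised — denominators: all relative
#'   ties and all non-relative ties, separately.
#'
#' @inheritParams ego_measures
#' @param measures Optional precomputed [all_ego_measures()] table.
#' @return An object of class `dyadic_features`: list with `strongest`
#'   (rows `first_named`, `health_contact`, `snack_partner`: counts, percent
#'   and denominator) and `exercise` (rows `relative`, `non-relative`:
#'   `n_exercised`, `n_ties`, `pct`).
#' @export
dyadic_features <- function(dataset,
                            health_contact_item = c("health_problem",
                                                    "emergency"),
                            measures = NULL) {
  stopifnot(inherits(dataset, "survey_dataset"))
  health_contact_item <- match.arg(health_contact_item)
  if (is.null(measures)) {
    measures <- all_ego_measures(dataset, health_contact_item)
  }
  .row <- function(feature, flags) {
    flags <- flags[!is.na(flags)]
    denom <- length(flags)
    n_rel <- sum(flags)
    tibble::tibble(
      feature = feature, n_relative = n_rel,
      n_nonrelative = denom - n_rel, denominator = denom,
      pct_relative = if (denom) 100 * n_rel / denom else NA_real_,
      pct_nonrelative = if (denom) 100 * (denom - n_rel) / denom else NA_real_
    )
  }
  strongest <- dplyr::bind_rows(
    .row("first_named", measures$first_named_relative),
    .row("health_contact", measures$health_contact_relative),
    .row("snack_partner", measures$top_snack_partner_relative)
  )

  ties <- dataset$ties
  rel <- is_relative(ties$relationship, dataset$codebook)
  ex <- !is.na(ties$exercised_14d) & ties$exercised_14d
  exercise <- dplyr::bind_rows(
    tibble::tibble(class = "relative",
                   n_exercised = sum(ex[rel %in% TRUE]),
                   n_ties = sum(rel %in% TRUE)),
    tibble::tibble(class = "non-relative",
                   n_exercised = sum(ex[rel %in% FALSE]),
                   n_ties = sum(rel %in% FALSE))
  )
  exercise$pct <- ifelse(exercise$n_ties > 0,
                         100 * exercise$n_exercised / exercise$n_ties,
                         NA_real_)

  structure(list(strongest = strongest, exercise = exercise,
                 health_contact_item = health_contact_item),
            class = "dyadic_features")
}

#' @export
print.dyadic_features <- function(x, ...) {
  cat("<dyadic_features>\n")
  print(dplyr::mutate(x$strongest,
                      dplyr::across(dplyr::starts_with("pct"),
                                    ~round_half_up(.x, 0))))
  print(dplyr::mutate(x$exercise, pct = round_half_up(.data$pct, 0)))
  invisible(x)
}
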