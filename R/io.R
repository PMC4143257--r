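# Violation rules that make a file unreadable as a dataset (structural), vs
# code-list rules that are reported but leave the rows in place.
.hard_rules <- c("duplicate_ego_id", "missing_ego_sex", "orphan_tie",
                 "missing_position", "duplicate_position", "position_gap",
                 "over_cap", "day_count_range", "orphan_nomination",
                 "duplicate_nomination_row", "nomination_position")

.assemble_checked <- function(egos, ties, nominations, codebook) {
  ds <- survey_dataset(egos, ties, nominations, codebook, check = FALSE)
  report <- validate_dataset(ds)
  hard <- report[report$rule %in% .hard_rules, ]
  if (nrow(hard)) {
    stop("invalid survey data (", nrow(hard), " violation(s)); first: ",
         hard$rule[1], " for ego '", hard$ego_id[1], "': ", hard$detail[1])
  }
  if (nrow(report)) {
    warning(nrow(report), " unknown code(s) reported by validate_dataset(); ",
            "rows retained. First: ", report$detail[1])
  }
  ds
}

#' Read and write the long (one row per tie) layout
#'
#' The long layout stores one row per nominated ego-alter tie. Ego-level
#' fields come either from a separate ego table (`egos_path`; required to
#' represent egos with zero nominations) or from `ego_`-prefixed columns
#' repeated on each tie row. Network-level nominations travel in a third
#' table.
#'
#' Files are plain CSV (UTF-8, header row, RFC 4180 quoting). Structural
#' problems — duplicate `(ego_id, position)` pairs, position gaps such as
#' 1,3, day counts outside 0-14 — are hard errors naming the offending ego;
#' unknown codes are reported as a warning and the rows retained.
#'
#' @param ties_path CSV of ties.
#' @param egos_path Optional CSV of egos; if `NULL`, ego fields are taken from
#'   `ego_`-prefixed tie columns.
#' @param nominations_path Optional CSV of network-level nominations.
#' @param codebook An [default_codebook()] object.
#' @return `read_long()` returns a `survey_dataset`; `write_long()` writes
#'   `ties.csv`, `egos.csv` and `nominations.csv` under `dir` and returns
#'   their paths invisibly.
#' @export
read_long <- function(ties_path, egos_path = NULL, nominations_path = NULL,
                      codebook = default_codebook()) {
  ties <- readr::read_csv(ties_path, show_col_types = FALSE,
                          progress = FALSE)
  if (is.null(egos_path)) {
    ego_cols <- grep("^ego_", names(ties), value = TRUE)
    if (!length(setdiff(ego_cols, "ego_id"))) {
      stop("no ego table given and no ego_* columns found in ", ties_path)
    }
    egos <- dplyr::distinct(ties[ego_cols])
    names(egos) <- sub("^ego_(?!id)", "", names(egos), perl = TRUE)
    ties <- ties[setdiff(names(ties), setdiff(ego_cols, "ego_id"))]
  } else {
    egos <- readr::read_csv(egos_path, show_col_types = FALSE, progress = FALSE)
  }
  nominations <- if (!is.null(nominations_path)) {
    readr::read_csv(nominations_path, show_col_types = FALSE, progress = FALSE)
  }
  .assemble_checked(egos, ties, nominations, codebook)
}

#' @rdname read_long
#' @param dataset A `survey_dataset`.
#' @param dir Output directory (created if absent).
#' @export
write_long <- function(dataset, dir) {
  stopifnot(inherits(dataset, "survey_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("ties.csv", "egos.csv", "nominations.csv"))
  readr::write_csv(dataset$ties, paths[1], progress = FALSE)
  readr::write_csv(dataset$egos, paths[2], progress = FALSE)
  readr::write_csv(dataset$nominations, paths[3], progress = FALSE)
  invisible(paths)
}

# Per-alter columns that appear once per roster slot in the wide layout.
.wide_block_cols <- setdiff(.tie_cols, c("ego_id", "position"))

#' Convert to and from the wide (one row per ego) layout
#'
#' The wide layout mirrors the roster instrument: one row per ego, with the
#' per-alter items repeated in positional blocks `a1_*` ... `a<cap>_*`
#' (slot 1 = the closest alter) and the three network-level nomination
#' columns alongside the ego fields. An entirely empty block is an
#' un-nominated slot; filled slots must be contiguous from slot 1 (a filled
#' slot C with an empty slot B is a hard error).
#'
#' @param dataset A `survey_dataset`.
#' @return `to_wide()` returns a tibble with one row per ego; `read_wide()`
#'   and `from_wide()` return a `survey_dataset` equivalent to the long
#'   representation of the same data.
#' @export
to_wide <- function(dataset) {
  stopifnot(inherits(dataset, "survey_dataset"))
  cap <- dataset$codebook$nomination_cap
  wide <- dataset$egos
  noms <- dataset$nominations
  wide <- dplyr::left_join(wide, noms, by = "ego_id")
  for (p in seq_len(cap)) {
    block <- dataset$ties[dataset$ties$position == p,
                          c("ego_id", .wide_block_cols)]
    names(block)[-1] <- paste0("a", p, "_", .wide_block_cols)
    wide <- dplyr::left_join(wide, block, by = "ego_id")
  }
  wide
}

#' @rdname to_wide
#' @param wide A tibble in the wide layout.
#' @param codebook An [default_codebook()] object.
#' @export
from_wide <- function(wide, codebook = default_codebook()) {
  wide <- tibble::as_tibble(wide)
  cap <- codebook$nomination_cap
  block_names <- lapply(seq_len(cap),
                        function(p) paste0("a", p, "_", .wide_block_cols))
  all_block_cols <- unlist(block_names)
  ego_cols <- setdiff(names(wide), c(all_block_cols, .nom_cols[-1]))
  egos <- wide[ego_cols]

  ties_per_pos <- vector("list", cap)
  filled <- matrix(FALSE, nrow(wide), cap)
  for (p in seq_len(cap)) {
    present <- intersect(block_names[[p]], names(wide))
    if (!length(present)) next
    block <- wide[present]
    names(block) <- sub(paste0("^a", p, "_"), "", names(block))
    filled[, p] <- rowSums(!is.na(block)) > 0
    block$ego_id <- wide$ego_id
    block$position <- p
    ties_per_pos[[p]] <- block[filled[, p], , drop = FALSE]
  }
  # filled slots must be contiguous: no slot may be filled after an empty one
  if (cap >= 2L) {
    for (i in seq_len(nrow(wide))) {
      f <- filled[i, ]
      if (any(f) && any(!f[seq_len(max(which(f)))])) {
        stop("non-contiguous roster slots for ego '", wide$ego_id[i],
             "': slot(s) ",
             paste(which(!f[seq_len(max(which(f)))]), collapse = ","),
             " empty before filled slot ", max(which(f)))
      }
    }
  }
  ties <- dplyr::bind_rows(ties_per_pos)
  noms <- wide[intersect(c("ego_id", .nom_cols[-1]), names(wide))]
  # an ego with no nomination columns filled is equivalent to no row at all
  pos_cols <- intersect(.nom_cols[-1], names(noms))
  if (length(pos_cols)) {
    any_set <- rowSums(!is.na(noms[pos_cols])) > 0
    noms <- noms[any_set, , drop = FALSE]
  } else {
    noms <- NULL
  }
  .assemble_checked(egos, ties, noms, codebook)
}

#' @rdname to_wide
#' @param path CSV file in the wide layout.
#' @export
read_wide <- function(path, codebook = default_codebook()) {
  wide <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  from_wide(wide, codebook)
}

#' @rdname to_wide
#' @export
write_wide <- function(dataset, path) {
  readr::write_csv(to_wide(dataset), path, progress = FALSE)
  invisible(path)
}
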