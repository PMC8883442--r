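#' Read a long-format spot-score table
#'
#' Reads the canonical interchange form of the colony screen: one row per
#' spot, i.e. per construct x strain x condition x replicate, with an ordinal
#' growth-reduction score in `0:3` (none, weak, moderate, severe).
#'
#' @param path Path to a tab- or comma-separated file. The delimiter is
#'   chosen from the file extension (`.csv` gives comma, anything else tab).
#' @param schema Optional named character vector mapping canonical column
#'   names (`construct_id`, `strain`, `condition_id`, `replicate`, `score`,
#'   and optionally `protein_id`, `vector`) to the column names used in the
#'   file, e.g. `c(score = "growth_score")`. Unmapped canonical names are
#'   looked up verbatim.
#'
#' @return A tibble of spot observations with the canonical columns present
#'   in the file, `replicate` and `score` coerced to integer. An empty file
#'   yields an empty tibble with a warning.
#'
#' @details Scores outside `0:3` or non-integer scores raise an error that
#'   names the offending row numbers (rows of the data, excluding the
#'   header). Missing required columns raise a schema error.
#'
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' readr::write_tsv(tibble::tibble(
#'   protein_id = "ABL1", construct_id = "ABL1_c1", vector = "nls",
#'   strain = "BY4742", condition_id = "C01", replicate = 1:2, score = c(0L, 3L)
#' ), f)
#' read_screen_long(f)
#' @export
read_screen_long <- function(path, schema = NULL) {
  required <- c("construct_id", "strain", "condition_id", "replicate", "score")
  optional <- c("protein_id", "vector")
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0L) {
    warn("Score table is empty; returning zero observations.")
    out <- tibble(protein_id = character(), construct_id = character(),
                  vector = character(), strain = character(),
                  condition_id = character(), replicate = integer(),
                  score = integer())
    return(out)
  }
  lookup <- function(canon) (schema %||% character())[canon] %||% NA_character_
  resolve <- function(canon) {
    mapped <- unname(lookup(canon))
    if (is.na(mapped)) canon else mapped
  }
  missing_cols <- required[!vapply(required, function(cn) resolve(cn) %in% names(raw), logical(1))]
  if (length(missing_cols) > 0L) {
    abort(paste0("Score table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "kinarray_schema_error")
  }
  keep <- c(optional[vapply(optional, function(cn) resolve(cn) %in% names(raw), logical(1))],
            required)
  out <- tibble::as_tibble(setNames(lapply(keep, function(cn) raw[[resolve(cn)]]), keep))
  out$replicate <- suppressWarnings(as.integer(out$replicate))
  score_num <- suppressWarnings(as.numeric(out$score))
  bad <- which(is.na(score_num) | score_num != round(score_num) |
                 score_num < 0 | score_num > 3)
  if (length(bad) > 0L) {
    abort(paste0("Scores must be integers in 0-3; invalid at data row(s): ",
                 paste(head(bad, 10L), collapse = ", "),
                 if (length(bad) > 10L) " ..." else ""),
          class = "kinarray_validation_error")
  }
  out$score <- as.integer(score_num)
  out[intersect(.spot_cols, names(out))]
}

#' Write a long-format spot-score table
#'
#' Inverse of [read_screen_long()]; writes canonical columns in canonical
#' order as TSV.
#'
#' @param observations Tibble of spot observations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_long <- function(observations, path) {
  cols <- intersect(.spot_cols, names(observations))
  readr::write_tsv(observations[cols], path, progress = FALSE)
  invisible(path)
}

#' Read a plate-grid score file into spot observations
#'
#' Parses a robot-gridded plate exported as a matrix of scores: first column
#' row letters (A, B, ...), header row column numbers, cells the 0-3 score or
#' blank. The reference array is 384-format (rows A-P by columns 1-24); other
#' formats are accepted when the `layout` declares them.
#'
#' @param path Grid file (TSV).
#' @param layout Data frame mapping plate positions to constructs, with
#'   columns `row` (letters), `col` (integers), `construct_id`, and
#'   optionally `protein_id`. The distinct rows/columns of the layout declare
#'   the expected grid dimensions.
#' @param strain Strain identifier recorded on every observation.
#' @param condition_id Condition identifier recorded on every observation.
#' @param replicate Replicate number (default 1).
#'
#' @return Tibble of spot observations. Blank cells are missing data and
#'   produce no observation (they are never score 0). Grid positions not in
#'   the layout are skipped with a warning.
#' @export
read_plate_grid <- function(path, layout, strain, condition_id, replicate = 1L) {
  stopifnot(all(c("row", "col", "construct_id") %in% names(layout)))
  grid <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  row_letters <- grid[[1L]]
  col_numbers <- suppressWarnings(as.integer(names(grid)[-1L]))
  exp_rows <- sort(unique(layout$row))
  exp_cols <- sort(unique(as.integer(layout$col)))
  if (!setequal(row_letters, exp_rows) || !setequal(col_numbers[!is.na(col_numbers)], exp_cols)) {
    abort(sprintf(
      "Grid is %d x %d but layout declares %d x %d (rows %s..%s, cols %s..%s).",
      length(row_letters), sum(!is.na(col_numbers)),
      length(exp_rows), length(exp_cols),
      min(exp_rows), max(exp_rows), min(exp_cols), max(exp_cols)),
      class = "kinarray_format_error")
  }
  names(grid)[1L] <- "row"
  long <- tidyr::pivot_longer(grid, cols = -"row", names_to = "col",
                              values_to = "score_chr")
  long$col <- as.integer(long$col)
  long <- dplyr::filter(long, !is.na(.data$score_chr), .data$score_chr != "")
  lay <- dplyr::mutate(tibble::as_tibble(layout), col = as.integer(.data$col))
  unknown <- anti_join(long, lay, by = c("row", "col"))
  if (nrow(unknown) > 0L) {
    warn(sprintf("%d scored grid position(s) absent from layout were ignored.",
                 nrow(unknown)))
  }
  joined <- inner_join(long, lay, by = c("row", "col"))
  score_num <- suppressWarnings(as.numeric(joined$score_chr))
  bad <- which(is.na(score_num) | score_num != round(score_num) |
                 score_num < 0 | score_num > 3)
  if (length(bad) > 0L) {
    abort(paste0("Grid scores must be integers in 0-3; invalid at position(s): ",
                 paste(paste0(joined$row[bad], joined$col[bad]), collapse = ", ")),
          class = "kinarray_validation_error")
  }
  out <- tibble(
    construct_id = joined$construct_id,
    strain = strain,
    condition_id = condition_id,
    replicate = as.integer(replicate),
    score = as.integer(score_num)
  )
  if ("protein_id" %in% names(joined)) {
    out <- dplyr::mutate(out, protein_id = joined$protein_id, .before = 1L)
  }
  out
}

#' Read a condition metadata table
#'
#' Conditions are treatment + concentration combinations evaluated in a
#' subset of the strains; `evaluated_<strain>` 0/1 columns record which.
#'
#' @param path TSV with columns `condition_id treatment additive
#'   concentration unit temperature` and one `evaluated_<strain>` flag column
#'   per strain.
#' @return Tibble with evaluation flags as logicals.
#' @export
read_condition_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot("condition_id" %in% names(tab))
  ev <- grep("^evaluated_", names(tab), value = TRUE)
  dplyr::mutate(tab, across(all_of(ev), ~ as.logical(as.integer(.x))))
}

#' Read a kinase/control annotation table
#'
#' @param path TSV with columns `protein_id family_group residue_class
#'   yeast_ortholog is_control is_kinase_dead is_dark is_cancer`.
#' @return Tibble with flag columns as logicals.
#' @export
read_annotation_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot("protein_id" %in% names(tab))
  flags <- intersect(c("yeast_ortholog", "is_control", "is_kinase_dead",
                       "is_dark", "is_cancer"), names(tab))
  dplyr::mutate(tab, across(all_of(flags), ~ as.logical(as.integer(.x))))
}

#' Pivot condition evaluation flags to long form
#'
#' @param conditions Condition tibble as from [read_condition_table()].
#' @return Tibble `condition_id`, `strain`, `evaluated`.
#' @export
condition_strains <- function(conditions) {
  ev <- grep("^evaluated_", names(conditions), value = TRUE)
  if (length(ev) == 0L) {
    abort("Condition table has no evaluated_<strain> columns.")
  }
  tidyr::pivot_longer(conditions[c("condition_id", ev)], cols = all_of(ev),
                      names_to = "strain", names_prefix = "evaluated_",
                      values_to = "evaluated")
}
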