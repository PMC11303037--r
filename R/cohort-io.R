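# Plain-text persistence of cohorts: increments.csv (long format,
# one row per fish-day) and truth.csv (one row per fish).

increment_cols <- c("fish_id", "age_dph", "radius_um",
                    "settlement_index", "stage", "capture_day")
truth_cols <- c("fish_id", "birth_day", "birth_quarter", "pld",
                "settle_day_rel_new_moon", "offshore", "grouped",
                "group_size", "stage_reached", "sex_path")

#' Write a cohort to a directory of CSV files
#'
#' Writes `increments.csv` and `truth.csv` (UTF-8, "." decimal,
#' header row). [read_cohort()] restores the same structures.
#'
#' @param cohort An `otl_cohort` (or list with `increments` and
#'   `truth` data frames).
#' @param path Directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.list(cohort), !is.null(cohort$truth))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  inc <- cohort$increments
  if (is.null(inc)) {
    inc <- as.data.frame(setNames(rep(list(character(0)),
                                      length(increment_cols)),
                                  increment_cols))
  }
  utils::write.csv(inc[, increment_cols, drop = FALSE],
                   file.path(path, "increments.csv"), row.names = FALSE)
  tr <- cohort$truth
  tr$birth_quarter <- as.character(tr$birth_quarter)
  utils::write.csv(tr[, truth_cols, drop = FALSE],
                   file.path(path, "truth.csv"), row.names = FALSE)
  invisible(path)
}

check_numeric_col <- function(raw, parsed, col, file) {
  bad <- which(is.na(parsed) & !is.na(raw) & nzchar(raw))
  if (length(bad)) {
    stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                 file, col, bad[1] + 1L)) # +1 for the header line
  }
  parsed
}

#' Read a cohort from a directory of CSV files
#'
#' Inverse of [write_cohort()]. Malformed numeric fields raise a
#' parse error naming the file, column and line; radius series that
#' are not strictly increasing within a fish, or settlement indices
#' outside the recorded age range, raise validation errors naming the
#' fish.
#'
#' @param path Directory containing `increments.csv` and `truth.csv`.
#' @return An `otl_cohort`.
#' @export
read_cohort <- function(path) {
  fi <- file.path(path, "increments.csv")
  ft <- file.path(path, "truth.csv")
  if (!file.exists(fi) || !file.exists(ft)) {
    stop("cohort directory must contain increments.csv and truth.csv")
  }
  inc <- utils::read.csv(fi, colClasses = "character")
  if (!all(increment_cols %in% names(inc))) {
    stop("increments.csv: missing column(s): ",
         paste(setdiff(increment_cols, names(inc)), collapse = ", "))
  }
  for (col in c("age_dph", "radius_um", "settlement_index",
                "capture_day")) {
    inc[[col]] <- check_numeric_col(inc[[col]],
                                    suppressWarnings(as.numeric(inc[[col]])),
                                    col, "increments.csv")
  }
  inc$age_dph <- as.integer(inc$age_dph)
  inc$settlement_index <- as.integer(inc$settlement_index)

  tr <- utils::read.csv(ft, colClasses = "character")
  if (!all(truth_cols %in% names(tr))) {
    stop("truth.csv: missing column(s): ",
         paste(setdiff(truth_cols, names(tr)), collapse = ", "))
  }
  for (col in c("birth_day", "pld", "settle_day_rel_new_moon",
                "group_size")) {
    tr[[col]] <- check_numeric_col(tr[[col]],
                                   suppressWarnings(as.numeric(tr[[col]])),
                                   col, "truth.csv")
  }
  tr$pld <- as.integer(tr$pld)
  tr$group_size <- as.integer(tr$group_size)
  tr$offshore <- as.logical(tr$offshore)
  tr$grouped <- as.logical(tr$grouped)
  if (nrow(tr) &&
      any(!as.character(tr$birth_quarter) %in% lunar_quarters())) {
    stop("truth.csv: unknown birth_quarter label")
  }
  tr$birth_quarter <- factor(tr$birth_quarter, levels = lunar_quarters())

  if (nrow(inc)) {
    for (id in unique(inc$fish_id)) {
      r <- inc[inc$fish_id == id, ]
      r <- r[order(r$age_dph), ]
      if (any(diff(r$radius_um) <= 0)) {
        stop("increments.csv: radii not strictly increasing for fish ", id)
      }
      si <- unique(r$settlement_index)
      if (length(si) != 1L ||
          (!is.na(si) && (si < 1 || si > max(r$age_dph)))) {
        stop("increments.csv: invalid settlement_index for fish ", id)
      }
    }
  }

  out <- list(increments = inc, truth = tr)
  class(out) <- "otl_cohort"
  out
}
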