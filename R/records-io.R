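#' Observation records for a burrow-structured breeding season
#'
#' An `observation_set` bundles the four tables the analyses consume:
#'
#' * `roster`: one row per individual — `id`, `sex` (`"male"`/`"female"`),
#'   `emergence_day`, `death_day` (integer day indices from an arbitrary
#'   season origin; when death is unobserved the last observation day
#'   stands in for it, so the stored value is always the resolved one).
#' * `occupancy`: total time observed per individual per burrow —
#'   `individual_id`, `burrow_id`, `duration` (nonnegative, in
#'   observation days/hours; only relative magnitudes matter).
#' * `fights`: one row per fight — `day`, `arriving_male_id`,
#'   `resident_male_id`, `burrow_id`.  Repeated rows are distinct fights.
#' * `matings`: one row per mating — `day`, `male_id`, `female_id`,
#'   `spermatophore_transferred` (logical).  Rows with
#'   `spermatophore_transferred = FALSE` are retained here; filtering to
#'   successful transfers happens in network construction.
#'
#' Validation enforces unique roster ids, `emergence_day <= death_day`,
#' nonnegative durations, correct sexes in fight/mating events, and that
#' all event ids resolve to roster rows.  Event days outside a
#' participant's adult lifespan raise a warning by default (they occur in
#' imperfect field data) and an error when
#' `lifespan_violation = "error"`.
#'
#' @param roster,occupancy,fights,matings data frames with the columns
#'   described above.  Missing event tables default to empty.
#' @param lifespan_violation `"warn"` (default) or `"error"`.
#' @return A validated `observation_set`; its tables are canonically
#'   sorted so that equal sets compare identical regardless of input row
#'   order.
#' @seealso [read_observation_set()], [write_observation_set()]
#' @export
observation_set <- function(roster,
                            occupancy = empty_occupancy(),
                            fights = empty_fights(),
                            matings = empty_matings(),
                            lifespan_violation = c("warn", "error")) {
  lifespan_violation <- match.arg(lifespan_violation)
  roster <- check_columns(roster, "roster",
                          c("id", "sex", "emergence_day", "death_day"))
  occupancy <- check_columns(occupancy, "occupancy",
                             c("individual_id", "burrow_id", "duration"))
  fights <- check_columns(fights, "fights",
                          c("day", "arriving_male_id", "resident_male_id",
                            "burrow_id"))
  matings <- check_columns(matings, "matings",
                           c("day", "male_id", "female_id",
                             "spermatophore_transferred"))

  roster$id <- as.character(roster$id)
  roster$sex <- as.character(roster$sex)
  roster$emergence_day <- as.integer(roster$emergence_day)
  roster$death_day <- as.integer(roster$death_day)
  occupancy$individual_id <- as.character(occupancy$individual_id)
  occupancy$burrow_id <- as.character(occupancy$burrow_id)
  occupancy$duration <- as.numeric(occupancy$duration)
  fights$day <- as.integer(fights$day)
  fights$arriving_male_id <- as.character(fights$arriving_male_id)
  fights$resident_male_id <- as.character(fights$resident_male_id)
  fights$burrow_id <- as.character(fights$burrow_id)
  matings$day <- as.integer(matings$day)
  matings$male_id <- as.character(matings$male_id)
  matings$female_id <- as.character(matings$female_id)
  matings$spermatophore_transferred <-
    parse_logical(matings$spermatophore_transferred, "spermatophore_transferred")

  if (anyDuplicated(roster$id)) {
    stop("duplicate roster ids: ",
         paste(unique(roster$id[duplicated(roster$id)]), collapse = ", "))
  }
  bad_sex <- !roster$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("roster 'sex' must be 'male' or 'female'; offending ids: ",
         paste(roster$id[bad_sex], collapse = ", "))
  }
  bad_life <- roster$emergence_day > roster$death_day
  if (any(bad_life)) {
    stop("emergence_day after death_day for: ",
         paste(roster$id[bad_life], collapse = ", "))
  }
  if (any(occupancy$duration < 0)) {
    stop("occupancy durations must be nonnegative")
  }

  males <- roster$id[roster$sex == "male"]
  females <- roster$id[roster$sex == "female"]

  check_known_ids(occupancy$individual_id, roster$id, "occupancy", "individual_id")
  check_known_ids(fights$arriving_male_id, males, "fights", "arriving_male_id",
                  universe = "male roster")
  check_known_ids(fights$resident_male_id, males, "fights", "resident_male_id",
                  universe = "male roster")
  check_known_ids(matings$male_id, males, "matings", "male_id",
                  universe = "male roster")
  check_known_ids(matings$female_id, females, "matings", "female_id",
                  universe = "female roster")
  if (any(fights$arriving_male_id == fights$resident_male_id)) {
    stop("fights with identical arriving and resident male in rows: ",
         paste(which(fights$arriving_male_id == fights$resident_male_id),
               collapse = ", "))
  }

  check_event_days(fights, c("arriving_male_id", "resident_male_id"),
                   roster, "fights", lifespan_violation)
  check_event_days(matings, c("male_id", "female_id"),
                   roster, "matings", lifespan_violation)

  obs <- list(
    roster = sort_by_cols(roster, c("id")),
    occupancy = sort_by_cols(occupancy, c("individual_id", "burrow_id")),
    fights = sort_by_cols(fights, c("day", "arriving_male_id",
                                    "resident_male_id", "burrow_id")),
    matings = sort_by_cols(matings, c("day", "male_id", "female_id",
                                      "spermatophore_transferred"))
  )
  class(obs) <- "observation_set"
  obs
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf(
    "<observation_set: %d individuals (%d male, %d female), %d occupancy records, %d fights, %d matings>\n",
    nrow(x$roster), sum(x$roster$sex == "male"), sum(x$roster$sex == "female"),
    nrow(x$occupancy), nrow(x$fights), nrow(x$matings)))
  invisible(x)
}

empty_occupancy <- function() {
  data.frame(individual_id = character(), burrow_id = character(),
             duration = numeric())
}
empty_fights <- function() {
  data.frame(day = integer(), arriving_male_id = character(),
             resident_male_id = character(), burrow_id = character())
}
empty_matings <- function() {
  data.frame(day = integer(), male_id = character(), female_id = character(),
             spermatophore_transferred = logical())
}

check_columns <- function(df, name, cols) {
  if (!is.data.frame(df)) stop("'", name, "' must be a data frame")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop("schema error in '", name, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df[cols]
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- ifelse(v %in% c("true", "t", "1"), TRUE,
                ifelse(v %in% c("false", "f", "0"), FALSE, NA))
  if (anyNA(out) && !anyNA(x)) {
    stop("column '", what, "' has values not interpretable as logical")
  }
  out
}

check_known_ids <- function(ids, universe_ids, table, column,
                            universe = "roster") {
  bad <- !ids %in% universe_ids
  if (any(bad)) {
    stop("referential error in '", table, "': column '", column,
         "' has ids absent from the ", universe, " in row(s) ",
         paste(utils::head(which(bad), 10), collapse = ", "),
         " (ids: ", paste(utils::head(unique(ids[bad]), 10), collapse = ", "),
         ")")
  }
  invisible(TRUE)
}

check_event_days <- function(events, id_cols, roster, table, action) {
  if (nrow(events) == 0) return(invisible(TRUE))
  emergence <- stats::setNames(roster$emergence_day, roster$id)
  death <- stats::setNames(roster$death_day, roster$id)
  bad <- rep(FALSE, nrow(events))
  for (col in id_cols) {
    ids <- events[[col]]
    bad <- bad | events$day < emergence[ids] | events$day > death[ids]
  }
  if (any(bad)) {
    msg <- paste0("'", table, "' has ", sum(bad),
                  " event(s) outside a participant's adult lifespan (rows ",
                  paste(utils::head(which(bad), 10), collapse = ", "), ")")
    if (action == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

sort_by_cols <- function(df, cols) {
  if (nrow(df) == 0) {
    rownames(df) <- NULL
    return(df)
  }
  ord <- do.call(order, c(unname(df[cols]), list(method = "radix")))
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

obs_csv_files <- c(roster = "roster.csv", occupancy = "occupancy.csv",
                   fights = "fights.csv", matings = "matings.csv")

#' Read an observation set from four CSV files
#'
#' Reads `roster.csv`, `occupancy.csv`, `fights.csv` and `matings.csv`
#' from a directory (or from explicitly named paths) and returns a fully
#' validated [observation_set()].  Files are comma-separated UTF-8 with a
#' header row; `spermatophore_transferred` is written/read as
#' `true`/`false`.
#'
#' @param dir directory containing the four CSV files under their
#'   canonical names.  Alternatively supply all four `*_path` arguments.
#' @param roster_path,occupancy_path,fights_path,matings_path explicit
#'   file paths overriding `dir`.
#' @inheritParams observation_set
#' @return An [observation_set()].
#' @export
read_observation_set <- function(dir = NULL,
                                 roster_path = NULL, occupancy_path = NULL,
                                 fights_path = NULL, matings_path = NULL,
                                 lifespan_violation = c("warn", "error")) {
  paths <- c(roster = roster_path, occupancy = occupancy_path,
             fights = fights_path, matings = matings_path)
  if (is.null(dir)) {
    if (length(paths) != 4) {
      stop("supply either 'dir' or all four explicit file paths")
    }
  } else {
    paths <- file.path(dir, obs_csv_files)
    names(paths) <- names(obs_csv_files)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  read1 <- function(p) {
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character")
  }
  observation_set(roster = read1(paths[["roster"]]),
                  occupancy = read1(paths[["occupancy"]]),
                  fights = read1(paths[["fights"]]),
                  matings = read1(paths[["matings"]]),
                  lifespan_violation = lifespan_violation)
}

#' Write an observation set as four CSV files
#'
#' Writes the canonical, sorted tables so output is byte-stable for a
#' given observation set: `read_observation_set()` on the written
#' directory reproduces the input exactly.
#'
#' @param obs an [observation_set()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the four file paths written.
#' @export
write_observation_set <- function(obs, dir) {
  stopifnot(inherits(obs, "observation_set"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory: ", dir)
  }
  paths <- file.path(dir, obs_csv_files)
  names(paths) <- names(obs_csv_files)
  tables <- obs[names(obs_csv_files)]
  tables$matings$spermatophore_transferred <-
    ifelse(tables$matings$spermatophore_transferred, "true", "false")
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (nm == "occupancy" && nrow(df) > 0) {
      # fixed decimal formatting keeps round-trips and diffs byte-stable
      df$duration <- format_number(df$duration)
    }
    utils::write.csv(df, paths[[nm]], row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(paths)
}

format_number <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  trimws(out)
}
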