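#' Read a mapped-colony table
#'
#' Reads a comma-delimited table of mapped colonies, one row per colony, and
#' validates it. Required columns: `colony_id`, `x`, `y` (planar coordinates,
#' metres, local frame), `planar_area` (m^2, > 0), `gravid` (true/false) and
#' `depth_class` (`"shallow"` or `"deeper"`).
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` of class `colony_table`.
#' @seealso [write_colony_table()], [generate_colony_map()]
#' @export
read_colony_table <- function(path) {
  raw <- read_raw_csv(path)
  require_columns(raw, c("colony_id", "x", "y", "planar_area", "gravid",
                         "depth_class"), "colony table")
  df <- data.frame(
    colony_id   = as.character(raw$colony_id),
    x           = parse_num(raw$x, "x"),
    y           = parse_num(raw$y, "y"),
    planar_area = parse_num(raw$planar_area, "planar_area"),
    gravid      = parse_bool(raw$gravid, "gravid"),
    depth_class = as.character(raw$depth_class),
    stringsAsFactors = FALSE
  )
  validate_colony_table(df)
}

#' Validate a colony table
#'
#' Enforces the colony-table invariants: unique ids, finite coordinates,
#' strictly positive planar areas and known depth classes.
#'
#' @param df A data.frame with colony-table columns.
#' @return `df`, classed as `colony_table`, invisibly unchanged otherwise.
#' @export
validate_colony_table <- function(df) {
  dup <- df$colony_id[duplicated(df$colony_id)]
  if (length(dup))
    stop("validation error: duplicate colony_id: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("validation error: non-finite coordinates", call. = FALSE)
  if (any(!is.finite(df$planar_area) | df$planar_area <= 0))
    stop("validation error: planar_area must be > 0", call. = FALSE)
  bad <- setdiff(unique(df$depth_class), c("shallow", "deeper"))
  if (length(bad))
    stop("validation error: unknown depth_class: ",
         paste(bad, collapse = ", "), call. = FALSE)
  class(df) <- c("colony_table", "data.frame")
  df
}

#' Read a spawn-event table
#'
#' One row per colony-night observation. Columns: `colony_id`, `night`
#' (`"n1"`/`"n2"`), `release_minute` (integer, minute 1 = first observed
#' release that night; empty when no release), `extent` (`"none"`,
#' `"partial"`, `"extensive"`, or empty when not reliably observed) and
#' `observer_id`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` of class `spawn_table`.
#' @export
read_spawn_events <- function(path) {
  raw <- read_raw_csv(path)
  require_columns(raw, c("colony_id", "night", "release_minute", "extent",
                         "observer_id"), "spawn-event table")
  df <- data.frame(
    colony_id      = as.character(raw$colony_id),
    night          = as.character(raw$night),
    release_minute = parse_int(raw$release_minute, "release_minute",
                               allow_na = TRUE),
    extent         = ifelse(nzchar(trimws(as.character(raw$extent))),
                            as.character(raw$extent), NA_character_),
    observer_id    = as.character(raw$observer_id),
    stringsAsFactors = FALSE
  )
  validate_spawn_events(df)
}

#' @rdname read_spawn_events
#' @param df A data.frame with spawn-event columns.
#' @export
validate_spawn_events <- function(df) {
  check_night(df$night)
  bad <- setdiff(stats::na.omit(unique(df$extent)),
                 c("none", "partial", "extensive"))
  if (length(bad))
    stop("validation error: unknown extent: ", paste(bad, collapse = ", "),
         call. = FALSE)
  released <- !is.na(df$extent) & df$extent != "none"
  if (any(released & (is.na(df$release_minute) | df$release_minute < 1)))
    stop("validation error: release_minute must be >= 1 for releasing colonies",
         call. = FALSE)
  if (anyDuplicated(df[c("colony_id", "night")]))
    stop("validation error: duplicate colony-night in spawn events",
         call. = FALSE)
  class(df) <- c("spawn_table", "data.frame")
  df
}

#' Read a fertilization-sample table
#'
#' One row per colony-night egg sample. Columns: `colony_id`, `night`,
#' `n_scored` (eggs examined, >= 1), `n_fertilized`, `n_damage_scored`
#' (subset additionally scored for damage; optional column, 0 when absent),
#' `n_damaged`, and optional `dispersal_group`.
#'
#' @param path Path to a CSV file with a header row.
#' @return A `data.frame` of class `fert_table`.
#' @export
read_fert_samples <- function(path) {
  raw <- read_raw_csv(path)
  require_columns(raw, c("colony_id", "night", "n_scored", "n_fertilized"),
                  "fertilization-sample table")
  n <- nrow(raw)
  df <- data.frame(
    colony_id       = as.character(raw$colony_id),
    night           = as.character(raw$night),
    n_scored        = parse_int(raw$n_scored, "n_scored"),
    n_fertilized    = parse_int(raw$n_fertilized, "n_fertilized"),
    n_damage_scored = if ("n_damage_scored" %in% names(raw))
      parse_int(raw$n_damage_scored, "n_damage_scored") else integer(n),
    n_damaged       = if ("n_damaged" %in% names(raw))
      parse_int(raw$n_damaged, "n_damaged") else integer(n),
    dispersal_group = if ("dispersal_group" %in% names(raw))
      ifelse(nzchar(trimws(as.character(raw$dispersal_group))),
             as.character(raw$dispersal_group), NA_character_)
    else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  validate_fert_samples(df)
}

#' @rdname read_fert_samples
#' @param df A data.frame with fertilization-sample columns.
#' @export
validate_fert_samples <- function(df) {
  check_night(df$night)
  if (any(df$n_scored < 1))
    stop("validation error: n_scored must be >= 1", call. = FALSE)
  if (any(df$n_fertilized < 0 | df$n_fertilized > df$n_scored))
    stop("validation error: n_fertilized must lie in [0, n_scored]",
         call. = FALSE)
  if (any(df$n_damage_scored < 0))
    stop("validation error: n_damage_scored must be >= 0", call. = FALSE)
  if (any(df$n_damaged < 0 | df$n_damaged > df$n_damage_scored))
    stop("validation error: n_damaged must lie in [0, n_damage_scored]",
         call. = FALSE)
  class(df) <- c("fert_table", "data.frame")
  df
}

#' Write pipeline tables
#'
#' CSV writers matched to the three readers; `read_*(write_*(x))` is the
#' identity. Booleans are written as `true`/`false`, missing values as empty
#' fields.
#'
#' @param df Table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_colony_table <- function(df, path) {
  out <- as.data.frame(df)
  out$gravid <- ifelse(out$gravid, "true", "false")
  write_csv(out, path)
}

#' @rdname write_colony_table
#' @export
write_spawn_events <- function(df, path) write_csv(as.data.frame(df), path)

#' @rdname write_colony_table
#' @export
write_fert_samples <- function(df, path) write_csv(as.data.frame(df), path)

#' Pipeline run configuration
#'
#' Bundles the tunable settings of the full analysis: density radii,
#' weighted-area window and decay length, the nearest-neighbour grid used for
#' the cubic approximation, the candidate model list and the random seed.
#'
#' @param radii Radii (m) for the local-density metrics.
#' @param wa_radius Radius (m) of the weighted-colony-area window.
#' @param lambda Exponential decay length (m) of the distance weighting.
#' @param grid `c(min, max, step)` (m) nearest-neighbour grid for [fit_cubic()].
#' @param models Named list of [model_spec()] candidates to compare.
#' @param seed Integer seed; identical config + inputs give identical outputs.
#' @param n_perm Number of permutations for the synchrony slope test.
#' @return A list of class `run_config`.
#' @export
run_config <- function(radii = c(2, 5, 10), wa_radius = 10, lambda = 5,
                       grid = c(0, 20, 0.1), models = default_model_set(),
                       seed = 1L, n_perm = 9999L) {
  stopifnot(all(radii > 0), wa_radius > 0, lambda > 0,
            length(grid) == 3, grid[3] > 0, grid[2] > grid[1])
  structure(list(radii = radii, wa_radius = wa_radius, lambda = lambda,
                 grid = grid, models = models, seed = as.integer(seed),
                 n_perm = as.integer(n_perm)),
            class = "run_config")
}

## ---- internal parsing helpers -------------------------------------------

read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
}

write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error: ", what, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(df)
}

parse_num <- function(x, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & nzchar(trimws(x)) | !nzchar(trimws(x)))
  if (length(bad))
    stop("parse error: column '", col, "' non-numeric at row ", bad[1],
         call. = FALSE)
  out
}

parse_int <- function(x, col, allow_na = FALSE) {
  x <- trimws(as.character(x))
  empty <- !nzchar(x) | toupper(x) == "NA"
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out) & !empty)
  if (length(bad))
    stop("parse error: column '", col, "' non-integer at row ", bad[1],
         call. = FALSE)
  if (!allow_na && any(empty))
    stop("parse error: column '", col, "' has missing values", call. = FALSE)
  out
}

parse_bool <- function(x, col) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  if (anyNA(out))
    stop("parse error: column '", col, "' not true/false at row ",
         which(is.na(out))[1], call. = FALSE)
  out
}

check_night <- function(night) {
  bad <- setdiff(unique(night), c("n1", "n2"))
  if (length(bad))
    stop("validation error: night must be 'n1' or 'n2', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(night)
}
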