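#' Diet profile matrix
#'
#' Rows are profile units (fecal samples, observation days, months, seasons,
#' or individual/season cells), columns are taxa or observed items. Rows of
#' compositional profiles sum to 1; all-zero rows are allowed only for units
#' with no retained items and are flagged.
#'
#' @param values non-negative numeric matrix, rownames = unit ids.
#' @param meta data.frame with one row per unit (any of `individual_id`,
#'   `group_id`, `date`, `season`, `temporal_unit`).
#' @param source `"edna"` or `"focal"`.
#' @param normalized whether rows are closed compositions (sum to 1) as
#'   opposed to rates.
#' @return object of class `diet_profile`.
#' @export
diet_profile <- function(values, meta, source = "edna", normalized = TRUE) {
  values <- as.matrix(values)
  if (any(values < 0)) stop("profile values must be non-negative")
  meta <- as.data.frame(meta)
  if (nrow(meta) != nrow(values)) stop("meta and values disagree on units")
  rs <- rowSums(values)
  if (normalized && any(rs > 0 & abs(rs - 1) > 1e-9))
    stop("non-empty rows of a normalized profile must sum to 1")
  structure(list(values = values, meta = meta, source = source,
                 normalized = normalized, empty = rs == 0),
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("<diet_profile> %d units x %d items (%s, %s)%s\n",
              nrow(x$values), ncol(x$values), x$source,
              if (x$normalized) "compositional" else "rates",
              if (any(x$empty)) sprintf(", %d empty", sum(x$empty)) else ""))
  invisible(x)
}

#' Relative read abundance (RRA) per sample
#'
#' Divides each sample's counts by that sample's total read count. Samples
#' with no retained reads give all-zero rows, flagged as empty.
#'
#' @param samples a [sample_table()].
#' @return a `diet_profile` with samples as rows and taxa as columns.
#' @export
to_rra <- function(samples) {
  v <- t(samples$values)
  rs <- rowSums(v)
  v[rs > 0, ] <- v[rs > 0, , drop = FALSE] / rs[rs > 0]
  meta <- samples$samples
  rownames(v) <- meta$sample_id
  diet_profile(v, meta, source = "edna")
}

#' Daily observation rates from a focal log
#'
#' Items observed only once in the whole log are dropped first; then for
#' every observation day, each remaining item's event count is divided by
#' the total number of focal screenings conducted that day. Rows are rates
#' (they sum to at most 1 only if every screening records at most one item);
#' renormalize with [close_profile()] before compositional analyses.
#'
#' @param log a `focal_log` (see [gen_focal_log()]).
#' @return a `diet_profile` (rates) with attribute `"item_totals"`, the
#'   per-item event totals after single-occurrence removal.
#' @export
normalize_focal <- function(log) {
  ev <- log$events
  tot <- base::table(ev$item)
  ev <- ev[ev$item %in% names(tot)[tot > 1], , drop = FALSE]
  scr <- log$screenings
  if (nrow(ev)) {
    miss <- setdiff(as.character(unique(ev$date)), as.character(scr$date))
    if (length(miss))
      stop("feeding events on days without screening counts: ",
           paste(miss, collapse = ", "))
    if (any(scr$n_screenings <= 0))
      stop("screening counts must be positive")
  }
  items <- sort(unique(ev$item))
  days <- sort(unique(scr$date))
  m <- matrix(0, length(days), length(items),
              dimnames = list(as.character(days), items))
  if (nrow(ev)) {
    cnt <- base::table(factor(as.character(ev$date),
                              levels = as.character(days)),
                       factor(ev$item, levels = items))
    m <- matrix(as.numeric(cnt), nrow = length(days),
                dimnames = dimnames(m))
    m <- m / scr$n_screenings[match(days, scr$date)]
  }
  out <- diet_profile(m, data.frame(date = days), source = "focal",
                      normalized = FALSE)
  attr(out, "item_totals") <- stats::setNames(
    as.numeric(base::table(factor(ev$item, levels = items))), items)
  out
}

#' Renormalize profile rows to sum to one
#' @param profile a `diet_profile` (typically daily focal rates).
#' @return a compositional `diet_profile`.
#' @export
close_profile <- function(profile) {
  v <- profile$values
  rs <- rowSums(v)
  v[rs > 0, ] <- v[rs > 0, , drop = FALSE] / rs[rs > 0]
  diet_profile(v, profile$meta, source = profile$source, normalized = TRUE)
}

#' Season calendar with mid-month boundaries
#'
#' The default is the southern-hemisphere study calendar: spring from
#' 16 August, summer from 16 November, autumn from 16 March, winter from
#' 16 May. Days on or after the boundary day of a boundary month belong to
#' the following season; the mapping is independent of the year.
#'
#' @param seasons character vector of season names in within-year order of
#'   their start dates.
#' @param start_month,start_day parallel vectors of boundary dates.
#' @return object of class `season_calendar`.
#' @export
season_calendar <- function(seasons = c("autumn", "winter", "spring", "summer"),
                            start_month = c(3, 5, 8, 11),
                            start_day = c(16, 16, 16, 16)) {
  stopifnot(length(seasons) == length(start_month),
            length(seasons) == length(start_day))
  key <- start_month * 100 + start_day
  o <- order(key)
  structure(list(seasons = seasons[o], key = key[o]),
            class = "season_calendar")
}

#' Map dates to seasons
#'
#' @param dates `Date` vector (or parseable strings).
#' @param calendar a [season_calendar()].
#' @return character vector of season names.
#' @export
season_of <- function(dates, calendar = season_calendar()) {
  dates <- as.Date(dates)
  md <- as.integer(format(dates, "%m")) * 100 + as.integer(format(dates, "%d"))
  idx <- findInterval(md, calendar$key)
  idx[idx == 0] <- length(calendar$seasons)  # before first boundary: wrap
  calendar$seasons[idx]
}

#' Aggregate profile rows by month or season
#'
#' Unweighted mean of rows per temporal unit, ignoring the year (data from
#' the same month of different years are pooled).
#'
#' @param profiles a `diet_profile` whose meta has a `date` column (or a
#'   `season` column when `unit = "season"` and dates are absent).
#' @param unit `"month"` or `"season"`.
#' @param calendar a [season_calendar()] (used for `unit = "season"`).
#' @return a `diet_profile` with one row per temporal unit present;
#'   `meta$temporal_unit` holds the unit labels.
#' @export
aggregate_temporal <- function(profiles, unit = c("month", "season"),
                               calendar = season_calendar()) {
  unit <- match.arg(unit)
  if (!nrow(profiles$values)) stop("empty profile")
  lab <- if (unit == "month") {
    format(as.Date(profiles$meta$date), "%m")
  } else if (!is.null(profiles$meta$season)) {
    as.character(profiles$meta$season)
  } else {
    season_of(profiles$meta$date, calendar)
  }
  m <- rowsum(profiles$values, lab) / as.vector(base::table(lab)[sort(unique(lab))])
  diet_profile(m, data.frame(temporal_unit = rownames(m)),
               source = profiles$source, normalized = profiles$normalized)
}

#' Equal-weight individual/season profiles
#'
#' To avoid pseudo-replication, every individual contributes a single row
#' per season: that individual's sample rows within the season are averaged
#' and the mean renormalized to sum to 1.
#'
#' @param profiles a `diet_profile` with `individual_id` and either `season`
#'   or `date` metadata.
#' @param calendar a [season_calendar()] used when only dates are present.
#' @return a compositional `diet_profile`, one row per individual/season;
#'   meta has `individual_id` and `season`.
#' @export
individual_weighted <- function(profiles, calendar = season_calendar()) {
  meta <- profiles$meta
  if (is.null(meta$individual_id)) stop("individual_id metadata required")
  season <- if (!is.null(meta$season)) as.character(meta$season)
            else season_of(meta$date, calendar)
  key <- paste(meta$individual_id, season, sep = "|")
  m <- rowsum(profiles$values, key) / as.vector(base::table(key)[sort(unique(key))])
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  parts <- strsplit(rownames(m), "|", fixed = TRUE)
  diet_profile(m, data.frame(individual_id = vapply(parts, `[`, "", 1),
                             season = vapply(parts, `[`, "", 2)),
               source = profiles$source, normalized = TRUE)
}

#' Per-individual/season relative observation profiles from a focal log
#'
#' Aggregates feeding events per focal individual and season and transforms
#' them to relative abundances (after single-occurrence item removal), the
#' observational analogue of [individual_weighted()].
#'
#' @param log a `focal_log`.
#' @param calendar a [season_calendar()].
#' @return a compositional `diet_profile`.
#' @export
focal_individual_profiles <- function(log, calendar = season_calendar()) {
  ev <- log$events
  tot <- base::table(ev$item)
  ev <- ev[ev$item %in% names(tot)[tot > 1], , drop = FALSE]
  if (!nrow(ev)) stop("no repeated items in focal log")
  season <- season_of(ev$date, calendar)
  key <- paste(ev$individual_id, season, sep = "|")
  items <- sort(unique(ev$item))
  cnt <- base::table(factor(key), factor(ev$item, levels = items))
  m <- matrix(as.numeric(cnt), nrow = nrow(cnt), dimnames = dimnames(cnt))
  m <- m / rowSums(m)
  parts <- strsplit(rownames(m), "|", fixed = TRUE)
  diet_profile(m, data.frame(individual_id = vapply(parts, `[`, "", 1),
                             season = vapply(parts, `[`, "", 2)),
               source = "focal", normalized = TRUE)
}

#' Write / read a diet profile as TSV (metadata columns first)
#' @param profile a `diet_profile`.
#' @param path TSV path.
#' @return `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  df <- cbind(profile$meta, as.data.frame(profile$values))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
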