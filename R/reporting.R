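round_half_up <- function(x, digits = 2) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Identification rate as a printed percentage
#'
#' `100 * identified / total`, rounded half-up to two decimals (the
#' precision used in reported tables: 12,315 of 19,406 observations gives
#' 63.46).
#'
#' @param total,identified non-negative counts, `identified <= total`,
#'   `total > 0`.
#' @return percentage rounded to 2 decimals.
#' @export
identification_rate <- function(total, identified) {
  if (total <= 0) stop("total must be positive")
  if (identified < 0 || identified > total)
    stop("identified must lie in [0, total]")
  round_half_up(100 * identified / total, 2)
}

#' Read accounting across host removal and assignment
#'
#' Partitions a library's reads into host and non-host, and reports the
#' fraction of non-host reads that received a taxonomic assignment
#' (`assigned_percent`, 2 decimals), plus the numbers of distinct orders,
#' families, genera and species among the assignments.
#'
#' @param total_reads total reads before host removal (or a [read_table()]).
#' @param host_reads reads assigned to host taxa.
#' @param assigned_reads reads retained with a taxonomic assignment after
#'   final filtering.
#' @param assignments optional assignment table used to count distinct taxa
#'   per rank.
#' @return a `read_accounting` list: `total_reads`, `host_reads`,
#'   `remaining_reads`, `assigned_reads`, `assigned_percent`, `n_taxa`.
#' @export
read_accounting <- function(total_reads, host_reads, assigned_reads,
                            assignments = NULL) {
  if (inherits(total_reads, "read_table"))
    total_reads <- sum(total_reads$counts)
  remaining <- total_reads - host_reads
  if (remaining < 0) stop("host reads exceed total")
  if (assigned_reads < 0 || assigned_reads > remaining)
    stop("assigned reads must lie in [0, remaining]")
  n_taxa <- c(order = NA_integer_, family = NA_integer_,
              genus = NA_integer_, species = NA_integer_)
  if (!is.null(assignments)) {
    paths <- strsplit(assignments$assigned_path[
      assignments$matched_db != "none"], ";", fixed = TRUE)
    for (k in 2:5) {
      lv <- unlist(lapply(paths, function(p) if (length(p) >= k) p[k]))
      n_taxa[RANKS[k]] <- length(unique(lv))
    }
  }
  structure(list(total_reads = total_reads, host_reads = host_reads,
                 remaining_reads = remaining,
                 assigned_reads = assigned_reads,
                 assigned_percent = round_half_up(
                   100 * assigned_reads / remaining, 2),
                 n_taxa = n_taxa),
            class = "read_accounting")
}

#' @export
print.read_accounting <- function(x, ...) {
  cat(sprintf(
    "reads: %s total, %s host, %s remaining; %s assigned (%.2f%%)\n",
    format(x$total_reads, big.mark = ","),
    format(x$host_reads, big.mark = ","),
    format(x$remaining_reads, big.mark = ","),
    format(x$assigned_reads, big.mark = ","), x$assigned_percent))
  invisible(x)
}

#' Reference database summary
#'
#' @param db a [reference_db()].
#' @return list: `n_sequences` (distinct sequences), `n_species` (distinct
#'   species labels), `sharing` (named histogram: labels-per-sequence ->
#'   number of sequences).
#' @export
refdb_summary <- function(db) {
  if (!nrow(db))
    return(list(n_sequences = 0L, n_species = 0L,
                sharing = integer(0)))
  per_seq <- vapply(split(db$species, db$seq_id),
                    function(x) length(unique(x)), 1L)
  hist <- base::table(per_seq)
  list(n_sequences = length(per_seq),
       n_species = length(unique(db$species)),
       sharing = stats::setNames(as.integer(hist), names(hist)))
}

#' Overlap between eDNA and observational item sets
#'
#' Partitions the union of the two item sets into eDNA-only, shared and
#' focal-only. A multi-species barcode label (`"A/B"`) counts as shared
#' when any member species was observed.
#'
#' @param edna_items,focal_items character vectors of item labels at a
#'   comparable rank.
#' @return a `method_overlap` list of the three disjoint sets and counts.
#' @export
method_overlap <- function(edna_items, focal_items) {
  edna_items <- unique(edna_items); focal_items <- unique(focal_items)
  shared_edna <- vapply(edna_items, function(x) {
    members <- strsplit(x, "/", fixed = TRUE)[[1]]
    x %in% focal_items || any(members %in% focal_items)
  }, logical(1))
  shared <- edna_items[shared_edna]
  matched_focal <- focal_items[focal_items %in% c(
    shared, unlist(strsplit(shared, "/", fixed = TRUE)))]
  structure(list(
    items_edna_only = setdiff(edna_items, shared),
    items_shared = shared,
    items_focal_only = setdiff(focal_items, matched_focal),
    n_edna_only = length(setdiff(edna_items, shared)),
    n_shared = length(shared),
    n_focal_only = length(setdiff(focal_items, matched_focal))),
    class = "method_overlap")
}

#' Fraction of samples containing target taxa, per season
#'
#' @param samples a taxon-level [sample_table()].
#' @param target_taxa character vector of row labels to look for.
#' @param calendar a [season_calendar()].
#' @return named per-season percentages (2 decimals) of samples with at
#'   least one retained read of any target taxon.
#' @export
seasonal_detection_rate <- function(samples, target_taxa,
                                    calendar = season_calendar()) {
  season <- season_of(samples$samples$collection_date, calendar)
  hit <- colSums(samples$values[rownames(samples$values) %in% target_taxa, ,
                                drop = FALSE]) > 0
  rates <- vapply(split(hit, season), function(h) mean(h) * 100, numeric(1))
  round_half_up(rates, 2)
}
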