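#' @importFrom stats rgamma rbinom rlnorm rmultinom rpois runif quantile
#'   wilcox.test cor cor.test pt ecdf setNames aggregate
#' @importFrom utils adist head
NULL

UNIT_TYPES <- c("sample", "blank", "extraction_negative", "pcr_negative",
                "positive_control")
CONTROL_TYPES <- setdiff(UNIT_TYPES, "sample")
NEGATIVE_TYPES <- c("extraction_negative", "pcr_negative")

#' Read-count table for one sequencing library
#'
#' The central container of the curation cascade: an integer count matrix of
#' unique sequences (rows) by PCR-replicate units (columns), together with
#' per-unit metadata. Units are individual PCR wells: three replicate wells
#' per fecal sample plus control wells (blanks, extraction negatives, PCR
#' negatives, positive controls).
#'
#' @param counts non-negative integer matrix, one row per unique sequence
#'   (rownames are the uppercase ACGT sequences) and one column per unit
#'   (colnames are unit ids).
#' @param units data.frame with one row per unit and columns `unit_id`,
#'   `sample_id`, `individual_id`, `group_id`, `collection_date` (`Date` or
#'   NA for controls), `replicate_index`, `unit_type` (one of
#'   `r paste(UNIT_TYPES, collapse = ", ")`).
#' @param library_id identifier of the sequencing library the table came from.
#'
#' @return an object of class `read_table`.
#' @export
read_table <- function(counts, units, library_id = "lib1") {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0 && is.null(rownames(counts)))
    stop("counts must have sequence rownames")
  if (anyDuplicated(rownames(counts))) stop("sequences must be unique")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (!grepl("^[ACGT]*$", paste(rownames(counts), collapse = "")))
    stop("sequences must be uppercase ACGT strings")
  units <- as.data.frame(units)
  req <- c("unit_id", "sample_id", "individual_id", "group_id",
           "collection_date", "replicate_index", "unit_type")
  miss <- setdiff(req, names(units))
  if (length(miss)) stop("units missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(units$unit_id)) stop("unit_ids must be unique")
  if (!all(units$unit_type %in% UNIT_TYPES))
    stop("unknown unit_type values")
  if (is.null(colnames(counts))) colnames(counts) <- units$unit_id
  if (!identical(sort(colnames(counts)), sort(as.character(units$unit_id))))
    stop("count columns and unit metadata do not match")
  counts <- counts[, as.character(units$unit_id), drop = FALSE]
  storage.mode(counts) <- "double"   # filtered stages stay integral; means are not
  structure(list(counts = counts, units = units, library_id = library_id),
            class = "read_table")
}

#' @export
print.read_table <- function(x, ...) {
  cat(sprintf(
    "<read_table> library '%s': %d sequences x %d units (%d sample, %d control), %s reads\n",
    x$library_id, nrow(x$counts), ncol(x$counts),
    sum(x$units$unit_type == "sample"),
    sum(x$units$unit_type != "sample"),
    format(total_reads(x), big.mark = ",")))
  invisible(x)
}

#' Total read count of a read table
#' @param table a [read_table()].
#' @return scalar read total over all units.
#' @export
total_reads <- function(table) sum(table$counts)

sequences_of <- function(table) rownames(table$counts) %||% character(0)

unit_is <- function(table, types) table$units$unit_type %in% types

# Replace the count matrix, dropping all-zero sequences optionally.
replace_counts <- function(table, counts, drop_empty = FALSE) {
  if (drop_empty && nrow(counts)) {
    counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  }
  table$counts <- counts
  table
}

# Keep a subset of sequences (logical or character index).
keep_sequences <- function(table, keep) {
  table$counts <- table$counts[keep, , drop = FALSE]
  table
}

#' Per-stage filter report entry
#'
#' Records read and sequence accounting for one curation stage; the invariant
#' `reads_in == reads_out + reads_removed` holds for every stage.
#'
#' @param stage stage name.
#' @param before,after read tables (or objects with a `counts` matrix) before
#'   and after the stage.
#' @param extra named list of stage-specific diagnostics.
#' @return a `filter_stage` list.
#' @export
stage_report <- function(stage, before, after, extra = list()) {
  rin <- sum(before$counts); rout <- sum(after$counts)
  structure(c(list(stage = stage,
                   sequences_in = nrow(before$counts),
                   sequences_out = nrow(after$counts),
                   reads_in = rin, reads_out = rout,
                   reads_removed = rin - rout),
              extra),
            class = "filter_stage")
}

#' @export
print.filter_stage <- function(x, ...) {
  cat(sprintf("[%s] sequences %d -> %d, reads %s -> %s (removed %s)\n",
              x$stage, x$sequences_in, x$sequences_out,
              format(x$reads_in, big.mark = ","),
              format(x$reads_out, big.mark = ","),
              format(x$reads_removed, big.mark = ",")))
  invisible(x)
}

#' Write / read a read table as TSV
#'
#' Two UTF-8 tab-separated files are used: `<stem>_counts.tsv` (first column
#' `sequence`, one column per unit) and `<stem>_units.tsv` (unit metadata).
#'
#' @param table a [read_table()].
#' @param stem path stem without extension.
#' @return `write_read_table` returns `stem` invisibly; `read_read_table`
#'   returns a [read_table()].
#' @export
write_read_table <- function(table, stem) {
  cdf <- data.frame(sequence = rownames(table$counts), table$counts,
                    check.names = FALSE)
  utils::write.table(cdf, paste0(stem, "_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  u <- table$units
  u$library_id <- table$library_id
  utils::write.table(u, paste0(stem, "_units.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(stem)
}

#' @rdname write_read_table
#' @export
read_read_table <- function(stem) {
  cdf <- utils::read.delim(paste0(stem, "_counts.tsv"), check.names = FALSE)
  units <- utils::read.delim(paste0(stem, "_units.tsv"), check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$sequence
  lib <- if ("library_id" %in% names(units)) units$library_id[1] else "lib1"
  units$library_id <- NULL
  units$collection_date <- as.Date(units$collection_date)
  read_table(counts, units, library_id = lib)
}

#' Sample-level table after replicate aggregation
#'
#' @param values real-valued matrix, rows = sequences or taxon labels,
#'   columns = sample ids (replicate means, see [aggregate_replicates()]).
#' @param samples data.frame of per-sample metadata (`sample_id`,
#'   `individual_id`, `group_id`, `collection_date`).
#' @return an object of class `sample_table`.
#' @export
sample_table <- function(values, samples) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples)
  if (!identical(colnames(values), as.character(samples$sample_id)))
    stop("value columns must match samples$sample_id")
  structure(list(values = values, samples = samples), class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat(sprintf("<sample_table> %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
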