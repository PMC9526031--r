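hamming <- function(a, b) {
  # equal-length strings; vectorized over a
  mapply(function(x, y) sum(charToRaw(x) != charToRaw(y)), a, b,
         USE.NAMES = FALSE)
}

#' Assign tagged raw reads to PCR units
#'
#' Each read must start with an 8-nt forward tag and end with the reverse
#' complement of an 8-nt reverse tag; the tag pair identifies the unit
#' exactly (no tag mismatches), and the two flanking primers may each carry
#' up to `max_primer_mismatch` substitutions. Matching reads are stripped to
#' their insert and identical inserts per unit are collapsed with summed
#' counts; everything else is counted as unassigned.
#'
#' @param reads a [Biostrings::DNAStringSet] or character vector of reads.
#' @param tags a tag assignment table ([gen_tag_table()] layout).
#' @param max_primer_mismatch allowed substitutions per primer (default 2).
#' @param units optional unit metadata data.frame (as in [read_table()]);
#'   defaults to minimal sample metadata derived from `tags`.
#' @param library_id library identifier for the output table.
#' @return a [read_table()]; attribute `"demux_report"` holds the number of
#'   unassigned reads by reason.
#' @export
demultiplex <- function(reads, tags, max_primer_mismatch = 2, units = NULL,
                        library_id = "lib1") {
  if (anyDuplicated(paste(tags$forward_tag, tags$reverse_tag)))
    stop("duplicate tag pair in tag table")
  if (any(nchar(tags$forward_tag) != 8) || any(nchar(tags$reverse_tag) != 8))
    stop("tags must be exactly 8 nt")
  reads <- as.character(reads)
  key <- paste(tags$forward_tag, tags$reverse_tag)
  n <- nchar(reads)
  nf <- nchar(tags$forward_primer); nr <- nchar(tags$reverse_primer)
  min_len <- 16L + nf + nr   # per-unit; conservative length gate applied below

  ftag <- substr(reads, 1, 8)
  rtag_rc <- substr(reads, n - 7, n)
  rtag <- revcomp(rtag_rc)
  unit_row <- match(paste(ftag, rtag), key)
  too_short <- n < 17L        # cannot even hold both tags + 1 base
  unit_row[too_short] <- NA

  assigned <- !is.na(unit_row)
  n_tag_fail <- sum(!assigned)
  n_primer_fail <- 0L
  inserts <- character(length(reads)); unit_ids <- character(length(reads))
  idx <- which(assigned)
  if (length(idx)) {
    u <- unit_row[idx]
    long_enough <- n[idx] >= min_len[u]
    exp_f <- tags$forward_primer[u]
    exp_r <- revcomp(tags$reverse_primer[u])
    got_f <- substr(reads[idx], 9, 8 + nf[u])
    got_r <- substr(reads[idx], n[idx] - 8 - nr[u] + 1, n[idx] - 8)
    mm_f <- hamming(got_f, exp_f)
    mm_r <- hamming(got_r, exp_r)
    ok <- long_enough & mm_f <= max_primer_mismatch &
      mm_r <= max_primer_mismatch
    n_primer_fail <- sum(!ok)
    keep <- idx[ok]
    inserts[keep] <- substr(reads[keep], 9 + nf[unit_row[keep]],
                            n[keep] - 8 - nr[unit_row[keep]])
    unit_ids[keep] <- tags$unit_id[unit_row[keep]]
    assigned[idx[!ok]] <- FALSE
  }

  if (is.null(units)) {
    units <- data.frame(unit_id = tags$unit_id, sample_id = tags$unit_id,
                        individual_id = NA, group_id = NA,
                        collection_date = as.Date(NA),
                        replicate_index = 1L, unit_type = "sample",
                        stringsAsFactors = FALSE)
  }
  keep <- assigned & nchar(inserts) > 0
  tab <- table(factor(inserts[keep], levels = sort(unique(inserts[keep]))),
               factor(unit_ids[keep], levels = units$unit_id))
  counts <- matrix(as.numeric(tab), nrow = nrow(tab), ncol = ncol(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  out <- read_table(counts, units, library_id = library_id)
  attr(out, "demux_report") <- list(
    n_reads = length(reads), n_assigned = sum(keep),
    n_unassigned = length(reads) - sum(keep),
    tag_failures = n_tag_fail, primer_failures = n_primer_fail)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Barcode length filter
#'
#' Removes sequences whose length falls outside the marker's expected
#' barcode range (10-220 bp for the plant P6-loop assay, 76-168 bp for the
#' arthropod 16S assay).
#'
#' @param table a [read_table()].
#' @param min_bp,max_bp inclusive length bounds.
#' @return filtered [read_table()] with a `"report"` attribute.
#' @export
length_filter <- function(table, min_bp, max_bp) {
  stopifnot(min_bp <= max_bp)
  len <- nchar(sequences_of(table))
  out <- keep_sequences(table, len >= min_bp & len <= max_bp)
  attr(out, "report") <- stage_report("length_filter", table, out)
  out
}

#' Library-wide minimum count filter
#'
#' Discards sequences whose summed count over every unit of the library
#' (samples and controls alike) is below `min_library_reads`.
#'
#' @param table a [read_table()].
#' @param min_library_reads minimum library total (default 10; a total of 9
#'   is removed, 10 is kept).
#' @return filtered [read_table()] with a `"report"` attribute.
#' @export
min_count_filter <- function(table, min_library_reads = 10) {
  out <- keep_sequences(table, rowSums(table$counts) >= min_library_reads)
  attr(out, "report") <- stage_report("min_count_filter", table, out)
  out
}

# canonical row order: decreasing library abundance, ties lexicographic
canonical_order <- function(counts) {
  order(-rowSums(counts), rownames(counts))
}

#' Abundance-based denoising (merge likely PCR/sequencing variants)
#'
#' Visits sequences in decreasing library abundance (ties broken
#' lexicographically). A sequence within `max_mismatch` substitutions or
#' indels (Levenshtein) of an already-retained, more abundant sequence, and
#' whose library total is at most `child_ratio` times that parent's current
#' total, is merged into the parent (counts added per unit). Merging is
#' iterative: absorbed counts raise the parent's total for later candidates.
#'
#' @param table a [read_table()].
#' @param max_mismatch maximum edit distance to a parent (default 1).
#' @param child_ratio maximum child/parent library-total ratio (default
#'   0.05; `0` disables merging).
#' @return denoised [read_table()] with a `"report"` attribute.
#' @export
denoise_merge <- function(table, max_mismatch = 1, child_ratio = 0.05) {
  counts <- table$counts
  if (nrow(counts) > 1 && child_ratio > 0) {
    ord <- canonical_order(counts)
    counts <- counts[ord, , drop = FALSE]
    totals <- rowSums(counts)
    parents <- integer(0)
    absorbed <- logical(nrow(counts))
    for (i in seq_len(nrow(counts))) {
      merged <- FALSE
      if (length(parents)) {
        ptot <- rowSums(counts[parents, , drop = FALSE])
        cand <- parents[totals[i] <= child_ratio * ptot]
        if (length(cand)) {
          d <- as.vector(adist(rownames(counts)[i],
                               rownames(counts)[cand]))
          cand <- cand[d <= max_mismatch]
          if (length(cand)) {
            # most abundant eligible parent wins (first in canonical order
            # among current totals, ties lexicographic)
            ct <- rowSums(counts[cand, , drop = FALSE])
            best <- cand[order(-ct, rownames(counts)[cand])][1]
            counts[best, ] <- counts[best, ] + counts[i, ]
            absorbed[i] <- TRUE
            merged <- TRUE
          }
        }
      }
      if (!merged) parents <- c(parents, i)
    }
    counts <- counts[!absorbed, , drop = FALSE]
  }
  counts <- counts[canonical_order(counts), , drop = FALSE]
  out <- replace_counts(table, counts)
  attr(out, "report") <- stage_report("denoise_merge", table, out)
  out
}

#' Greedy abundance-sorted identity clustering
#'
#' Sequences are visited in decreasing library abundance (ties
#' lexicographic); each joins the first existing cluster whose
#' representative is at least `identity_threshold` identical under global
#' alignment (identity = matches / alignment length, match +1, mismatch -1,
#' gap -2), otherwise it founds a new cluster. Cluster counts are summed per
#' unit under the representative (the most abundant member).
#'
#' @param table a [read_table()].
#' @param identity_threshold identity threshold in (0, 1\] (default 0.97).
#' @return clustered [read_table()]; attributes `"report"` and
#'   `"cluster_members"` (named list representative -> members).
#' @export
cluster_greedy <- function(table, identity_threshold = 0.97) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  counts <- table$counts
  members <- list()
  if (nrow(counts) > 1) {
    ord <- canonical_order(counts)
    counts <- counts[ord, , drop = FALSE]
    reps <- integer(0)
    assign_to <- integer(nrow(counts))
    for (i in seq_len(nrow(counts))) {
      hit <- 0L
      if (length(reps)) {
        ids <- seq_identity(rownames(counts)[i], rownames(counts)[reps])
        w <- which(ids >= identity_threshold)
        if (length(w)) hit <- reps[w[1]]
      }
      if (hit) assign_to[i] <- hit
      else { reps <- c(reps, i); assign_to[i] <- i }
    }
    new <- rowsum(counts, group = assign_to, reorder = FALSE)
    rownames(new) <- rownames(counts)[as.integer(rownames(new))]
    members <- split(rownames(counts), rownames(counts)[assign_to])
    counts <- new
  } else {
    members <- as.list(setNames(rownames(counts), rownames(counts)))
  }
  counts <- counts[canonical_order(counts), , drop = FALSE]
  out <- replace_counts(table, counts)
  attr(out, "report") <- stage_report(
    "cluster_greedy", table, out,
    extra = list(n_clusters = nrow(counts)))
  attr(out, "cluster_members") <- members
  out
}

#' Remove sequences more abundant in negative controls than in samples
#'
#' A sequence is treated as a reagent/lab contaminant and removed entirely
#' when its maximum per-unit relative abundance (count divided by unit
#' depth) over extraction- and PCR-negative units strictly exceeds its
#' maximum over sample units.
#'
#' @param table a [read_table()].
#' @return list with elements `table` and `report`.
#' @export
remove_contaminants <- function(table) {
  neg <- unit_is(table, NEGATIVE_TYPES)
  smp <- unit_is(table, "sample")
  if (!any(neg)) {
    warning("no negative-control units; contaminant filter is a no-op")
    return(list(table = table,
                report = stage_report("remove_contaminants", table, table)))
  }
  depth <- colSums(table$counts)
  rel <- sweep(table$counts, 2, pmax(depth, 1), "/")
  rel[, depth == 0] <- 0
  max_neg <- apply(rel[, neg, drop = FALSE], 1, max)
  max_smp <- if (any(smp)) apply(rel[, smp, drop = FALSE], 1, max) else 0
  contaminant <- max_neg > max_smp
  out <- keep_sequences(table, !contaminant)
  rep <- stage_report("remove_contaminants", table, out,
                      extra = list(n_contaminant_sequences = sum(contaminant)))
  list(table = out, report = rep)
}

#' Blank-based tag-jump filter
#'
#' Tag switching leaks reads of a sequence into foreign wells in proportion
#' to that sequence's abundance in the library. Deliberately empty wells
#' (blanks) measure the leak: for every sequence `s` with library total
#' `T_s` and blank count `b`, the positive leak fractions `b / T_s` are
#' pooled over sequences and blanks, and the library ratio `r` is the given
#' quantile (default the maximum) of that pool. Every cell with fewer than
#' `r * T_s` reads is then set to zero. A Wilcoxon signed-rank diagnostic
#' (blank totals of the more abundant half of sequences paired by rank with
#' the less abundant half) is reported, not used as a gate.
#'
#' @param table a [read_table()].
#' @param quantile quantile of positive leak fractions used as the library
#'   ratio (default 1 = maximum).
#' @return list with elements `table` and `report` (incl. `ratio` and the
#'   Wilcoxon diagnostic).
#' @export
tagjump_filter <- function(table, quantile = 1.0) {
  blank <- unit_is(table, "blank")
  totals <- rowSums(table$counts)
  wilcox <- list(statistic = NA_real_, p_value = NA_real_)
  r <- 0
  if (any(blank) && nrow(table$counts)) {
    b <- table$counts[, blank, drop = FALSE]
    f <- sweep(b, 1, pmax(totals, 1), "/")[totals > 0, , drop = FALSE]
    pos <- f[f > 0]
    if (length(pos)) r <- stats::quantile(pos, quantile, names = FALSE)
    bt <- rowSums(b)
    if (length(bt) >= 4) {
      ord <- order(-totals, rownames(table$counts))
      half <- length(ord) %/% 2
      hi <- bt[ord[seq_len(half)]]
      lo <- bt[ord[length(ord) - half + seq_len(half)]]
      if (any(hi != lo)) {
        wt <- suppressWarnings(wilcox.test(hi, lo, paired = TRUE,
                                           exact = FALSE))
        wilcox <- list(statistic = unname(wt$statistic),
                       p_value = wt$p.value)
      }
    }
  }
  counts <- table$counts
  if (r > 0) {
    thresh <- r * totals
    zero <- counts < thresh & counts > 0
    counts[zero] <- 0
  }
  out <- replace_counts(table, counts, drop_empty = TRUE)
  rep <- stage_report("tagjump_filter", table, out,
                      extra = list(ratio = r, wilcoxon = wilcox))
  list(table = out, report = rep)
}

#' Remove host sequences
#'
#' Drops every sequence whose taxonomic assignment matches a host taxon
#' (matched against any level of the assigned path, the display label, or
#' the member species of a multi-species label).
#'
#' @param table a [read_table()].
#' @param assignments assignment table from [assign_taxonomy()].
#' @param host_taxa character vector of host taxon names.
#' @return list with elements `table` and `report`.
#' @export
remove_host <- function(table, assignments, host_taxa) {
  if (!length(host_taxa)) {
    return(list(table = table,
                report = stage_report("remove_host", table, table)))
  }
  is_host_assignment <- vapply(seq_len(nrow(assignments)), function(i) {
    parts <- c(strsplit(assignments$assigned_path[i], ";")[[1]],
               assignments$assigned_taxon[i],
               strsplit(assignments$species_labels[i] %||% "", "/")[[1]])
    any(parts %in% host_taxa)
  }, logical(1))
  host_seqs <- assignments$sequence[is_host_assignment]
  out <- keep_sequences(table, !(sequences_of(table) %in% host_seqs))
  rep <- stage_report("remove_host", table, out,
                      extra = list(n_host_sequences = length(
                        intersect(host_seqs, sequences_of(table)))))
  list(table = out, report = rep)
}

#' Replicate-consensus aggregation to sample level
#'
#' Collapses PCR replicates: for each sample and sequence, the mean count
#' over all R replicates (zeros included) is retained when the sequence is
#' non-zero in at least `min_replicates` replicates AND that mean is at
#' least `min_mean_reads`; otherwise the sample gets zero. Control units are
#' dropped. Samples with fewer than `min_replicates` replicate units present
#' are excluded with a warning.
#'
#' @param table a [read_table()].
#' @param min_replicates presence requirement (default 2 of 3).
#' @param min_mean_reads floor on the retained replicate mean (default 5).
#' @return a [sample_table()] with attributes `"report"` and
#'   `"excluded_samples"`.
#' @export
aggregate_replicates <- function(table, min_replicates = 2,
                                 min_mean_reads = 5) {
  smp <- table$units[table$units$unit_type == "sample", , drop = FALSE]
  ids <- unique(smp$sample_id)
  nrep <- base::table(smp$sample_id)
  excluded <- names(nrep)[nrep < min_replicates]
  if (length(excluded))
    warning("samples with fewer than ", min_replicates,
            " replicates excluded: ", paste(excluded, collapse = ", "))
  ids <- setdiff(ids, excluded)
  vals <- matrix(0, nrow(table$counts), length(ids),
                 dimnames = list(rownames(table$counts), ids))
  for (sid in ids) {
    uu <- smp$unit_id[smp$sample_id == sid]
    sub <- table$counts[, uu, drop = FALSE]
    present <- rowSums(sub > 0)
    mu <- rowMeans(sub)
    keep <- present >= min_replicates & mu >= min_mean_reads
    vals[keep, sid] <- mu[keep]
  }
  meta <- smp[!duplicated(smp$sample_id), c("sample_id", "individual_id",
                                            "group_id", "collection_date")]
  meta <- meta[match(ids, meta$sample_id), ]
  out <- sample_table(vals, meta)
  attr(out, "report") <- stage_report(
    "aggregate_replicates", table, list(counts = vals),
    extra = list(n_samples = length(ids), excluded_samples = excluded))
  attr(out, "excluded_samples") <- excluded
  out
}

#' Merge sample-table rows by assigned taxon label
#'
#' @param stab a [sample_table()] whose rows are sequences.
#' @param assignments assignment table from [assign_taxonomy()] (after any
#'   range rules and rank capping).
#' @param drop_unassigned drop sequences without a database match.
#' @return a [sample_table()] with one row per distinct taxon label.
#' @export
merge_by_taxon <- function(stab, assignments, drop_unassigned = TRUE) {
  lab <- assignments$assigned_taxon[match(rownames(stab$values),
                                          assignments$sequence)]
  keep <- !is.na(lab) & (!drop_unassigned |
    assignments$matched_db[match(rownames(stab$values),
                                 assignments$sequence)] != "none")
  v <- rowsum(stab$values[keep, , drop = FALSE], lab[keep])
  sample_table(v[order(rownames(v)), , drop = FALSE], stab$samples)
}

#' Run the full curation cascade
#'
#' Applies, in fixed order: length filter, library minimum-count filter,
#' denoising, greedy 97% clustering, taxonomic assignment (local database
#' first, then global) with geographic range rules and optional rank cap,
#' host removal, contaminant removal, blank-based tag-jump filtering, and
#' replicate-consensus aggregation, finally merging sequences with identical
#' taxon labels. Stages can be skipped by name via `skip`.
#'
#' @param table a [read_table()] (already demultiplexed).
#' @param global_db,local_db reference databases ([reference_db()]); local
#'   may be `NULL`.
#' @param length_range barcode length bounds.
#' @param min_library_reads minimum library total per sequence.
#' @param denoise_max_mismatch,denoise_child_ratio see [denoise_merge()].
#' @param cluster_identity see [cluster_greedy()].
#' @param assign_threshold see [assign_taxonomy()].
#' @param range_table optional geographic validity table
#'   (see [apply_range_rules()]).
#' @param rank_cap optional rank (e.g. `"family"`) passed to [cap_rank()].
#' @param host_taxa host taxon names for [remove_host()].
#' @param tagjump_quantile see [tagjump_filter()].
#' @param min_replicates,min_mean_reads see [aggregate_replicates()].
#' @param skip character vector of stage names to skip (among
#'   `length`, `min_count`, `denoise`, `cluster`, `range_rules`, `cap_rank`,
#'   `host`, `contaminant`, `tagjump`).
#' @param verbose print per-stage read accounting.
#' @return list with `samples` (taxon-level [sample_table()]),
#'   `sequence_samples` (sequence-level [sample_table()]), `assignments`,
#'   and `report` (list of `filter_stage` entries).
#' @export
curate <- function(table, global_db, local_db = NULL,
                   length_range = c(10, 220), min_library_reads = 10,
                   denoise_max_mismatch = 1, denoise_child_ratio = 0.05,
                   cluster_identity = 0.97, assign_threshold = 0.97,
                   range_table = NULL, rank_cap = NULL,
                   host_taxa = character(0), tagjump_quantile = 1,
                   min_replicates = 2, min_mean_reads = 5,
                   skip = character(0), verbose = FALSE) {
  report <- list()
  note <- function(x) {
    r <- attr(x, "report")
    if (!is.null(r)) {
      report[[r$stage]] <<- r
      if (verbose) print(r)
    }
    x
  }
  if (!"length" %in% skip)
    table <- note(length_filter(table, length_range[1], length_range[2]))
  if (!"min_count" %in% skip)
    table <- note(min_count_filter(table, min_library_reads))
  if (!"denoise" %in% skip)
    table <- note(denoise_merge(table, denoise_max_mismatch,
                                denoise_child_ratio))
  if (!"cluster" %in% skip)
    table <- note(cluster_greedy(table, cluster_identity))

  asg <- assign_taxonomy(table, local_db = local_db, global_db = global_db,
                         threshold = assign_threshold)
  if (!is.null(range_table) && !"range_rules" %in% skip)
    asg <- apply_range_rules(asg, range_table)
  if (!is.null(rank_cap) && !"cap_rank" %in% skip)
    asg <- cap_rank(asg, rank_cap)

  if (!"host" %in% skip && length(host_taxa)) {
    h <- remove_host(table, asg, host_taxa)
    table <- h$table; report$remove_host <- h$report
    if (verbose) print(h$report)
  }
  if (!"contaminant" %in% skip) {
    cc <- remove_contaminants(table)
    table <- cc$table; report$remove_contaminants <- cc$report
    if (verbose) print(cc$report)
  }
  if (!"tagjump" %in% skip) {
    tj <- tagjump_filter(table, tagjump_quantile)
    table <- tj$table; report$tagjump_filter <- tj$report
    if (verbose) print(tj$report)
  }
  stab <- aggregate_replicates(table, min_replicates, min_mean_reads)
  report$aggregate_replicates <- attr(stab, "report")
  if (verbose) print(attr(stab, "report"))
  taxa <- merge_by_taxon(stab, asg)
  list(samples = taxa, sequence_samples = stab, assignments = asg,
       report = report)
}

#' Write a curation filter report as JSON
#'
#' @param report list of `filter_stage` entries (from [curate()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write reports")
  jsonlite::write_json(lapply(report, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}
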