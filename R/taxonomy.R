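RANKS <- c("kingdom", "order", "family", "genus", "species")

#' Global-alignment sequence identity
#'
#' Identity between a query and one or more subject sequences, defined as
#' matches divided by global alignment length (Needleman-Wunsch with match
#' +1, mismatch -1, gap -2).
#'
#' @param query single DNA string.
#' @param subjects character vector of DNA strings.
#' @return numeric identity fractions in \[0, 1\].
#' @export
seq_identity <- function(query, subjects) {
  if (!length(subjects)) return(numeric(0))
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(subjects),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 0, gapExtension = 2)
  Biostrings::nmatch(aln) / Biostrings::nchar(aln)
}

split_path <- function(p) strsplit(p, ";", fixed = TRUE)[[1]]

# Deepest shared prefix of several taxon paths.
common_prefix <- function(paths) {
  parts <- lapply(paths, split_path)
  d <- min(lengths(parts))
  keep <- 0L
  for (k in seq_len(d)) {
    lv <- vapply(parts, `[`, character(1), k)
    if (length(unique(lv)) == 1L) keep <- k else break
  }
  if (keep == 0L) character(0) else parts[[1]][seq_len(keep)]
}

# Build one assignment row from a set of candidate reference rows (all at
# the best identity). Multiple species on one sequence, or ties between
# reference sequences, resolve to the joined label at the lowest common rank.
combine_candidates <- function(sequence, db_rows, matched_db, identity) {
  prefix <- common_prefix(db_rows$taxon_path)
  species <- sort(unique(db_rows$species))
  if (length(prefix) == length(RANKS)) {
    label <- prefix[length(RANKS)]
    rank <- "species"
  } else if (length(prefix) == 0L) {
    return(unassigned_row(sequence))
  } else {
    rank <- RANKS[length(prefix)]
    label <- if (length(species) > 1) paste(species, collapse = "/")
             else prefix[length(prefix)]
  }
  data.frame(sequence = sequence, matched_db = matched_db,
             identity = identity, assigned_taxon = label,
             assigned_path = paste(prefix, collapse = ";"),
             assigned_rank = rank,
             species_labels = paste(species, collapse = "/"),
             demoted = FALSE, demote_reason = NA_character_,
             stringsAsFactors = FALSE)
}

unassigned_row <- function(sequence) {
  data.frame(sequence = sequence, matched_db = "none", identity = NA_real_,
             assigned_taxon = NA_character_, assigned_path = NA_character_,
             assigned_rank = NA_character_, species_labels = NA_character_,
             demoted = FALSE, demote_reason = NA_character_,
             stringsAsFactors = FALSE)
}

best_hit <- function(query, db, threshold) {
  seqs <- unique(db$sequence)
  if (!length(seqs)) return(NULL)
  ids <- seq_identity(query, seqs)
  best <- max(ids)
  if (best < threshold) return(NULL)
  hit_seqs <- seqs[ids >= best - 1e-12]
  list(rows = db[db$sequence %in% hit_seqs, , drop = FALSE], identity = best)
}

#' Cascading taxonomic assignment against local and global databases
#'
#' Each sequence is compared to the local reference database first (when
#' given); the best match at or above the identity threshold wins. Sequences
#' without a local hit are run against the global database at the same
#' threshold; everything else is unassigned. A reference sequence shared by
#' several species yields a joined multi-species label (e.g.
#' `"Species_A/Species_B"`) at the species' lowest common rank; ties between
#' distinct reference sequences at equal identity are likewise resolved to
#' their lowest common rank.
#'
#' @param table a [read_table()] (or character vector of sequences).
#' @param global_db a [reference_db()].
#' @param local_db an optional [reference_db()] searched first.
#' @param threshold identity threshold (default 0.97).
#' @return data.frame with one row per sequence: `sequence`, `matched_db`
#'   (`local`/`global`/`none`), `identity`, `assigned_taxon`,
#'   `assigned_path`, `assigned_rank`, `species_labels`, `demoted`,
#'   `demote_reason`.
#' @export
assign_taxonomy <- function(table, global_db, local_db = NULL,
                            threshold = 0.97) {
  queries <- if (inherits(table, "read_table")) sequences_of(table)
             else as.character(table)
  dbs <- list()
  if (!is.null(local_db)) dbs$local <- local_db
  dbs$global <- global_db
  dbs <- Filter(function(d) !is.null(d), dbs)
  empty <- vapply(dbs, function(d) nrow(d) == 0, logical(1))
  if (all(empty)) {
    warning("all reference databases are empty; every sequence unassigned")
    return(do.call(rbind, lapply(queries, unassigned_row)))
  }
  dbs <- dbs[!empty]
  rows <- lapply(queries, function(q) {
    for (nm in names(dbs)) {
      hit <- best_hit(q, dbs[[nm]], threshold)
      if (!is.null(hit))
        return(combine_candidates(q, hit$rows, nm, hit$identity))
    }
    unassigned_row(q)
  })
  do.call(rbind, rows)
}

rank_depth <- function(rank) match(rank, RANKS)

#' Demote species-level assignments outside their known geographic range
#'
#' Species-level assignments whose species is not flagged as occurring in
#' the study region are re-assigned to genus when the genus is flagged
#' valid, else to family. Multi-species labels are left untouched if any
#' member species is valid, and demoted the same way otherwise. Species
#' missing from the range table are treated as invalid, with a warning.
#'
#' @param assignments output of [assign_taxonomy()].
#' @param range_table data.frame with columns `name`, `rank`
#'   (`species`/`genus`), `valid` (logical).
#' @return assignments with demotions applied (`demoted`, `demote_reason`).
#' @export
apply_range_rules <- function(assignments, range_table) {
  valid_of <- function(name, rank) {
    i <- which(range_table$name == name & range_table$rank == rank)
    if (!length(i)) return(NA)
    isTRUE(range_table$valid[i[1]])
  }
  for (i in seq_len(nrow(assignments))) {
    sp <- assignments$species_labels[i]
    if (is.na(sp) || !nzchar(sp)) next
    species <- strsplit(sp, "/", fixed = TRUE)[[1]]
    if (is.na(rank_depth(assignments$assigned_rank[i])) ||
        rank_depth(assignments$assigned_rank[i]) < rank_depth("genus"))
      next  # already at family or above; range rules moot
    v <- vapply(species, valid_of, NA, rank = "species")
    if (any(is.na(v)))
      warning("species missing from range table treated as invalid: ",
              paste(species[is.na(v)], collapse = ", "))
    v[is.na(v)] <- FALSE
    if (any(v)) next
    path <- split_path(assignments$assigned_path[i])
    genus <- if (length(path) >= 4) path[4] else NA
    gv <- if (!is.na(genus)) isTRUE(valid_of(genus, "genus")) else FALSE
    if (gv) {
      new_path <- path[seq_len(4)]
      assignments$assigned_rank[i] <- "genus"
    } else {
      new_path <- path[seq_len(min(3, length(path)))]
      assignments$assigned_rank[i] <- "family"
    }
    assignments$assigned_path[i] <- paste(new_path, collapse = ";")
    assignments$assigned_taxon[i] <- new_path[length(new_path)]
    assignments$species_labels[i] <- NA_character_
    assignments$demoted[i] <- TRUE
    assignments$demote_reason[i] <- "range mismatch"
  }
  assignments
}

#' Truncate assignments to a maximum taxonomic rank
#'
#' Used for markers where finer ranks are unreliable (the arthropod assay is
#' kept at family level). Assignments already at or above the cap are
#' unchanged.
#'
#' @param assignments output of [assign_taxonomy()].
#' @param cap rank name (one of kingdom, order, family, genus, species).
#' @return capped assignments (`demote_reason = "family-cap"` style flag).
#' @export
cap_rank <- function(assignments, cap) {
  d <- rank_depth(cap)
  if (is.na(d)) stop("unknown rank: ", cap)
  for (i in seq_len(nrow(assignments))) {
    rd <- rank_depth(assignments$assigned_rank[i])
    if (is.na(rd) || rd <= d) next
    path <- split_path(assignments$assigned_path[i])
    new_path <- path[seq_len(min(d, length(path)))]
    assignments$assigned_path[i] <- paste(new_path, collapse = ";")
    assignments$assigned_taxon[i] <- new_path[length(new_path)]
    assignments$assigned_rank[i] <- RANKS[length(new_path)]
    assignments$species_labels[i] <- NA_character_
    assignments$demoted[i] <- TRUE
    assignments$demote_reason[i] <- paste0(cap, "-cap")
  }
  assignments
}

#' Reference database FASTA + taxonomy TSV I/O
#'
#' `write_reference_db` writes `<stem>.fasta` (one record per unique
#' sequence, named by `seq_id`) and `<stem>_taxonomy.tsv` (one row per
#' sequence-label pair). `read_reference_db` reads them back.
#'
#' @param db a [reference_db()].
#' @param stem path stem.
#' @param scope database scope on read.
#' @return `stem` (write) or a [reference_db()] (read).
#' @export
write_reference_db <- function(db, stem) {
  uniq <- db[!duplicated(db$seq_id), ]
  ss <- Biostrings::DNAStringSet(uniq$sequence)
  names(ss) <- uniq$seq_id
  Biostrings::writeXStringSet(ss, paste0(stem, ".fasta"))
  utils::write.table(as.data.frame(db), paste0(stem, "_taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(stem)
}

#' @rdname write_reference_db
#' @export
read_reference_db <- function(stem, scope = "local") {
  tx <- utils::read.delim(paste0(stem, "_taxonomy.tsv"))
  fa <- Biostrings::readDNAStringSet(paste0(stem, ".fasta"))
  seqs <- as.character(fa)
  tx$sequence <- unname(seqs[match(tx$seq_id, names(fa))])
  reference_db(tx, scope = scope)
}
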