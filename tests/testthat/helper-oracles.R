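# Independent brute-force oracles and tiny fixture builders.
# These deliberately avoid the package's own code paths.

# Needleman-Wunsch identity (match +1, mismatch -1, gap -2), matches over
# alignment length, via explicit DP + traceback.
nw_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- gap * (0:n); S[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    S[i + 1, j + 1] <- max(
      S[i, j] + if (A[i] == B[j]) match else mismatch,
      S[i, j + 1] + gap, S[i + 1, j] + gap)
  }
  i <- n; j <- m; matches <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] ==
          S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  matches / len
}

brute_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  d
}

brute_mantel_r <- function(d1, d2) {
  cor(as.vector(d1[upper.tri(d1)]), as.vector(d2[upper.tri(d2)]))
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, sub + (sub >= k))))
}

# ANOSIM R straight from the definition (Clarke): mean rank difference over
# n(n-1)/4.
brute_anosim_R <- function(d, groups) {
  ut <- upper.tri(d)
  rk <- rank(d[ut])
  same <- outer(groups, groups, "==")[ut]
  (mean(rk[!same]) - mean(rk[same])) / (length(rk) / 2)
}

brute_indval <- function(m, groups) {
  gs <- sort(unique(as.character(groups)))
  iv <- matrix(0, length(gs), ncol(m), dimnames = list(gs, colnames(m)))
  for (k in seq_len(ncol(m))) {
    mu <- vapply(gs, function(g) mean(m[groups == g, k]), numeric(1))
    for (g in seq_along(gs)) {
      A <- if (sum(mu) > 0) mu[g] / sum(mu) else 0
      B <- mean(m[groups == gs[g], k] > 0)
      iv[g, k] <- A * B * 100
    }
  }
  iv
}

# Greedy abundance-sorted clustering, re-derived with the NW oracle.
brute_greedy_cluster <- function(seqs, totals, threshold) {
  ord <- order(-totals, seqs)
  reps <- character(0)
  assign_to <- character(length(seqs))
  names(assign_to) <- seqs
  for (s in seqs[ord]) {
    hit <- NA_character_
    for (r in reps) {
      if (nw_identity(s, r) >= threshold) { hit <- r; break }
    }
    if (is.na(hit)) { reps <- c(reps, s); assign_to[s] <- s }
    else assign_to[s] <- hit
  }
  assign_to
}

# Minimal read_table fixture: counts matrix with named rows (sequences built
# from an alphabet of well-separated barcodes unless given) and unit types.
toy_units <- function(ids, types = rep("sample", length(ids)),
                      sample_ids = NULL, replicate_index = NULL,
                      individual = "ind_001", date = as.Date("2018-09-10")) {
  data.frame(
    unit_id = ids,
    sample_id = ifelse(types == "sample",
                       if (is.null(sample_ids)) ids else sample_ids, NA),
    individual_id = ifelse(types == "sample", individual, NA),
    group_id = ifelse(types == "sample", "Kubu", NA),
    collection_date = as.Date(ifelse(types == "sample", as.character(date),
                                     NA)),
    replicate_index = if (is.null(replicate_index))
      ifelse(types == "sample", 1L, NA_integer_) else replicate_index,
    unit_type = types, stringsAsFactors = FALSE)
}

toy_table <- function(counts, types = rep("sample", ncol(counts)), ...) {
  ids <- colnames(counts)
  if (is.null(ids)) {
    ids <- paste0("u", seq_len(ncol(counts)))
    colnames(counts) <- ids
  }
  read_table(counts, toy_units(ids, types, ...), library_id = "toy")
}

# Distinct barcodes (pairwise far apart) for toy tables.
toy_seqs <- function(n, len = 60, seed = 99) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Reference database matching a ground truth's taxa exactly.
truth_db <- function(truth, scope = "global") {
  tx <- truth$taxa
  reference_db(data.frame(
    seq_id = sprintf("t%03d", seq_len(nrow(tx))), sequence = tx$sequence,
    taxon_path = paste("Viridiplantae", "OrderX", tx$family, tx$genus,
                       tx$taxon, sep = ";"),
    rank = "species", species = tx$taxon, geographic_valid = TRUE,
    stringsAsFactors = FALSE), scope = scope)
}

fast_cfg <- function(...) {
  defaults <- list(n_taxa = 8, n_seasons = 4, n_individuals = 3,
                   samples_per_individual_season = 1,
                   depth_lognormal_params = c(6, 0.4),
                   tagjump_rate = 0, contaminant_rate = 0,
                   n_blanks = 2, n_extraction_neg = 1, n_pcr_neg = 1,
                   n_positive = 1)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
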