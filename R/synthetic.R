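#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe a
#' plausible year of a four-group vervet monkey study: four seasons, a few
#' dozen dietary plant taxa, triplicate PCRs per fecal sample with log-normal
#' per-replicate depth around ~3000 reads (a MiniSeq run split over ~2500
#' wells), sparse uneven diets (Dirichlet concentration 0.5), a 0.1% tag-jump
#' leak, a couple of contaminant reads per control well, and imperfect focal
#' observers (70% per-event detection).
#'
#' @param n_taxa number of dietary taxa.
#' @param n_seasons number of seasons (default 4).
#' @param n_individuals number of sampled individuals.
#' @param samples_per_individual_season fecal samples per individual and season.
#' @param replicates_per_sample PCR replicates per sample (>= 2, default 3).
#' @param depth_lognormal_params `c(mu, sigma)` of log read depth per replicate.
#' @param dirichlet_concentration positive Dirichlet concentration, recycled
#'   to `n_taxa`, used for every season's baseline composition.
#' @param tagjump_rate fraction in \[0,1) of each sequence's library total
#'   leaked into other units.
#' @param contaminant_rate expected contaminant reads per control unit
#'   (samples receive `sample_contamination_factor` times this).
#' @param host_read_fraction fraction in \[0,1) of each sample unit's reads
#'   that are host (vervet/human) sequence.
#' @param detection_prob per-taxon probability that an eaten item is recorded
#'   by a focal observer; recycled to `n_taxa`.
#' @param rng_seed integer seed; all generators derive their streams from it.
#' @param indicator_share truth mass given to a season's indicator taxon
#'   within its own season.
#' @param within_season_concentration Dirichlet precision of per-sample
#'   compositions around their season composition (larger = less variable).
#' @param n_blanks,n_extraction_neg,n_pcr_neg,n_positive control wells per
#'   library.
#' @param sample_contamination_factor multiplier on `contaminant_rate` for
#'   sample wells.
#' @param seq_len_range barcode insert length range in bp.
#' @param focal_days_per_season observation days simulated per season.
#' @param follows_per_day focal follows per observation day (10 screenings
#'   each).
#' @param feeding_rate probability a focal screening records a feeding event.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 30, n_seasons = 4, n_individuals = 40,
                       samples_per_individual_season = 2,
                       replicates_per_sample = 3,
                       depth_lognormal_params = c(mu = 8, sigma = 0.6),
                       dirichlet_concentration = 0.5,
                       tagjump_rate = 0.001,
                       contaminant_rate = 2,
                       host_read_fraction = 0,
                       detection_prob = 0.7,
                       rng_seed = 1L,
                       indicator_share = 0.08,
                       within_season_concentration = 100,
                       n_blanks = 4, n_extraction_neg = 2, n_pcr_neg = 2,
                       n_positive = 2,
                       sample_contamination_factor = 0.1,
                       seq_len_range = c(60, 140),
                       focal_days_per_season = 25,
                       follows_per_day = 5,
                       feeding_rate = 0.4) {
  cfg <- list(n_taxa = n_taxa, n_seasons = n_seasons,
              n_individuals = n_individuals,
              samples_per_individual_season = samples_per_individual_season,
              replicates_per_sample = replicates_per_sample,
              depth_lognormal_params = unname(depth_lognormal_params),
              dirichlet_concentration = rep_len(dirichlet_concentration, n_taxa),
              tagjump_rate = tagjump_rate,
              contaminant_rate = contaminant_rate,
              host_read_fraction = host_read_fraction,
              detection_prob = rep_len(detection_prob, n_taxa),
              rng_seed = as.integer(rng_seed),
              indicator_share = indicator_share,
              within_season_concentration = within_season_concentration,
              n_blanks = n_blanks, n_extraction_neg = n_extraction_neg,
              n_pcr_neg = n_pcr_neg, n_positive = n_positive,
              sample_contamination_factor = sample_contamination_factor,
              seq_len_range = seq_len_range,
              focal_days_per_season = focal_days_per_season,
              follows_per_day = follows_per_day,
              feeding_rate = feeding_rate)
  stopifnot(cfg$n_taxa >= 1, cfg$n_seasons >= 1,
            cfg$replicates_per_sample >= 2,
            all(cfg$dirichlet_concentration > 0),
            cfg$tagjump_rate >= 0, cfg$tagjump_rate < 1,
            cfg$contaminant_rate >= 0,
            cfg$host_read_fraction >= 0, cfg$host_read_fraction < 1,
            all(cfg$detection_prob >= 0 & cfg$detection_prob <= 1))
  class(cfg) <- "sim_config"
  cfg
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, which.max(alpha)] <- 1  # numeric underflow guard
  g / rowSums(g)
}

random_dna <- function(n, len_range) {
  lens <- if (len_range[1] == len_range[2]) rep(len_range[1], n) else
    sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
}

# Draw n sequences pairwise below `max_identity` (so neither denoising nor
# 97% clustering can merge them), with bounded retries per sequence.
draw_distinct_sequences <- function(n, len_range, max_identity = 0.97,
                                    avoid = character(0), max_tries = 50) {
  if (n == 0) return(character(0))
  out <- character(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- random_dna(1, len_range)
      others <- c(avoid, out)
      if (!length(others) ||
          all(seq_identity(cand, others) < max_identity)) {
        out <- c(out, cand); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not draw pairwise-dissimilar sequences at the ",
                  "requested lengths after ", max_tries, " tries")
  }
  out
}

season_name_default <- function(n) {
  if (n == 4) c("spring", "summer", "autumn", "winter")
  else paste0("season_", seq_len(n))
}

#' Generate a barcode reference database with shared sequences
#'
#' Emulates a local barcode collection in which some sequences are shared by
#' several species (the P6 loop does not always separate congeners): a given
#' number of single-species sequences plus sequences carrying two or three
#' species labels. All sequences are pairwise below 97% identity so that
#' clustering cannot merge them.
#'
#' @param n_unique,n_shared2,n_shared3 numbers of sequences carrying one, two
#'   and three species labels.
#' @param seq_len_range length range in bp.
#' @param seed integer seed.
#' @param scope `"local"` or `"global"`.
#' @param prefix species name prefix.
#' @return a [reference_db()].
#' @export
gen_reference_db <- function(n_unique, n_shared2, n_shared3,
                             seq_len_range = c(60, 140), seed = 1L,
                             scope = "local", prefix = "Species") {
  stopifnot(n_unique >= 0, n_shared2 >= 0, n_shared3 >= 0)
  set.seed(seed)
  n_seq <- n_unique + n_shared2 + n_shared3
  seqs <- draw_distinct_sequences(n_seq, seq_len_range)
  labels_per_seq <- rep(c(1L, 2L, 3L), c(n_unique, n_shared2, n_shared3))
  n_species <- sum(labels_per_seq)
  sp_idx <- 0L
  rows <- vector("list", n_seq)
  for (i in seq_len(n_seq)) {
    k <- labels_per_seq[i]
    sp <- sprintf("%s_%03d", prefix, sp_idx + seq_len(k))
    sp_idx <- sp_idx + k
    genus <- sprintf("Genus_%03d", i)  # shared sequences: congeners
    family <- sprintf("Family_%03d", (i - 1L) %/% 5L + 1L)
    rows[[i]] <- data.frame(
      seq_id = sprintf("ref_%03d", i), sequence = seqs[i],
      taxon_path = paste("Viridiplantae", "OrderIncertae", family, genus, sp,
                         sep = ";"),
      rank = "species", species = sp, geographic_valid = TRUE,
      stringsAsFactors = FALSE)
  }
  reference_db(do.call(rbind, rows), scope = scope)
}

#' Reference database constructor
#'
#' One row per (sequence, taxon label) pair. A sequence shared by several
#' species appears in several rows with the same `seq_id`.
#'
#' @param records data.frame with columns `seq_id`, `sequence`, `taxon_path`
#'   (semicolon-separated kingdom;order;family;genus;species, truncated at
#'   the record's rank), `rank`, `species`, `geographic_valid`.
#' @param scope `"local"` or `"global"`.
#' @return object of class `reference_db` (a data.frame).
#' @export
reference_db <- function(records, scope = "local") {
  records <- as.data.frame(records)
  req <- c("seq_id", "sequence", "taxon_path", "rank", "species",
           "geographic_valid")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("reference_db missing: ", paste(miss, collapse = ", "))
  sp <- split(records$seq_id, records$sequence)
  if (any(vapply(sp, function(x) length(unique(x)), 1L) > 1))
    stop("a sequence maps to multiple seq_ids")
  structure(records, class = c("reference_db", "data.frame"), scope = scope)
}

#' Seasonal ground-truth diet compositions
#'
#' Draws one baseline composition per season from the configured Dirichlet,
#' plants one indicator taxon per season (taxon `i` has mass only in season
#' `i`, at share `indicator_share`), and resamples a composition for every
#' fecal sample around its season baseline with precision
#' `within_season_concentration`, so within-season variance is smaller than
#' between-season variance.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `ground_truth` with elements `taxa` (taxon
#'   metadata incl. barcode sequence, indicator season, detection
#'   probability, observer recording level), `season_names`,
#'   `season_composition` (season x taxon), `samples` (per-sample metadata),
#'   `per_sample_composition` (sample x taxon), and the `cfg`.
#' @export
gen_seasonal_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$rng_seed)
  n_tax <- cfg$n_taxa; n_sea <- cfg$n_seasons
  seasons <- season_name_default(n_sea)
  taxa <- sprintf("Taxon_%03d", seq_len(n_tax))
  seqs <- draw_distinct_sequences(n_tax, cfg$seq_len_range)
  indicator <- rep(NA_character_, n_tax)
  n_ind_taxa <- if (cfg$indicator_share > 0) min(n_sea, n_tax) else 0L
  indicator[seq_len(n_ind_taxa)] <- seasons[seq_len(n_ind_taxa)]

  comp <- matrix(0, n_sea, n_tax, dimnames = list(seasons, taxa))
  for (s in seq_len(n_sea)) {
    g <- rgamma(n_tax, shape = cfg$dirichlet_concentration)
    g[!is.na(indicator)] <- 0            # indicators live only in their season
    base <- if (sum(g) > 0) g / sum(g) else rep(1 / n_tax, n_tax)
    row <- base * (1 - cfg$indicator_share * (s <= n_ind_taxa))
    if (s <= n_ind_taxa) row[s] <- cfg$indicator_share
    comp[s, ] <- row / sum(row)
  }

  months_by_season <- list(spring = c(9, 10), summer = c(12, 1, 2),
                           autumn = 4, winter = c(6, 7))
  lvl <- sample(c("species", "genus", "broad"), n_tax, replace = TRUE,
                prob = c(0.7, 0.2, 0.1))
  genus <- sprintf("Genus_%03d", seq_len(n_tax))
  family <- sprintf("Family_%03d", (seq_len(n_tax) - 1L) %/% 5L + 1L)

  ids <- sprintf("ind_%03d", seq_len(cfg$n_individuals))
  groups <- c("Ankhase", "BaieDankie", "Kubu", "Noha")
  grp <- groups[(seq_len(cfg$n_individuals) - 1L) %% length(groups) + 1L]
  rows <- list(); comp_rows <- list(); r <- 0L
  for (s in seq_len(n_sea)) {
    mo <- if (n_sea == 4) months_by_season[[seasons[s]]] else
      ((s - 1L) %% 12L) + 1L
    for (i in seq_len(cfg$n_individuals)) {
      for (k in seq_len(cfg$samples_per_individual_season)) {
        r <- r + 1L
        m <- mo[sample.int(length(mo), 1)]
        d <- sample.int(28, 1)
        rows[[r]] <- data.frame(
          sample_id = sprintf("%s_%s_%d", seasons[s], ids[i], k),
          individual_id = ids[i], group_id = grp[i], season = seasons[s],
          collection_date = as.Date(sprintf("2018-%02d-%02d", m, d)),
          stringsAsFactors = FALSE)
        comp_rows[[r]] <- rdirichlet(1, cfg$within_season_concentration *
                                          comp[s, ])
      }
    }
  }
  samples <- do.call(rbind, rows)
  psc <- do.call(rbind, comp_rows)
  dimnames(psc) <- list(samples$sample_id, taxa)

  structure(list(
    taxa = data.frame(taxon = taxa, sequence = seqs, genus = genus,
                      family = family, indicator_season = indicator,
                      detection_prob = cfg$detection_prob,
                      obs_level = lvl, stringsAsFactors = FALSE),
    season_names = seasons, season_composition = comp,
    samples = samples, per_sample_composition = psc,
    planted_artifacts = list(), origin_totals = NULL, cfg = cfg),
    class = "ground_truth")
}

#' Generate a replicate-level read table with planted artifacts
#'
#' Builds one sequencing library from a [gen_seasonal_profiles()] truth:
#' every fecal sample gets `replicates_per_sample` PCR wells with
#' log-normally drawn depth and multinomial counts from the sample's true
#' composition; control wells (blanks, extraction negatives, PCR negatives,
#' 70/30 two-taxon positive controls) are added; then host reads, uniform
#' tag-jump leakage proportional to each sequence's library total, and
#' low-level contaminants are planted. Every planted read is recorded so
#' recovery tests can score filters against the truth.
#'
#' @param truth a `ground_truth`.
#' @param cfg a [sim_config()]; defaults to the one inside `truth`.
#' @param library_id library identifier.
#' @return list with elements `table` (a [read_table()]) and `truth` (the
#'   input with `planted_artifacts` and `origin_totals` filled in).
#' @export
gen_read_table <- function(truth, cfg = truth$cfg, library_id = "lib1") {
  set.seed(cfg$rng_seed + 1L)
  mu <- cfg$depth_lognormal_params[1]; sig <- cfg$depth_lognormal_params[2]
  taxa_seq <- truth$taxa$sequence
  pc_seq <- draw_distinct_sequences(2, cfg$seq_len_range, avoid = taxa_seq)
  host_seq <- draw_distinct_sequences(2, cfg$seq_len_range,
                                      avoid = c(taxa_seq, pc_seq))
  contam_seq <- draw_distinct_sequences(3, cfg$seq_len_range,
                                        avoid = c(taxa_seq, pc_seq, host_seq))
  all_seq <- c(taxa_seq, pc_seq, host_seq, contam_seq)
  seq_role <- c(truth$taxa$taxon, c("PC_taxon_A", "PC_taxon_B"),
                c("host_vervet", "host_human"),
                paste0("contaminant_", 1:3))

  su <- truth$samples
  sunits <- do.call(rbind, lapply(seq_len(cfg$replicates_per_sample),
    function(k) data.frame(
      unit_id = paste0(su$sample_id, "_r", k), sample_id = su$sample_id,
      individual_id = su$individual_id, group_id = su$group_id,
      collection_date = su$collection_date, replicate_index = k,
      unit_type = "sample", stringsAsFactors = FALSE)))
  sunits <- sunits[order(sunits$sample_id, sunits$replicate_index), ]
  ctrl <- function(type, n, tag) if (n == 0) NULL else data.frame(
    unit_id = sprintf("%s_%02d", tag, seq_len(n)), sample_id = NA,
    individual_id = NA, group_id = NA, collection_date = as.Date(NA),
    replicate_index = NA_integer_, unit_type = type, stringsAsFactors = FALSE)
  units <- rbind(sunits,
                 ctrl("blank", cfg$n_blanks, "blank"),
                 ctrl("extraction_negative", cfg$n_extraction_neg, "extneg"),
                 ctrl("pcr_negative", cfg$n_pcr_neg, "pcrneg"),
                 ctrl("positive_control", cfg$n_positive, "pos"))
  rownames(units) <- NULL
  n_units <- nrow(units)
  zero <- matrix(0, length(all_seq), n_units,
                 dimnames = list(all_seq, units$unit_id))
  comp <- zero; pc <- zero; host <- zero; jump <- zero; contam <- zero

  is_sample <- units$unit_type == "sample"
  for (j in which(is_sample)) {
    depth <- round(rlnorm(1, mu, sig))
    if (depth == 0) next
    p <- truth$per_sample_composition[units$sample_id[j], ]
    comp[seq_along(taxa_seq), j] <- rmultinom(1, depth, p)
    if (cfg$host_read_fraction > 0) {
      h <- round(depth * cfg$host_read_fraction / (1 - cfg$host_read_fraction))
      hv <- rbinom(1, h, 0.9)
      host[length(taxa_seq) + 3L, j] <- hv
      host[length(taxa_seq) + 4L, j] <- h - hv
    }
  }
  for (j in which(units$unit_type == "positive_control")) {
    depth <- round(rlnorm(1, mu, sig))
    if (depth == 0) next
    pc[length(taxa_seq) + 1:2, j] <- rmultinom(1, depth, c(0.7, 0.3))
  }

  base <- comp + pc + host
  if (cfg$tagjump_rate > 0) {
    for (s in which(rowSums(base) > 0)) {
      nj <- rbinom(n_units, base[s, ], cfg$tagjump_rate)
      for (src in which(nj > 0)) {
        dest <- sample(setdiff(seq_len(n_units), src), nj[src], replace = TRUE)
        tb <- tabulate(dest, n_units)
        jump[s, ] <- jump[s, ] + tb
      }
    }
  }
  if (cfg$contaminant_rate > 0) {
    lam <- ifelse(is_sample,
                  cfg$contaminant_rate * cfg$sample_contamination_factor,
                  cfg$contaminant_rate)
    ncon <- rpois(n_units, lam)
    ci <- length(taxa_seq) + 4L + 1:3
    for (j in which(ncon > 0))
      contam[ci, j] <- rmultinom(1, ncon[j], rep(1 / 3, 3))
  }

  planted <- function(m) {
    idx <- which(m > 0, arr.ind = TRUE)
    data.frame(unit_id = colnames(m)[idx[, 2]],
               sequence = rownames(m)[idx[, 1]],
               count = m[idx], stringsAsFactors = FALSE)
  }
  truth$planted_artifacts <- list(tagjump = planted(jump),
                                  contaminant = planted(contam),
                                  host = planted(host))
  truth$origin_totals <- c(composition = sum(comp), positive_control = sum(pc),
                           host = sum(host), tagjump = sum(jump),
                           contaminant = sum(contam))
  truth$sequence_roles <- data.frame(sequence = all_seq, role = seq_role,
                                     stringsAsFactors = FALSE)
  total <- comp + pc + host + jump + contam
  tab <- read_table(total[rowSums(total) > 0, , drop = FALSE], units,
                    library_id = library_id)
  list(table = tab, truth = truth)
}

SPER01_FWD <- "GGGCAATCCTGAGCCAA"
SPER01_REV <- "CCATTGAGTCTCTGCACCTATC"

#' Tag assignment table for a read table's units
#'
#' Assigns each unit a unique pair of 8-nt tags plus the amplification
#' primers, in the layout expected by [demultiplex()]: columns `unit_id`,
#' `forward_tag`, `reverse_tag`, `forward_primer`, `reverse_primer`.
#'
#' @param table a [read_table()] (only its units are used).
#' @param seed integer seed.
#' @param forward_primer,reverse_primer primer sequences.
#' @return a data.frame of class `tag_table`.
#' @export
gen_tag_table <- function(table, seed = 1L, forward_primer = SPER01_FWD,
                          reverse_primer = SPER01_REV) {
  set.seed(seed)
  n <- nrow(table$units)
  tags <- character(0)
  while (length(tags) < 2 * n) {
    tags <- unique(c(tags, random_dna(2 * n, c(8, 8))))
  }
  tags <- tags[seq_len(2 * n)]
  structure(data.frame(unit_id = table$units$unit_id,
                       forward_tag = tags[seq_len(n)],
                       reverse_tag = tags[n + seq_len(n)],
                       forward_primer = forward_primer,
                       reverse_primer = reverse_primer,
                       stringsAsFactors = FALSE),
            class = c("tag_table", "data.frame"))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

mutate_positions <- function(seqs, start, width, error_rate) {
  # substitution errors restricted to [start, start+width-1] of each string
  n_err <- rbinom(length(seqs), width, error_rate)
  for (i in which(n_err > 0)) {
    pos <- start + sample.int(width, n_err[i]) - 1L
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Emit tagged raw amplicon reads for a read table
#'
#' One FASTA record per read: `forward_tag + forward_primer + insert +
#' revcomp(reverse_primer) + revcomp(reverse_tag)`. Substitution errors at
#' `error_rate` per base are confined to the two primer regions, so the
#' primer-mismatch tolerance of [demultiplex()] is exercised while tags and
#' inserts stay exact.
#'
#' @param table a [read_table()].
#' @param tags a [gen_tag_table()] covering every unit of `table`.
#' @param error_rate per-base substitution rate within primer regions.
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet] of reads.
#' @export
gen_raw_reads <- function(table, tags, error_rate = 0, seed = 1L) {
  set.seed(seed)
  if (anyDuplicated(paste(tags$forward_tag, tags$reverse_tag)))
    stop("duplicate tag pair in tag table")
  missing <- setdiff(table$units$unit_id, tags$unit_id)
  if (length(missing)) stop("units without tag assignment: ",
                            paste(head(missing), collapse = ", "))
  tg <- tags[match(table$units$unit_id, tags$unit_id), ]
  reads <- character(0)
  for (j in seq_len(ncol(table$counts))) {
    cnt <- table$counts[, j]
    nz <- which(cnt > 0)
    if (!length(nz)) next
    inserts <- rep(rownames(table$counts)[nz], cnt[nz])
    fp <- tg$forward_primer[j]; rp <- tg$reverse_primer[j]
    body <- paste0(tg$forward_tag[j], fp, inserts, revcomp(rp),
                   revcomp(tg$reverse_tag[j]))
    if (error_rate > 0) {
      body <- mutate_positions(body, 9L, nchar(fp), error_rate)
      body <- vapply(body, function(b)
        paste0(substr(b, 1, nchar(b) - 8 - nchar(rp)),
               mutate_positions(substr(b, nchar(b) - 8 - nchar(rp) + 1,
                                       nchar(b) - 8), 1L, nchar(rp),
                                error_rate),
               substr(b, nchar(b) - 7, nchar(b))), character(1),
        USE.NAMES = FALSE)
    }
    reads <- c(reads, body)
  }
  reads <- sample(reads)                       # shuffle library order
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read_%07d", seq_along(reads))
  out
}

#' Simulate a year of focal-observation feeding records
#'
#' For each season, `focal_days_per_season` observation days are drawn from
#' the season's months; each day has `follows_per_day` 20-minute focal
#' follows of 10 instantaneous screenings each (so daily screening totals
#' are multiples of 10). Feeding events occur at `feeding_rate` per
#' screening, items drawn from the day's true season composition and thinned
#' by each taxon's detection probability; recorded labels follow the taxon's
#' observer resolution (species, genus, or an undetermined broad category).
#'
#' @param truth a `ground_truth`.
#' @param cfg a [sim_config()]; defaults to the one inside `truth`.
#' @return a `focal_log`: list with `events` (date, individual_id, item,
#'   level, taxon) and `screenings` (date, n_screenings).
#' @export
gen_focal_log <- function(truth, cfg = truth$cfg) {
  set.seed(cfg$rng_seed + 2L)
  seasons <- truth$season_names
  months_by_season <- list(spring = c(9, 10), summer = c(12, 1, 2),
                           autumn = 4, winter = c(6, 7))
  taxa <- truth$taxa
  label_of <- function(i) switch(taxa$obs_level[i],
                                 species = taxa$taxon[i],
                                 genus = taxa$genus[i],
                                 broad = "undetermined_item")
  ev <- list(); scr <- list(); e <- 0L
  ids <- sprintf("ind_%03d", seq_len(cfg$n_individuals))
  for (s in seq_along(seasons)) {
    mo <- if (length(seasons) == 4) months_by_season[[seasons[s]]] else
      ((s - 1L) %% 12L) + 1L
    days <- unique(as.Date(sprintf(
      "2018-%02d-%02d", sample(rep(mo, 2), cfg$focal_days_per_season, TRUE),
      sample.int(28, cfg$focal_days_per_season, TRUE))))
    for (d in as.list(days)) {
      n_follow <- cfg$follows_per_day
      n_screen <- 10L * n_follow
      followed <- sample(ids, min(n_follow, length(ids)))
      scr[[length(scr) + 1L]] <- data.frame(date = d, n_screenings = n_screen)
      n_ev <- rbinom(1, n_screen, cfg$feeding_rate)
      if (n_ev == 0) next
      tx <- sample.int(cfg$n_taxa, n_ev, replace = TRUE,
                       prob = truth$season_composition[s, ])
      seen <- runif(n_ev) < taxa$detection_prob[tx]
      for (i in which(seen)) {
        e <- e + 1L
        ev[[e]] <- data.frame(
          date = d, individual_id = sample(followed, 1),
          item = label_of(tx[i]), level = taxa$obs_level[tx[i]],
          taxon = taxa$taxon[tx[i]], stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (e) do.call(rbind, ev) else
    data.frame(date = as.Date(character(0)), individual_id = character(0),
               item = character(0), level = character(0), taxon = character(0))
  screenings <- do.call(rbind, scr)
  screenings <- aggregate(n_screenings ~ date, screenings, sum)
  structure(list(events = events, screenings = screenings),
            class = "focal_log")
}

#' Reconcile planted read origins with the table total
#'
#' Checks the planted-truth bookkeeping of [gen_read_table()]: the sum of
#' the per-origin totals (composition, positive control, host, tag-jump,
#' contaminant) must equal the grand total of the table.
#'
#' @param sim output of [gen_read_table()].
#' @return named origin totals, invisibly; errors if they do not reconcile.
#' @export
check_origin_totals <- function(sim) {
  tot <- sum(sim$truth$origin_totals)
  if (abs(tot - total_reads(sim$table)) > 1e-9)
    stop("origin totals do not reconcile with table total")
  invisible(sim$truth$origin_totals)
}
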