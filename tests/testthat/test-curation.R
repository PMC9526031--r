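test_that("length filter enforces barcode bounds", {
  seqs <- c(strrep("A", 9), toy_seqs(2, len = 60), strrep("G", 250))
  counts <- matrix(5, 4, 2, dimnames = list(seqs, c("u1", "u2")))
  tab <- toy_table(counts)
  out <- length_filter(tab, 10, 220)
  expect_setequal(rownames(out$counts), seqs[2:3])
  r <- attr(out, "report")
  expect_equal(r$reads_in, r$reads_out + r$reads_removed)

  expect_equal(nrow(length_filter(tab, 0, Inf)$counts), 4)
  empty <- length_filter(tab, 300, 400)
  expect_equal(nrow(empty$counts), 0)
  expect_identical(empty$units, tab$units)
})

test_that("minimum library count is summed over samples and controls", {
  seqs <- toy_seqs(4)
  counts <- rbind(c(3, 3, 3, 0, 0, 0),    # 9 -> removed
                  c(3, 3, 3, 1, 0, 0),    # 10 incl. a control read -> kept
                  c(10, 0, 0, 0, 0, 0),   # 10 -> kept
                  c(0, 0, 0, 9, 0, 0))    # 9 in control only -> removed
  dimnames(counts) <- list(seqs, paste0("u", 1:6))
  tab <- toy_table(counts, types = c(rep("sample", 3), "blank",
                                     "extraction_negative", "pcr_negative"))
  out <- min_count_filter(tab, 10)
  expect_setequal(rownames(out$counts), seqs[2:3])
  expect_equal(nrow(min_count_filter(tab, 0)$counts), 4)
})

test_that("denoising merges low-abundance 1-mismatch children", {
  parent <- toy_seqs(1, len = 80, seed = 1)
  child <- parent
  substr(child, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(parent, 10, 10))[1]
  far <- toy_seqs(1, len = 80, seed = 2)
  counts <- rbind(c(600, 400), c(12, 8), c(50, 50))
  dimnames(counts) <- list(c(parent, child, far), c("u1", "u2"))
  tab <- toy_table(counts)
  out <- denoise_merge(tab, max_mismatch = 1, child_ratio = 0.05)
  expect_setequal(rownames(out$counts), c(parent, far))
  expect_equal(unname(out$counts[parent, ]), c(612, 408))
  expect_equal(total_reads(out), total_reads(tab))

  # equal-abundance 1-mismatch pair: the ratio test blocks both directions
  counts2 <- rbind(c(100, 0), c(100, 0))
  dimnames(counts2) <- list(c(parent, child), c("u1", "u2"))
  out2 <- denoise_merge(toy_table(counts2))
  expect_equal(nrow(out2$counts), 2)

  # child_ratio = 0 disables merging
  expect_equal(nrow(denoise_merge(tab, child_ratio = 0)$counts), 3)
})

test_that("greedy clustering matches the alignment oracle", {
  # 100-bp representative plus a 3-substitution (97%) minor variant
  rep100 <- toy_seqs(1, len = 100, seed = 3)
  var3 <- rep100
  for (p in c(5, 50, 95))
    substr(var3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(rep100, p, p))[1]
  expect_equal(nw_identity(rep100, var3), 0.97)
  counts <- rbind(c(500, 500), c(30, 20))
  dimnames(counts) <- list(c(rep100, var3), c("u1", "u2"))
  out <- cluster_greedy(toy_table(counts), 0.97)
  expect_equal(nrow(out$counts), 1)
  expect_equal(rownames(out$counts), rep100)  # most abundant member leads
  expect_equal(unname(out$counts[1, ]), c(530, 520))

  # threshold 1.0 on distinct sequences is the identity transform
  distinct <- toy_seqs(5, len = 70, seed = 4)
  cd <- matrix(10, 5, 2, dimnames = list(distinct, c("u1", "u2")))
  expect_equal(nrow(cluster_greedy(toy_table(cd), 1.0)$counts), 5)

  # brute-force equivalence + row-order invariance on a mutated family
  set.seed(8)
  base <- toy_seqs(3, len = 90, seed = 5)
  seqs <- base
  for (b in base) {
    for (k in 1:2) {
      v <- b
      for (p in sample(90, k))
        substr(v, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(b, p, p)), 1)
      seqs <- c(seqs, v)
    }
  }
  seqs <- unique(seqs)
  totals <- rev(seq(100, by = 37, length.out = length(seqs)))
  counts <- cbind(ceiling(totals / 2), floor(totals / 2))
  rownames(counts) <- seqs; colnames(counts) <- c("u1", "u2")
  got <- cluster_greedy(toy_table(counts), 0.97)
  oracle <- brute_greedy_cluster(seqs, rowSums(counts), 0.97)
  expect_setequal(rownames(got$counts), unique(unname(oracle)))
  for (r in rownames(got$counts))
    expect_equal(unname(got$counts[r, 1] + got$counts[r, 2]),
                 unname(sum(rowSums(counts)[names(oracle)[oracle == r]])))

  perm <- sample(nrow(counts))
  got_perm <- cluster_greedy(toy_table(counts[perm, , drop = FALSE]), 0.97)
  expect_identical(got$counts, got_perm$counts)
})

test_that("contaminant rule compares relative abundance maxima strictly", {
  seqs <- toy_seqs(3)
  #               s1   s2   neg
  counts <- rbind(c(10, 15, 50),    # 50% of the negative, ~1% of samples
                  c(500, 600, 40),
                  c(490, 385, 10))
  dimnames(counts) <- list(seqs, c("u1", "u2", "n1"))
  tab <- toy_table(counts, types = c("sample", "sample",
                                     "extraction_negative"))
  res <- remove_contaminants(tab)
  expect_setequal(rownames(res$table$counts), seqs[2:3])
  expect_equal(res$report$reads_in,
               res$report$reads_out + res$report$reads_removed)

  # sequence absent from all controls is kept even if rare in samples
  counts2 <- rbind(c(1, 0, 0), c(999, 1000, 100))
  dimnames(counts2) <- list(seqs[1:2], c("u1", "u2", "n1"))
  tab2 <- toy_table(counts2, types = c("sample", "sample", "pcr_negative"))
  expect_equal(nrow(remove_contaminants(tab2)$table$counts), 2)

  # no control units: identity with a warning
  tab3 <- toy_table(counts2[, 1:2])
  expect_warning(res3 <- remove_contaminants(tab3), "no negative-control")
  expect_identical(res3$table$counts, tab3$counts)
})

test_that("tag-jump ratio follows the hand-computed blank leak fraction", {
  seqs <- toy_seqs(2)
  # sequence 1: library total 10000, blank count 20 -> f = 0.002
  counts <- rbind(c(9940, 30, 10, 20),
                  c(1000, 900, 800, 0))
  dimnames(counts) <- list(seqs, c("u1", "u2", "u3", "b1"))
  tab <- toy_table(counts, types = c("sample", "sample", "sample", "blank"))
  res <- tagjump_filter(tab, quantile = 1.0)
  expect_equal(res$report$ratio, 0.002)
  # cells below r * T_s are zeroed: 10 < 20 for sequence 1
  expect_equal(unname(res$table$counts[seqs[1], ]), c(9940, 30, 0, 20))
  # sequence 2 threshold = 0.002 * 2700 = 5.4; all cells comfortably above
  expect_equal(unname(res$table$counts[seqs[2], ]), c(1000, 900, 800, 0))

  # no reads in blanks: ratio 0, table unchanged
  counts0 <- counts; counts0[, "b1"] <- 0
  tab0 <- toy_table(counts0, types = c("sample", "sample", "sample", "blank"))
  res0 <- tagjump_filter(tab0)
  expect_equal(res0$report$ratio, 0)
  expect_identical(res0$table$counts, tab0$counts)
})

test_that("replicate aggregation applies the 2-of-3 rule with a 5-read mean", {
  seqs <- toy_seqs(3)
  counts <- rbind(c(6, 7, 0),      # 2/3 present, mean 13/3 < 5 -> 0
                  c(10, 20, 30),   # mean 20 retained
                  c(100, 0, 0))    # 1/3 present -> 0
  dimnames(counts) <- list(seqs, c("sA_r1", "sA_r2", "sA_r3"))
  tab <- toy_table(counts, sample_ids = rep("sA", 3),
                   replicate_index = 1:3)
  st <- aggregate_replicates(tab, min_replicates = 2, min_mean_reads = 5)
  expect_equal(unname(st$values[, "sA"]), c(0, 20, 0))

  # a sample with too few replicate units is excluded with a warning
  counts2 <- cbind(counts, sB_r1 = c(50, 50, 50))
  tab2 <- toy_table(counts2, sample_ids = c(rep("sA", 3), "sB"),
                    replicate_index = c(1:3, 1L))
  expect_warning(st2 <- aggregate_replicates(tab2), "sB")
  expect_equal(colnames(st2$values), "sA")
})

test_that("host removal drops host sequences everywhere, controls included", {
  cfg <- fast_cfg(rng_seed = 31)
  truth <- gen_seasonal_profiles(cfg)
  db <- truth_db(truth)
  host_seq <- toy_seqs(1, len = 70, seed = 6)
  seqs <- c(truth$taxa$sequence[1:2], host_seq)
  counts <- rbind(c(100, 100, 0), c(200, 200, 0), c(300, 300, 40))
  dimnames(counts) <- list(seqs, c("u1", "u2", "n1"))
  tab <- toy_table(counts, types = c("sample", "sample", "pcr_negative"))
  host_db <- reference_db(data.frame(
    seq_id = "h1", sequence = host_seq,
    taxon_path = "Animalia;Primates;Cercopithecidae;Chlorocebus;Chlorocebus_pygerythrus",
    rank = "species", species = "Chlorocebus_pygerythrus",
    geographic_valid = TRUE))
  asg <- assign_taxonomy(tab, global_db = reference_db(rbind(
    as.data.frame(db), as.data.frame(host_db)), scope = "global"))
  res <- remove_host(tab, asg, host_taxa = "Chlorocebus_pygerythrus")
  expect_setequal(rownames(res$table$counts), seqs[1:2])
  expect_equal(res$report$reads_removed, 640)

  # empty host list: identity
  res0 <- remove_host(tab, asg, character(0))
  expect_identical(res0$table$counts, tab$counts)
})

test_that("every stage conserves reads_in = reads_out + reads_removed", {
  for (seed in 1:3) {
    cfg <- fast_cfg(rng_seed = seed, tagjump_rate = 0.005,
                    contaminant_rate = 3, host_read_fraction = 0.1)
    sim <- gen_read_table(gen_seasonal_profiles(cfg), cfg)
    db <- truth_db(sim$truth)
    res <- suppressWarnings(curate(sim$table, global_db = db,
                                   host_taxa = "host"))
    for (st in res$report)
      expect_equal(st$reads_in, st$reads_out + st$reads_removed,
                   tolerance = 1e-9)
  }
})
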