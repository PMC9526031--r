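test_that("Shannon index and Hutcheson variance behave", {
  expect_equal(shannon(rep(25, 4))$H, log(4))
  expect_equal(shannon(c(0, 0, 17, 0))$H, 0)
  expect_error(shannon(c(0, 0)), "all-zero")
  # zero-category padding leaves H untouched
  expect_equal(shannon(c(5, 9, 0, 0, 3))$H, shannon(c(5, 9, 3))$H)
  d <- shannon(c(40, 30, 20, 10))
  expect_true(d$H <= log(d$S) + 1e-12)

  # variance against a bootstrap oracle at N = 10,000
  set.seed(2)
  p <- c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  x <- as.vector(rmultinom(1, 10000, p))
  est <- shannon(x)$variance
  boot <- replicate(400, {
    xx <- as.vector(rmultinom(1, 10000, x / sum(x)))
    shannon(xx)$H
  })
  expect_lt(abs(est - var(boot)) / var(boot), 0.2)
})

test_that("Hutcheson t-test separates what it should and only that", {
  x <- c(100, 100, 100, 100)
  h <- hutcheson_t(x, x)
  expect_equal(h$t, 0)
  expect_equal(h$p_value, 1)
  a <- c(100, 100, 100, 100); b <- c(397, 1, 1, 1)
  h1 <- hutcheson_t(a, b); h2 <- hutcheson_t(b, a)
  expect_equal(h1$t, -h2$t)
  expect_equal(h1$p_value, h2$p_value)
  expect_lt(h1$p_value, 0.01)
  expect_error(hutcheson_t(c(5), c(5)), "zero pooled variance")
})

test_that("Bray-Curtis matches hand computation and the vegan oracle", {
  m <- rbind(a = c(0.3, 0.7), b = c(0.7, 0.3), c = c(0.3, 0.7))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.4)
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis(disjoint)["a", "b"], 1)
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))), "all-zero")

  set.seed(5)
  x <- matrix(runif(48), 6, 8, dimnames = list(paste0("r", 1:6), NULL))
  expect_equal(unclass(bray_curtis(x)),
               as.matrix(vegan::vegdist(x, "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(bray_curtis(x)), brute_bray(x), tolerance = 1e-12)
})

test_that("Mantel r matches brute force; exhaustive null on 5 labels", {
  set.seed(6)
  x <- matrix(runif(25), 5, 5, dimnames = list(letters[1:5], NULL))
  y <- matrix(runif(25), 5, 5, dimnames = list(letters[1:5], NULL))
  d1 <- bray_curtis(x); d2 <- bray_curtis(y)
  mt <- mantel_test(d1, d2, n_perm = 999, seed = 3)
  expect_equal(mt$statistic, brute_mantel_r(d1, d2))
  expect_equal(mt$statistic,
               unname(vegan::mantel(d1, d2, permutations = 9)$statistic),
               tolerance = 1e-12)
  # identical matrices correlate perfectly
  expect_equal(mantel_test(d1, d1, n_perm = 99, seed = 1)$statistic, 1)

  # exhaustive permutation tail vs the sampled estimator
  perms <- all_perms(5)
  exact <- apply(perms, 1, function(p)
    brute_mantel_r(d1, d2[p, p]))
  exact_p <- mean(exact >= mt$statistic - 1e-12)
  expect_lt(abs(mt$p_value - exact_p), 0.08)

  # invariant to joint relabeling
  p <- c(3, 1, 5, 2, 4)
  mt2 <- mantel_test(d1[p, p], d2[p, p], n_perm = 99, seed = 1)
  expect_equal(mt2$statistic, mt$statistic)

  expect_error(mantel_test(d1, d2[1:4, 1:4]), "size")
})

test_that("PCoA exactly embeds Euclidean configurations", {
  set.seed(7)
  pts <- cbind(runif(5, 0, 3), runif(5, 0, 3))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("p", 1:5)
  pc <- pcoa(d)
  expect_equal(as.matrix(dist(pc$coordinates)), d,
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(sum(pc$relative_eigenvalues), 1, tolerance = 1e-12)
  expect_length(pc$negative_eigenvalues, 0)

  # duplicate points coincide
  d2 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  pc2 <- pcoa(d2)
  expect_equal(pc2$coordinates[1, ], pc2$coordinates[2, ],
               tolerance = 1e-10)

  # non-Euclidean input reports negative eigenvalues instead of hiding them
  set.seed(8)
  comp <- matrix(runif(40), 8, 5)
  pcb <- pcoa(bray_curtis(comp))
  expect_true(length(pcb$negative_eigenvalues) > 0)
  expect_equal(sum(pcb$relative_eigenvalues), 1, tolerance = 1e-12)
})

test_that("ANOSIM matches brute force, vegan, and its bounds", {
  # two fully separated tight clusters: R = 1
  m <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  rownames(m) <- paste0("r", 1:10)
  d <- as.matrix(dist(m)); rownames(d) <- colnames(d) <- rownames(m)
  g <- rep(c("a", "b"), each = 5)
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)
  expect_lte(res$p_value, 0.02)

  set.seed(9)
  x <- matrix(runif(42), 6, 7, dimnames = list(paste0("r", 1:6), NULL))
  db <- bray_curtis(x)
  gg <- c("a", "a", "a", "b", "b", "b")
  mine <- anosim(db, gg, n_perm = 99, seed = 2)
  expect_equal(mine$statistic, brute_anosim_R(db, gg))
  expect_equal(mine$statistic,
               unname(vegan::anosim(db, gg, permutations = 9)$statistic),
               tolerance = 1e-12)
  expect_gte(mine$statistic, -1); expect_lte(mine$statistic, 1)

  # exhaustive label permutations on 6 units confirm the p estimate
  perms <- all_perms(6)
  exact <- apply(perms, 1, function(p) brute_anosim_R(db, gg[p]))
  exact_p <- mean(exact >= mine$statistic - 1e-12)
  expect_lt(abs(mine$p_value - exact_p), 0.12)

  expect_error(anosim(db, c("a", rep("b", 5))), ">= 2 members")
  expect_error(anosim(db, rep("a", 6)), "two groups")
})

test_that("random labels give mean ANOSIM R near zero", {
  set.seed(10)
  x <- matrix(runif(60), 12, 5, dimnames = list(paste0("r", 1:12), NULL))
  d <- bray_curtis(x)
  ut <- upper.tri(d)
  rs <- replicate(500, brute_anosim_R(d, sample(rep(c("a", "b"), 6))))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("IndVal follows the Dufrene-Legendre formula", {
  # perfect indicator: present in every row of one group, absent elsewhere
  # (5 + 5 units so the permutation null can actually reach p < 0.05)
  m <- cbind(ind = c(rep(1, 5), rep(0, 5)),
             noise = c(0.5, 0.4, 0.6, 0.5, 0.45, 0.55, 0.5, 0.42, 0.58, 0.5))
  rownames(m) <- paste0("u", 1:10)
  g <- rep(c("g1", "g2"), each = 5)
  res <- indval(m, g, n_perm = 199, seed = 1)
  t1 <- res$taxa[res$taxa$taxon == "ind", ]
  expect_equal(t1$statistic, 100)
  expect_equal(t1$group, "g1")
  expect_lte(t1$p_value, 0.05)

  # taxon uniform across 2 equal groups: A = 0.5, B = 1 -> IndVal 50
  m2 <- cbind(u = rep(1, 10))
  rownames(m2) <- paste0("u", 1:10)
  res2 <- indval(m2, g, n_perm = 99, seed = 1)
  expect_equal(res2$taxa$statistic, 50)

  # matches the brute-force component formula on random data
  set.seed(11)
  m3 <- matrix(rpois(48, 2) * runif(48), 8, 6,
               dimnames = list(paste0("u", 1:8), paste0("t", 1:6)))
  g3 <- rep(c("x", "y"), each = 4)
  keep <- colSums(m3) > 0
  res3 <- indval(m3[, keep, drop = FALSE], g3, n_perm = 49, seed = 2)
  expect_equal(res3$indval, brute_indval(m3[, keep, drop = FALSE], g3),
               tolerance = 1e-12)
  # A sums to 1 over groups wherever the taxon occurs
  expect_equal(unname(colSums(res3$A)), rep(1, sum(keep)), tolerance = 1e-12)
})

test_that("per-item Spearman applies count and shared-barcode filters", {
  months <- sprintf("%02d", 1:6)
  ev <- cbind(A = 1:6 / 21, B = 6:1 / 21, `X/Y` = rep(1 / 21, 6))
  ev <- ev / rowSums(ev)
  rownames(ev) <- months
  fv <- cbind(A = 1:6 / 21, B = 1:6 / 21, X = rep(1, 6), Y = rep(1, 6))
  rownames(fv) <- months
  edna <- diet_profile(ev, data.frame(temporal_unit = months),
                       normalized = TRUE)
  focal <- diet_profile(fv / rowSums(fv), data.frame(temporal_unit = months))
  counts <- c(A = 400, B = 349, X = 500, Y = 500)
  res <- spearman_by_item(edna, focal, min_focal_count = 350,
                          focal_counts = counts)
  # B fails the 350 floor; X/Y matches two observed species -> excluded
  expect_equal(res$item, "A")
  expect_equal(res$rho, 1)

  # reversed series anticorrelate perfectly
  res2 <- spearman_by_item(edna, focal, min_focal_count = 1,
                           focal_counts = counts)
  expect_equal(res2$rho[res2$item == "B"], -1)
})
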