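perm_result <- function(statistic, n_perm, p_value, seed, method) {
  structure(list(statistic = statistic, n_permutations = n_perm,
                 p_value = p_value, seed = seed, method = method),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$method, x$statistic, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

perm_p <- function(perm_stats, observed) {
  (1 + sum(perm_stats >= observed - 1e-12)) / (1 + length(perm_stats))
}

profile_values <- function(x) {
  if (inherits(x, "diet_profile")) x$values else as.matrix(x)
}

#' Shannon-Wiener diversity with the Hutcheson variance
#'
#' `H = -sum(p log p)` in nats over non-zero proportions, with the
#' approximate estimator variance
#' `(sum(p log^2 p) - H^2) / N + (S - 1) / (2 N^2)` used by the Hutcheson
#' t-test. `N` is the total count, so the variance is meaningful for count
#' input.
#'
#' @param x non-negative counts (or proportions) for one community.
#' @return a `diversity_result` list: `H`, `variance`, `N`, `S`.
#' @export
shannon <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0)) stop("counts must be non-negative")
  N <- sum(x)
  if (N == 0) stop("all-zero input")
  p <- x[x > 0] / N
  S <- length(p)
  H <- -sum(p * log(p))
  v <- (sum(p * log(p)^2) - H^2) / N + (S - 1) / (2 * N^2)
  structure(list(H = H, variance = max(v, 0), N = N, S = S),
            class = "diversity_result")
}

#' Hutcheson t-test comparing two Shannon indices
#'
#' `t = (H1 - H2) / sqrt(V1 + V2)` with Welch-style degrees of freedom
#' `(V1 + V2)^2 / (V1^2 / N1 + V2^2 / N2)` and a two-sided p-value from the
#' t distribution.
#'
#' @param c1,c2 count vectors of the two communities.
#' @return list with `t`, `df`, `p_value`, and the two `diversity_result`s.
#' @export
hutcheson_t <- function(c1, c2) {
  d1 <- shannon(c1); d2 <- shannon(c2)
  V <- d1$variance + d2$variance
  if (V <= 0) stop("zero pooled variance")
  t <- (d1$H - d2$H) / sqrt(V)
  df <- V^2 / (d1$variance^2 / d1$N + d2$variance^2 / d2$N)
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p_value = p, d1 = d1, d2 = d2)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over items; values lie in
#' \[0, 1\] for non-negative profiles. A pair of all-zero rows has no
#' defined dissimilarity and raises an error.
#'
#' @param profiles a `diet_profile` or non-negative matrix (rows = units).
#' @return symmetric `distance_matrix` (a base matrix with zero diagonal).
#' @export
bray_curtis <- function(profiles) {
  m <- profile_values(profiles)
  if (any(m < 0)) stop("profiles must be non-negative")
  n <- nrow(m)
  if (sum(rowSums(m) == 0) > 1) stop("two all-zero rows: undefined pair")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      s <- sum(xi + m[j, ])
      d[i, j] <- d[j, i] <- if (s == 0) NA_real_ else
        sum(abs(xi - m[j, ])) / s
    }
  }
  structure(d, class = c("distance_matrix", class(d)))
}

upper_entries <- function(d) d[upper.tri(d)]

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries; the null distribution
#' permutes the rows and columns of the second matrix simultaneously.
#' One-sided p-value for positive association with the
#' `(1 + hits) / (1 + n_perm)` estimator.
#'
#' @param d1,d2 symmetric distance matrices with matching labels and order.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return a `perm_result` (statistic = Mantel r).
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = 1L) {
  d1 <- unclass(d1); d2 <- unclass(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrix labels do not match")
  r_obs <- cor(upper_entries(d1), upper_entries(d2))
  set.seed(seed)
  n <- nrow(d1)
  perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    cor(upper_entries(d1), upper_entries(d2[p, p]))
  }, numeric(1))
  perm_result(r_obs, n_perm, perm_p(perm, r_obs), seed, "Mantel")
}

#' Principal coordinates analysis (metric MDS)
#'
#' Gower double-centering of `-d^2 / 2`, eigendecomposition, coordinates
#' scaled by the square roots of the positive eigenvalues. Relative
#' eigenvalues are each positive eigenvalue over the sum of positive
#' eigenvalues; negative eigenvalues are reported, not silently dropped.
#' Axis signs follow the convention that the first non-zero coordinate of
#' each axis is positive.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param tol eigenvalues within `tol * max(lambda)` of zero are dropped.
#' @return list with `coordinates`, `eigenvalues` (all),
#'   `relative_eigenvalues` (positive axes), `negative_eigenvalues`.
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- unclass(as.matrix(d))
  n <- nrow(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  A <- -0.5 * d^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lambda <- e$values
  pos <- lambda > tol * max(abs(lambda))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(lambda[pos]), sum(pos))
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = lambda,
       relative_eigenvalues = lambda[pos] / sum(lambda[pos]),
       negative_eigenvalues = lambda[lambda < -tol * max(abs(lambda))])
}

anosim_stat <- function(rk, within, M) {
  (mean(rk[!within]) - mean(rk[within])) / (M / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Ranks all pairwise dissimilarities and compares mean between-group and
#' within-group ranks: `R = (rB - rW) / (M / 2)` with `M = n (n - 1) / 2`
#' pairs, so `R` lies in \[-1, 1\] and complete separation gives 1. The
#' null permutes group labels; one-sided p for separation.
#'
#' @param d symmetric distance matrix.
#' @param groups group membership (>= 2 groups of >= 2 members each).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return a `perm_result` (statistic = R).
#' @export
anosim <- function(d, groups, n_perm = 9999, seed = 1L) {
  d <- unclass(as.matrix(d))
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) stop("groups and matrix size differ")
  if (nlevels(droplevels(groups)) < 2) stop("need at least two groups")
  if (any(base::table(groups) < 2)) stop("every group needs >= 2 members")
  ut <- upper.tri(d)
  rku <- rank(d[ut])   # midranks over all off-diagonal pairs
  M <- sum(ut)
  gi <- matrix(as.integer(groups), nrow(d), nrow(d))
  within_u <- (gi == t(gi))[ut]
  r_obs <- anosim_stat(rku, within_u, M)
  set.seed(seed)
  n <- nrow(d)
  perm <- vapply(seq_len(n_perm), function(k) {
    g <- as.integer(groups)[sample.int(n)]
    gm <- matrix(g, n, n)
    anosim_stat(rku, (gm == t(gm))[ut], M)
  }, numeric(1))
  perm_result(r_obs, n_perm, perm_p(perm, r_obs), seed, "ANOSIM")
}

indval_components <- function(m, groups) {
  ng <- as.vector(base::table(groups)[sort(unique(as.character(groups)))])
  gm <- rowsum(m, as.character(groups)) / ng       # group mean abundance
  A <- sweep(gm, 2, colSums(gm), "/")
  occ <- rowsum((m > 0) + 0, as.character(groups)) / ng
  list(A = A, B = occ, indval = A * occ * 100)
}

#' Indicator value analysis (IndVal)
#'
#' For each taxon and group: specificity `A` is the group's mean abundance
#' over the sum of all groups' mean abundances, fidelity `B` is the
#' fraction of the group's units containing the taxon, and
#' `IndVal = A * B * 100`. Each taxon's statistic is its maximum over
#' groups; significance by permuting group labels (one-sided,
#' `(1 + hits) / (1 + n_perm)`). Taxa absent everywhere are excluded with a
#' warning.
#'
#' @param profiles a `diet_profile` or matrix (rows = units).
#' @param groups group membership per unit (e.g. season).
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return an `indval_result`: `indval` (group x taxon matrix), `A`, `B`,
#'   and a `taxa` data.frame (taxon, best group, statistic, p-value).
#' @export
indval <- function(profiles, groups, n_perm = 9999, seed = 1L) {
  m <- profile_values(profiles)
  groups <- as.character(groups)
  if (length(groups) != nrow(m)) stop("groups and profile rows differ")
  if (length(unique(groups)) < 2) stop("need at least two groups")
  absent <- colSums(m) == 0
  if (any(absent)) {
    warning("taxa absent everywhere excluded: ",
            paste(colnames(m)[absent], collapse = ", "))
    m <- m[, !absent, drop = FALSE]
  }
  obs <- indval_components(m, groups)
  stat <- apply(obs$indval, 2, max)
  best <- rownames(obs$indval)[apply(obs$indval, 2, which.max)]
  set.seed(seed)
  n <- nrow(m)
  hits <- numeric(ncol(m))
  for (k in seq_len(n_perm)) {
    g <- groups[sample.int(n)]
    ps <- apply(indval_components(m, g)$indval, 2, max)
    hits <- hits + (ps >= stat - 1e-12)
  }
  p <- (1 + hits) / (1 + n_perm)
  structure(list(indval = obs$indval, A = obs$A, B = obs$B,
                 taxa = data.frame(taxon = colnames(m), group = best,
                                   statistic = stat, p_value = p,
                                   row.names = NULL),
                 n_permutations = n_perm, seed = seed),
            class = "indval_result")
}

#' Per-item Spearman correlation between eDNA and focal monthly series
#'
#' For every item present in both monthly-aggregated profiles, with at
#' least `min_focal_count` events in the focal dataset, the Spearman rank
#' correlation (midrank ties) of the two monthly series is computed. Items
#' whose multi-species barcode label matches two or more observed species
#' are excluded; items with fewer than 3 shared months are skipped with a
#' warning.
#'
#' @param edna,focal monthly `diet_profile`s (meta `temporal_unit`).
#' @param min_focal_count minimum focal event total per item (default 350).
#' @param focal_counts named per-item focal event totals; defaults to the
#'   `"item_totals"` attribute carried by [normalize_focal()] output.
#' @return data.frame: item, n_months, rho, p_value.
#' @export
spearman_by_item <- function(edna, focal, min_focal_count = 350,
                             focal_counts = attr(focal, "item_totals")) {
  ev <- profile_values(edna); fv <- profile_values(focal)
  if (is.null(focal_counts))
    stop("per-item focal counts are required for the minimum-count filter")
  months <- intersect(rownames(ev), rownames(fv))
  # pair each eDNA item with its focal counterpart: exact label match, or a
  # multi-species barcode label whose single observed member species stands
  # in for it; labels matching two or more observed species are excluded
  pairs <- list()
  for (lab in colnames(ev)) {
    if (lab %in% colnames(fv)) {
      pairs[[lab]] <- lab
    } else if (grepl("/", lab, fixed = TRUE)) {
      members <- strsplit(lab, "/", fixed = TRUE)[[1]]
      obs <- members[members %in% colnames(fv)]
      if (length(obs) == 1) pairs[[lab]] <- obs
    }
  }
  keep <- vapply(pairs, function(f)
    isTRUE(focal_counts[f] >= min_focal_count), logical(1))
  pairs <- pairs[keep]
  out <- list()
  for (item in names(pairs)) {
    if (length(months) < 3) {
      warning("item skipped, fewer than 3 paired months: ", item)
      next
    }
    ct <- suppressWarnings(cor.test(ev[months, item],
                                    fv[months, pairs[[item]]],
                                    method = "spearman", exact = FALSE))
    out[[item]] <- data.frame(item = item, n_months = length(months),
                              rho = unname(ct$estimate),
                              p_value = ct$p.value)
  }
  if (!length(out))
    return(data.frame(item = character(0), n_months = integer(0),
                      rho = numeric(0), p_value = numeric(0)))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a permutation/statistic result as JSON
#' @param result a `perm_result`, `indval_result`, or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stat_result <- function(result, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write results")
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null",
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}
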