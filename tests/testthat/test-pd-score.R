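make_space <- function(a, b, x, y, species) {
  structure(tibble::tibble(a = a, b = b, x = x, y = y),
            species = species, class = c("distance_space", "tbl_df", "tbl", "data.frame"))
}

test_that("distance space has one point per pair with matrix coordinates", {
  set.seed(21)
  lab <- paste0("s", 1:4)
  v1 <- matrix(runif(16, 0.2, 1), 4); v1 <- (v1 + t(v1)) / 2; diag(v1) <- 0
  v2 <- matrix(runif(16, 0.2, 1), 4); v2 <- (v2 + t(v2)) / 2; diag(v2) <- 0
  phy <- standardize_dist(dist_matrix(v1, labels = lab))
  og <- standardize_dist(dist_matrix(v2, labels = lab))
  sp <- distance_space(phy, og)
  expect_equal(nrow(sp), 6)   # 4 choose 2
  i <- which(sp$a == "s2" & sp$b == "s3" | sp$a == "s3" & sp$b == "s2")
  expect_equal(sp$x[i], phy["s2", "s3"])
  expect_equal(sp$y[i], og["s2", "s3"])

  og_other <- standardize_dist(dist_matrix(v2, labels = paste0("z", 1:4)))
  expect_error(distance_space(phy, og_other), "label sets differ")
})

test_that("partition sizes follow the counting identities", {
  s4 <- random_space(4)
  p4 <- partition_points(s4, "t01")
  expect_length(p4$in_cluster, 3)
  expect_length(p4$out_cluster, 3)

  s3 <- random_space(3)
  p3 <- partition_points(s3, "t02")
  expect_length(p3$in_cluster, 2)
  expect_length(p3$out_cluster, 1)
  expect_length(intersect(p3$in_cluster, p3$out_cluster), 0)

  expect_error(partition_points(s4, "zz"), "not in distance space")
})

test_that("silhouette formulas: hand-evaluated and degenerate cases", {
  # C_c = {(0,0), (0,0)}, C_other = {(1,1)}: h = 0, f = sqrt(2), s = 1
  sp <- make_space(a = c("c", "c", "x"), b = c("x", "y", "y"),
                   x = c(0, 0, 1), y = c(0, 0, 1),
                   species = c("c", "x", "y"))
  fit <- pd_silhouette(sp, "c")
  expect_equal(fit$breakdown$h, c(0, 0))
  expect_equal(fit$breakdown$f, c(sqrt(2), sqrt(2)))
  expect_equal(fit$breakdown$s, c(1, 1))
  expect_equal(fit$pd, 1)

  # all coincident points: s = 0 by convention
  sp0 <- make_space(a = c("c", "c", "x"), b = c("x", "y", "y"),
                    x = c(0, 0, 0), y = c(0, 0, 0),
                    species = c("c", "x", "y"))
  expect_equal(pd_silhouette(sp0, "c")$pd, 0)
})

test_that("tidy/glance expose the per-point breakdown and the fit summary", {
  set.seed(31)
  s <- random_space(6)
  fit <- pd_silhouette(s, "t03")
  td <- tidy(fit)
  expect_equal(nrow(td), 5)
  expect_named(td, c("a", "b", "h", "f", "s"))
  gl <- glance(fit)
  expect_equal(gl$pd, fit$pd)
  expect_equal(gl$n_points_out, 10)
})

test_that("CHI and DBI conventions at degenerate geometries", {
  tight <- make_space(a = c("c", "c", "x"), b = c("x", "y", "y"),
                      x = c(0, 0, 1), y = c(0, 0, 1),
                      species = c("c", "x", "y"))
  expect_equal(chi_score(tight, "c"), Inf)  # zero scatter, distinct centroids
  expect_equal(dbi_score(tight, "c"), 0)

  coinc <- make_space(a = c("c", "c", "x"), b = c("x", "y", "y"),
                      x = c(-1, 1, 0), y = c(0, 0, 0),
                      species = c("c", "x", "y"))
  # in-centroid (0,0) == out-centroid (0,0)
  expect_equal(chi_score(coinc, "c"), 0)
  expect_equal(dbi_score(coinc, "c"), Inf)
})

test_that("scores are invariant to relabeling non-target species", {
  set.seed(41)
  s <- random_space(7)
  pd1 <- pd_silhouette(s, "t04")$pd
  chi1 <- chi_score(s, "t04")
  dbi1 <- dbi_score(s, "t04")
  perm <- sample(nrow(s))
  s2 <- make_space(s$a[perm], s$b[perm], s$x[perm], s$y[perm],
                   attr(s, "species"))
  expect_equal(pd_silhouette(s2, "t04")$pd, pd1, tolerance = 1e-12)
  expect_equal(chi_score(s2, "t04"), chi1, tolerance = 1e-12)
  expect_equal(dbi_score(s2, "t04"), dbi1, tolerance = 1e-12)
})

test_that("PD ranks an off-trend gene above a perfectly concordant one", {
  set.seed(51)
  lab <- paste0("s", 1:8)
  v <- matrix(runif(64, 0.2, 1.5), 8); v <- (v + t(v)) / 2; diag(v) <- 0
  phy <- standardize_dist(dist_matrix(v, labels = lab))
  concordant <- distance_space(phy, phy)   # y == x for every pair

  # displace the target's pair-points >= 2 standardized units off-diagonal
  v2 <- v
  v2[1, -1] <- v[1, -1] + 2.5 * attr(phy, "scale")
  v2[-1, 1] <- v2[1, -1]
  off <- distance_space(phy, standardize_dist(dist_matrix(v2, labels = lab)))
  expect_gt(pd_silhouette(off, "s1")$pd, pd_silhouette(concordant, "s1")$pd)
})

test_that("subsampled silhouette converges to the exact score at full size", {
  set.seed(61)
  s <- random_space(10)
  exact <- pd_silhouette(s, "t01")$pd
  full <- pd_silhouette(s, "t01", subsample_other = 36)$pd  # |C_other| = 36
  expect_equal(full, exact)
  sub <- pd_silhouette(s, "t01", subsample_other = 10, seed = 2)$pd
  expect_true(is.finite(sub) && abs(sub) <= 1)
})

test_that("gene score table: z-scores, dense ranking, flags, shift invariance", {
  spaces <- list()
  set.seed(71)
  base <- random_space(6)
  # three genes with increasing displacement of the target points
  for (k in 1:3) {
    s <- base
    part <- partition_points(s, "t01")
    s$y[part$in_cluster] <- s$y[part$in_cluster] + c(0, 1.2, 3)[k]
    spaces[[paste0("g", k)]] <- s
  }
  tab <- score_genes(spaces, "t01")
  expect_equal(tab$rank_pd, 1:3)
  expect_equal(mean(tab$z_pd), 0, tolerance = 1e-9)
  expect_equal(stats::sd(tab$z_pd), 1, tolerance = 1e-9)
  expect_equal(tab$group_id[1], "g3")

  # flags respond to the z threshold, not the raw PD level
  expect_equal(tab$above_threshold, tab$z_pd >= 1)
  tab2 <- score_genes(spaces, "t01", z_threshold = 10)
  expect_false(any(tab2$above_threshold))

  expect_warning(score_genes(spaces[1], "t01"), "single group")
})
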