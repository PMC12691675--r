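test_that("p-distance handles mismatches and gap policies", {
  m <- as_msa(c(a = "AAAA", b = "AAAT", c = "AAAA"), "dna")
  d <- dist_p(m)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)

  g <- as_msa(c(a = "A-AA", b = "ATAA"), "dna")
  expect_equal(dist_p(g)["a", "b"], 0)  # 0 mismatches over 3 compared columns

  allgap <- as_msa(c(a = "--AA", b = "TT--"), "dna")
  expect_error(dist_p(allgap), "no comparable columns")
})

test_that("nucleotide corrections match closed forms and inflate p", {
  # p = 0.3 under JC: 3 of 10 sites differ
  m <- as_msa(c(a = "AAAAAAAAAA", b = "AAAAAAACCC"), "dna")
  expect_equal(dist_p(m)["a", "b"], 0.3)
  expect_equal(dist_nt(m, "jc")["a", "b"], -0.75 * log(1 - 0.4),
               tolerance = 1e-12)

  set.seed(7)
  r1 <- sample(c("A", "C", "G", "T"), 200, TRUE)
  r2 <- r1
  r2[151:200] <- sample(c("A", "C", "G", "T"), 50, TRUE)
  m2 <- as_msa(c(a = paste(r1, collapse = ""), b = paste(r2, collapse = "")),
               "dna")
  expect_gte(dist_nt(m2, "jc")["a", "b"], dist_p(m2)["a", "b"])

  # identical rows are 0 under every model
  same <- as_msa(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"), "dna")
  for (mod in c("p", "jc", "k2p_gamma")) {
    expect_equal(max(dist_nt(same, mod)), 0)
  }

  # saturated JC (p >= 3/4) reports d_max with a warning
  sat <- as_msa(c(a = "AAAACCCC", b = "CCCCAAAA"), "dna")
  expect_warning(ds <- dist_nt(sat, "jc", d_max = 10), "saturated")
  expect_equal(ds["a", "b"], 10)
})

test_that("ML JTT+Gamma distance: zero for identical pairs, Poisson limit", {
  m <- as_msa(c(a = "MKLVWYTRA", b = "MKLVWYTRA", c = "MKLVWYTRC"), "protein")
  d <- dist_ml_jtt(m)
  expect_equal(d["a", "b"], 0, tolerance = 1e-6)
  expect_gt(d["a", "c"], 0)

  # Poisson + equal-frequency limit (alpha -> Inf) equals the closed-form
  # 20-state correction -19/20 * log(1 - 20p/19)
  set.seed(11)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  s1 <- sample(aa, 500, TRUE)
  s2 <- s1; idx <- sample(500, 60)
  s2[idx] <- sample(aa, 60, TRUE)
  mp <- as_msa(c(a = paste(s1, collapse = ""), b = paste(s2, collapse = "")),
               "protein")
  p <- dist_p(mp)["a", "b"]
  closed <- -19 / 20 * log(1 - 20 * p / 19)
  est <- dist_ml_jtt(mp, gamma_alpha = Inf, model = "poisson")["a", "b"]
  expect_equal(est, closed, tolerance = 1e-3)
})

test_that("ML distances agree with an independent pairwise ML implementation", {
  skip_if_not_installed("phangorn")
  sim <- evolve_alignment(simulate_tree(5, seed = 3), 400, "protein",
                          base_rate = 0.3, seed = 3)
  d <- dist_ml_jtt(sim$msa)
  pd <- phangorn::phyDat(t(sapply(strsplit(unclass(sim$msa), ""), identity)),
                         type = "AA")
  ref <- as.matrix(phangorn::dist.ml(pd, model = "JTT", k = 4, shape = 1))
  expect_equal(unclass(d)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("estimators are permutation-equivariant and monotone in divergence", {
  set.seed(5)
  sim <- evolve_alignment(simulate_tree(6, seed = 5), 300, "protein",
                          base_rate = 0.25, seed = 5)
  d1 <- dist_ml_jtt(sim$msa)
  perm <- sample(names(sim$msa))
  d2 <- dist_ml_jtt(as_msa(unclass(sim$msa)[perm], "protein"))
  expect_equal(unclass(d2)[rownames(d1), colnames(d1)], unclass(d1),
               tolerance = 1e-12)

  # divergence ladder: ML estimates sort like the true distances
  tree2 <- ape::read.tree(text = "(a:0.05,(b:0.2,(c:0.45,d:0.75):0.1):0.1);")
  sim2 <- evolve_alignment(tree2, 2000, "protein", base_rate = 1, seed = 9)
  d <- dist_ml_jtt(sim2$msa)
  expect_equal(order(unclass(d)["a", c("b", "c", "d")]), 1:3)
})

test_that("standardization centers/scales the upper triangle and is affine-invariant", {
  m <- dist_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
                          dimnames = list(letters[1:3], letters[1:3])))
  z <- standardize_dist(m)
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  expect_equal(sort(z[upper.tri(z)]), c(-1, 0, 1))

  set.seed(13)
  v <- matrix(runif(49, 0.1, 2), 7); v <- (v + t(v)) / 2; diag(v) <- 0
  m2 <- dist_matrix(v, labels = paste0("s", 1:7))
  z2 <- standardize_dist(m2)
  ut <- z2[upper.tri(z2)]
  expect_equal(mean(ut), 0, tolerance = 1e-9)
  expect_equal(stats::sd(ut), 1, tolerance = 1e-9)

  # affine invariance: standardize(a*M + b) == standardize(M)
  m3 <- dist_matrix(3.7 * unclass(m2) + 0.9 - diag(0.9, 7),
                    labels = rownames(m2))
  z3 <- standardize_dist(m3)
  expect_equal(unclass(z3), unclass(z2), tolerance = 1e-9, ignore_attr = TRUE)

  const <- dist_matrix(matrix(1, 4, 4) - diag(4), labels = paste0("s", 1:4))
  expect_error(standardize_dist(const), "degenerate")
})

test_that("PHYLIP matrices round-trip and malformed files error", {
  set.seed(17)
  v <- matrix(runif(25), 5); v <- (v + t(v)) / 2; diag(v) <- 0
  m <- dist_matrix(v, labels = paste0("tax", 1:5))
  path <- withr::local_tempfile(fileext = ".phy")
  write_phylip_dist(m, path)
  back <- read_phylip_dist(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-10)

  # lower-triangular dialect symmetrizes
  lt <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("3", "a", "b 0.5", "c 0.25 0.75"), lt)
  mlt <- read_phylip_dist(lt)
  expect_equal(mlt["a", "b"], 0.5)
  expect_equal(mlt["b", "c"], 0.75)
  expect_equal(unclass(mlt), t(unclass(mlt)), ignore_attr = TRUE)

  badn <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("3", "a", "b 0.5", "c 0.2 0.3", "d 0.1 0.2 0.3"), badn)
  expect_error(read_phylip_dist(badn), "3 taxa")

  asym <- withr::local_tempfile(fileext = ".phy")
  writeLines(c("2", "a 0 0.5", "b 0.1 0"), asym)
  expect_error(read_phylip_dist(asym), "asymmetric")
})
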