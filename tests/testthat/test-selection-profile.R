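test_that("back-translation threads codons through the gapped alignment", {
  msa <- as_msa(c(a = "M-K", b = "MSK"), "protein")
  cds <- c(a = "ATGAAATAA", b = "ATGTCTAAA")  # a has terminal stop, b none
  aln <- backtranslate(msa, cds)
  expect_equal(unname(aln["a", ]), c("ATG", "---", "AAA"))
  expect_equal(unname(aln["b", ]), c("ATG", "TCT", "AAA"))
  # round trip: ungap + join reproduces the CDS minus terminal stop
  expect_equal(paste(aln["a", aln["a", ] != "---"], collapse = ""), "ATGAAA")

  expect_error(backtranslate(msa, c(a = "ATGAAATAA", b = "ATGTC")), "codon")
  expect_error(backtranslate(msa, c(a = "ATGAAATAA", b = "ATGAAATTTAAA")),
               "aligned residues")
  expect_error(
    backtranslate(as_msa(c(a = "MKK", b = "MSK"), "protein"),
                  c(a = "ATGTAAAAA", b = "ATGTCTAAA")),
    "internal stop")
})

test_that("NG86 site counts match enumeration for every sense codon", {
  # frozen hand-enumerated examples
  expect_equal(ng86_site_counts("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_equal(ng86_site_counts("ATG"), c(S = 0, N = 3))
  expect_equal(ng86_site_counts("TGG"), c(S = 0, N = 3))

  for (codon in SENSE_CODONS) {
    expect_equal(ng86_site_counts(codon), oracle_site_counts(codon),
                 info = codon)
  }
  # every position with at least one non-stop change contributes exactly 1,
  # so S + N <= 3, with equality whenever no position is stop-locked (true
  # for every sense codon of the bacterial code)
  for (codon in SENSE_CODONS) {
    cnt <- sum(ng86_site_counts(codon))
    expect_lte(cnt, 3 + 1e-12)
    expect_equal(cnt, 3, tolerance = 1e-12)
  }
  expect_error(ng86_site_counts("TAA"), "sense")
  expect_error(ng86_site_counts("TTN"), "sense")
})

test_that("codon pair differences average over stop-free mutation paths", {
  expect_equal(codon_pair_differences("TTT", "TTC"), c(Sd = 1, Nd = 0))
  expect_equal(codon_pair_differences("AAA", "AAA"), c(Sd = 0, Nd = 0))
  # two-difference pair: brute-force path enumeration oracle
  expect_equal(codon_pair_differences("GTT", "AGT"),
               oracle_pair_diffs("GTT", "AGT"))

  # symmetry and oracle agreement across random pairs with <= 2 differences
  set.seed(81)
  pairs <- 0
  while (pairs < 40) {
    c1 <- sample(SENSE_CODONS, 1); c2 <- sample(SENSE_CODONS, 1)
    nd <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (nd > 2) next
    pairs <- pairs + 1
    expect_equal(codon_pair_differences(c1, c2), oracle_pair_diffs(c1, c2),
                 info = paste(c1, c2))
    d12 <- codon_pair_differences(c1, c2)
    d21 <- codon_pair_differences(c2, c1)
    expect_equal(d12, d21, info = paste(c1, c2))
  }
})

test_that("per-site dN/dS pooling, sentinels and window smoothing", {
  # target identical to everyone: all values missing
  msa <- as_msa(c(t = "MKL", a = "MKL", b = "MKL"), "protein")
  cds <- c(t = "ATGAAACTT", a = "ATGAAACTT", b = "ATGAAACTT")
  aln <- backtranslate(msa, cds)
  prof <- site_dnds_profile(aln, "t")
  expect_true(all(is.na(prof$dnds)))

  # target differs only synonymously at column 3: value 0 there
  cds2 <- c(t = "ATGAAACTC", a = "ATGAAACTT", b = "ATGAAACTT")
  prof2 <- site_dnds_profile(backtranslate(msa, cds2), "t")
  expect_equal(prof2$dnds[3], 0)
  expect_true(all(is.na(prof2$dnds[1:2])))

  # nonsynonymous-only divergence: capped sentinel with flag
  msa3 <- as_msa(c(t = "MKL", a = "MRL", b = "MRL"), "protein")
  cds3 <- c(t = "ATGAAACTT", a = "ATGAGACTT", b = "ATGAGACTT")
  prof3 <- site_dnds_profile(backtranslate(msa3, cds3), "t", cap = 10)
  expect_equal(prof3$dnds[2], 10)
  expect_true(prof3$capped[2])

  # window = 3 equals an independent pooled-count recomputation
  set.seed(91)
  sim <- evolve_alignment(simulate_tree(4, seed = 7), 40, "protein",
                          base_rate = 0.4, seed = 7)
  aln4 <- backtranslate(sim$msa, sim$cds)
  w3 <- site_dnds_profile(aln4, "sp01", window = 3)
  counts <- pdscore:::pooled_site_counts(aln4, "sp01",
                                         Biostrings::getGeneticCode("11"))
  for (j in c(1, 5, 17, 40)) {
    win <- max(1, j - 1):min(40, j + 1)
    S <- sum(counts$S[win]); N <- sum(counts$N[win])
    Sd <- sum(counts$Sd[win]); Nd <- sum(counts$Nd[win])
    expected <- if (Sd == 0 && Nd == 0) NA_real_
      else if (Sd == 0) 10 else (Nd / N) / (Sd / S)
    expect_equal(w3$dnds[j], expected, info = paste("col", j))
  }
})

test_that("gene-average dN/dS agrees with a direct whole-gene oracle", {
  # identical sequences: missing
  msa <- as_msa(c(t = "MKL", a = "MKL"), "protein")
  cds <- c(t = "ATGAAACTT", a = "ATGAAACTT")
  expect_true(is.na(gene_average_dnds(backtranslate(msa, cds), "t")))

  # all-synonymous divergence: 0 (long enough that pS stays in the JC domain)
  msa2 <- as_msa(c(t = "MKLKL", a = "MKLKL"), "protein")
  cds2t <- c(t = "ATGAAACTCAAACTT", a = "ATGAAACTTAAACTT")
  expect_equal(gene_average_dnds(backtranslate(msa2, cds2t), "t"), 0)

  # random alignments vs an independently coded whole-gene NG86 oracle
  set.seed(101)
  sim <- evolve_alignment(simulate_tree(5, seed = 11), 60, "protein",
                          base_rate = 0.3, seed = 11)
  aln <- backtranslate(sim$msa, sim$cds)
  target <- "sp01"
  oracle <- local({
    others <- setdiff(rownames(aln), target)
    vals <- sapply(others, function(sp) {
      S <- N <- Sd <- Nd <- 0
      for (j in seq_len(ncol(aln))) {
        tc <- aln[target, j]; oc <- aln[sp, j]
        st <- oracle_site_counts(tc); so <- oracle_site_counts(oc)
        S <- S + (st[["S"]] + so[["S"]]) / 2
        N <- N + (st[["N"]] + so[["N"]]) / 2
        d <- oracle_pair_diffs(tc, oc)
        Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
      }
      pS <- Sd / S; pN <- Nd / N
      if (pS == 0 || pS >= 0.75 || pN >= 0.75) return(NA_real_)
      (-0.75 * log(1 - 4 * pN / 3)) / (-0.75 * log(1 - 4 * pS / 3))
    })
    mean(vals[!is.na(vals)])
  })
  expect_equal(suppressWarnings(gene_average_dnds(aln, target)), oracle,
               tolerance = 1e-10)
})

test_that("run detection reports maximal above-threshold stretches", {
  expect_equal(nrow(detect_runs(rep(1.5, 12))), 1)
  expect_equal(detect_runs(rep(1.5, 12))$end, 12)
  expect_equal(nrow(detect_runs(rep(1.5, 9))), 0)

  # a missing value splits 15 high sites into two sub-threshold fragments
  v <- rep(1.5, 15); v[8] <- NA
  expect_equal(nrow(detect_runs(v)), 0)

  # boundary: exactly threshold does not count; sentinel (cap) does
  v2 <- c(rep(1, 12))
  expect_equal(nrow(detect_runs(v2)), 0)
  v3 <- c(rep(10, 11))
  expect_equal(detect_runs(v3), tibble::tibble(start = 1L, end = 11L))
})

test_that("per-column divergence and site flagging follow the conventions", {
  msa <- as_msa(c(t = "MK-RV", a = "MKLRV", b = "MQLRV", e = "MQLKV",
                  r = "MKLSV"), "protein")
  div <- site_divergence_profile(msa, "t")
  expect_equal(div[1], 0)          # column identical everywhere
  expect_true(is.na(div[3]))       # target gap
  expect_equal(div[2], 0.5)        # 2 of 4 others differ
  expect_equal(div[4], 0.5)        # target R vs {R, R, K, S}: 2 of 4 differ
  expect_error(site_divergence_profile(msa, "zz"), "not in alignment")

  # target residue unique among 5 species
  u <- as_msa(c(t = "W", a = "A", b = "A", c = "A", d = "A"), "protein")
  expect_equal(site_divergence_profile(u, "t"), 1)

  # flagged sites must differ from the reference; ties break to lower index
  flags <- flag_top_deviating_sites(div, msa, "t", "r", k = 15)
  expect_true(all(flags %in% c(4)))  # only col 4 differs t vs r (both non-gap)
  expect_equal(flag_top_deviating_sites(div, msa, "t", "r", k = 0), integer(0))
  expect_error(flag_top_deviating_sites(div, msa, "t", "nope"), "not in alignment")
})
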