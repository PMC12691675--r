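# Independent oracles, written before and kept independent of the package
# implementations they check.

# --- silhouette / cluster-index oracles (plain double loops) ---------------

brute_silhouette <- function(xy, in_idx, out_idx) {
  eu <- function(i, j) sqrt(sum((xy[i, ] - xy[j, ])^2))
  s <- numeric(length(in_idx))
  for (a in seq_along(in_idx)) {
    i <- in_idx[a]
    h <- 0
    if (length(in_idx) > 1) {
      tot <- 0
      for (j in setdiff(in_idx, i)) tot <- tot + eu(i, j)
      h <- tot / (length(in_idx) - 1)
    }
    tot <- 0
    for (j in out_idx) tot <- tot + eu(i, j)
    f <- tot / length(out_idx)
    s[a] <- if (max(f, h) == 0) 0 else (f - h) / max(f, h)
  }
  list(s = s, pd = mean(s))
}

brute_chi <- function(xy, in_idx, out_idx) {
  g1 <- xy[in_idx, , drop = FALSE]; g2 <- xy[out_idx, , drop = FALSE]
  c1 <- colMeans(g1); c2 <- colMeans(g2); cc <- colMeans(xy)
  bss <- nrow(g1) * sum((c1 - cc)^2) + nrow(g2) * sum((c2 - cc)^2)
  wss <- 0
  for (i in seq_len(nrow(g1))) wss <- wss + sum((g1[i, ] - c1)^2)
  for (i in seq_len(nrow(g2))) wss <- wss + sum((g2[i, ] - c2)^2)
  if (wss == 0) return(if (bss == 0) 0 else Inf)
  (bss / 1) / (wss / (nrow(xy) - 2))
}

brute_dbi <- function(xy, in_idx, out_idx) {
  g1 <- xy[in_idx, , drop = FALSE]; g2 <- xy[out_idx, , drop = FALSE]
  c1 <- colMeans(g1); c2 <- colMeans(g2)
  s1 <- mean(apply(g1, 1, function(p) sqrt(sum((p - c1)^2))))
  s2 <- mean(apply(g2, 1, function(p) sqrt(sum((p - c2)^2))))
  sep <- sqrt(sum((c1 - c2)^2))
  if (sep == 0) return(Inf)
  (s1 + s2) / sep
}

# random distance space over n species (coordinates arbitrary; the score only
# sees the point cloud)
random_space <- function(n, sd = 1) {
  lab <- sprintf("t%02d", seq_len(n))
  pairs <- utils::combn(lab, 2)
  out <- tibble::tibble(a = pairs[1, ], b = pairs[2, ],
                        x = stats::rnorm(ncol(pairs), sd = sd),
                        y = stats::rnorm(ncol(pairs), sd = sd))
  structure(out, species = lab, class = c("distance_space", class(out)))
}

# --- NG86 oracles ----------------------------------------------------------

BACT_CODE <- Biostrings::getGeneticCode("11")

oracle_site_counts <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  aa <- BACT_CODE[[codon]]
  S <- N <- 0
  for (pos in 1:3) {
    muts <- setdiff(c("A", "C", "G", "T"), nts[pos])
    fates <- vapply(muts, function(nt) {
      m <- nts; m[pos] <- nt
      BACT_CODE[[paste(m, collapse = "")]]
    }, "")
    fates <- fates[fates != "*"]
    if (length(fates)) {
      S <- S + sum(fates == aa) / length(fates)
      N <- N + sum(fates != aa) / length(fates)
    }
  }
  c(S = S, N = N)
}

# exhaustive path enumeration between codons (recursive, not permutation-based)
oracle_pair_diffs <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  paths <- list()
  recurse <- function(cur, sd, nd, stopped) {
    pos <- which(cur != b)
    if (!length(pos)) {
      paths[[length(paths) + 1L]] <<- c(sd, nd, stopped)
      return(invisible())
    }
    for (p in pos) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- BACT_CODE[[paste(cur, collapse = "")]]
      aa2 <- BACT_CODE[[paste(nxt, collapse = "")]]
      hit_stop <- stopped || aa1 == "*" || aa2 == "*"
      if (aa1 == "*" || aa2 == "*") {
        recurse(nxt, sd, nd + 1, hit_stop)
      } else if (aa1 == aa2) {
        recurse(nxt, sd + 1, nd, hit_stop)
      } else {
        recurse(nxt, sd, nd + 1, hit_stop)
      }
    }
  }
  recurse(a, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  clean <- m[m[, 3] == 0, , drop = FALSE]
  use <- if (nrow(clean)) clean else m
  c(Sd = mean(use[, 1]), Nd = mean(use[, 2]))
}

SENSE_CODONS <- names(BACT_CODE)[BACT_CODE != "*"]

# --- run-detection oracle (linear scan) ------------------------------------

oracle_runs <- function(values, threshold = 1, min_len = 10) {
  above <- !is.na(values) & values > threshold
  runs <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(tibble::tibble(start = integer(0), end = integer(0)))
  m <- do.call(rbind, runs)
  tibble::tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
}

# --- tiny GenBank fixture builder ------------------------------------------

# genome: 16S at 11..40 (+), CDS1 "ATGAAATAA" at 41..49 (+),
# CDS2 = revcomp of "ATGTGTTGCTGA" placed at 61..72 on the minus strand
gb_fixture <- function(path, with_16s = TRUE, extra_cds = NULL) {
  rrna16 <- paste(rep(c("A", "C", "G", "T"), length.out = 30), collapse = "")
  cds1 <- "ATGAAATAA"
  cds2 <- "ATGTGTTGCTGA"   # M C C *
  genome <- paste0(strrep("G", 10), rrna16, cds1, strrep("A", 11),
                   pdscore::revcomp(cds2), strrep("T", 8))
  feat <- c(
    "FEATURES             Location/Qualifiers",
    "     source          1..90",
    if (with_16s) c(
      "     rRNA            11..40",
      "                     /locus_tag=\"FIX_r001\"",
      "                     /product=\"16S ribosomal RNA\""),
    "     CDS             41..49",
    "                     /locus_tag=\"FIX_0001\"",
    "                     /gene=\"aaa\"",
    "                     /translation=\"MK\"",
    "     CDS             complement(61..72)",
    "                     /locus_tag=\"FIX_0002\"",
    "                     /translation=\"MCC\"",
    extra_cds)
  seq_line <- paste0("        1 ", tolower(genome))
  writeLines(c(
    "LOCUS       FIXCONTIG1               90 bp    DNA     linear   BCT 01-JAN-2024",
    "DEFINITION  synthetic fixture genome.",
    feat,
    "ORIGIN",
    seq_line,
    "//"), path)
  invisible(list(genome = genome, rrna16 = rrna16, cds1 = cds1, cds2 = cds2))
}
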