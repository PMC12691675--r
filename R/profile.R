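#' Per-codon-site dN/dS of the target species against all others
#'
#' At each codon column, pairwise Nei-Gojobori counts (fractional site counts
#' averaged over the pair; path-averaged difference counts) of the target
#' versus every other species with a sense codon at that column are pooled,
#' optionally over a centered window of columns, and the ratio
#' `(Nd/N) / (Sd/S)` reported. A column is missing when no comparable pair
#' exists or no substitutions were observed; `Sd = 0` with `Nd > 0` yields an
#' infinite ratio reported as a capped sentinel with a flag.
#'
#' @param aln a [backtranslate()] codon alignment.
#' @param target target species label.
#' @param window odd window width in codons (default 1 = per-site).
#' @param cap sentinel value reported for infinite ratios (default 10).
#' @return tibble: `codon_column`, `dnds`, `capped`.
#' @export
site_dnds_profile <- function(aln, target, window = 1L, cap = 10) {
  stopifnot(inherits(aln, "codon_aln"))
  if (!target %in% rownames(aln)) {
    stop("target '", target, "' not in alignment", call. = FALSE)
  }
  if (window %% 2 != 1 || window < 1) stop("window must be odd", call. = FALSE)
  code <- Biostrings::getGeneticCode(attr(aln, "code_id"))
  counts <- pooled_site_counts(aln, target, code)
  nc <- ncol(aln)
  half <- (window - 1L) / 2L
  dnds <- rep(NA_real_, nc)
  capped <- rep(FALSE, nc)
  for (j in seq_len(nc)) {
    win <- max(1L, j - half):min(nc, j + half)
    S <- sum(counts$S[win]); N <- sum(counts$N[win])
    Sd <- sum(counts$Sd[win]); Nd <- sum(counts$Nd[win])
    if (S == 0 && N == 0) next            # no comparable pair in window
    if (Sd == 0 && Nd == 0) next          # no substitutions
    if (Sd == 0) {
      dnds[j] <- cap; capped[j] <- TRUE
    } else {
      dnds[j] <- (Nd / N) / (Sd / S)
    }
  }
  tibble::tibble(codon_column = seq_len(nc), dnds = dnds, capped = capped)
}

# per-column pooled NG86 counts of target vs all other species
pooled_site_counts <- function(aln, target, code) {
  site_tab <- ng86_site_table(code)
  others <- setdiff(rownames(aln), target)
  nc <- ncol(aln)
  S <- N <- Sd <- Nd <- numeric(nc)
  pair_cache <- new.env(parent = emptyenv())
  for (j in seq_len(nc)) {
    tc <- aln[target, j]
    if (!is_sense_codon(tc, code)) next
    for (sp in others) {
      oc <- aln[sp, j]
      if (!is_sense_codon(oc, code)) next
      S[j] <- S[j] + (site_tab[tc, "S"] + site_tab[oc, "S"]) / 2
      N[j] <- N[j] + (site_tab[tc, "N"] + site_tab[oc, "N"]) / 2
      if (tc != oc) {
        key <- paste(sort(c(tc, oc)), collapse = "")
        d <- pair_cache[[key]]
        if (is.null(d)) {
          d <- codon_pair_differences(tc, oc, code)
          pair_cache[[key]] <- d
        }
        Sd[j] <- Sd[j] + d[["Sd"]]
        Nd[j] <- Nd[j] + d[["Nd"]]
      }
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Gene-average dN/dS of the target against each other species
#'
#' For every non-target species, whole-gene Nei-Gojobori counts are pooled
#' over all codon columns, the proportions `pN = Nd/N` and `pS = Sd/S` are
#' Jukes-Cantor corrected (`d = -3/4 * log(1 - 4p/3)`), and the ratio
#' `dN/dS` formed. The gene average is the mean over species with a defined
#' ratio; species with `dS = 0` or a correction outside its domain
#' (`p >= 3/4`) are excluded with a warning. With `method = "pooled"` the
#' counts are pooled over species before forming one ratio instead.
#'
#' @inheritParams site_dnds_profile
#' @param method `"mean_of_ratios"` (default) or `"pooled"`.
#' @return a single number, or `NA` when no species has a defined ratio.
#' @export
gene_average_dnds <- function(aln, target,
                              method = c("mean_of_ratios", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(aln, "codon_aln"))
  if (!target %in% rownames(aln)) {
    stop("target '", target, "' not in alignment", call. = FALSE)
  }
  code <- Biostrings::getGeneticCode(attr(aln, "code_id"))
  site_tab <- ng86_site_table(code)
  others <- setdiff(rownames(aln), target)
  per_species <- lapply(others, function(sp) {
    S <- N <- Sd <- Nd <- 0
    for (j in seq_len(ncol(aln))) {
      tc <- aln[target, j]; oc <- aln[sp, j]
      if (!is_sense_codon(tc, code) || !is_sense_codon(oc, code)) next
      S <- S + (site_tab[tc, "S"] + site_tab[oc, "S"]) / 2
      N <- N + (site_tab[tc, "N"] + site_tab[oc, "N"]) / 2
      if (tc != oc) {
        d <- codon_pair_differences(tc, oc, code)
        Sd <- Sd + d[["Sd"]]; Nd <- Nd + d[["Nd"]]
      }
    }
    c(S = S, N = N, Sd = Sd, Nd = Nd)
  })
  m <- do.call(rbind, per_species)
  if (method == "pooled") m <- matrix(colSums(m), 1, dimnames = list(NULL, colnames(m)))
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  vals <- apply(m, 1, function(r) {
    if (r[["S"]] == 0 || r[["N"]] == 0) return(NA_real_)
    pS <- r[["Sd"]] / r[["S"]]; pN <- r[["Nd"]] / r[["N"]]
    if (pS == 0 && pN == 0) return(NA_real_)   # no substitutions at all
    if (pS >= 0.75 || pN >= 0.75) return(NaN)  # correction out of domain
    dS <- jc(pS); dN <- jc(pN)
    if (dS == 0) return(NaN)                   # ratio undefined
    dN / dS
  })
  if (any(is.nan(vals))) {
    warning(sum(is.nan(vals)),
            " species excluded (saturated correction or zero synonymous divergence)",
            call. = FALSE)
    vals <- vals[!is.nan(vals)]
  }
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  mean(vals)
}

#' Detect runs of elevated dN/dS
#'
#' Maximal intervals of consecutive columns whose values are non-missing and
#' strictly above the threshold, of length at least `min_len`. Capped
#' sentinel values count as above threshold (they are); missing values break
#' a run.
#'
#' @param values numeric vector of per-column values (`NA` = missing).
#' @param threshold run threshold (default 1, the neutral dN/dS ratio).
#' @param min_len minimum run length in columns (default 10).
#' @return tibble of `start`, `end` (1-based, inclusive).
#' @export
detect_runs <- function(values, threshold = 1, min_len = 10L) {
  above <- !is.na(values) & values > threshold
  if (!any(above)) {
    return(tibble::tibble(start = integer(0), end = integer(0)))
  }
  r <- rle(above)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  tibble::tibble(start = starts[keep], end = stops[keep])
}

#' Per-column amino-acid divergence of the target species
#'
#' For every alignment column where the target has a residue, the fraction of
#' other species whose symbol differs from the target's (gaps in others count
#' as differing). Columns where the target has a gap are missing.
#'
#' @param protein_msa an [as_msa()] protein alignment.
#' @param target target species label.
#' @return numeric vector, one value in \[0, 1\] (or `NA`) per column.
#' @export
site_divergence_profile <- function(protein_msa, target) {
  stopifnot(inherits(protein_msa, "msa"))
  m <- msa_matrix(protein_msa)
  if (!target %in% rownames(m)) {
    stop("target '", target, "' not in alignment", call. = FALSE)
  }
  tr <- m[target, ]
  others <- m[setdiff(rownames(m), target), , drop = FALSE]
  div <- colMeans(others != rep(tr, each = nrow(others)))
  div[tr %in% GAP_CHARS] <- NA_real_
  unname(div)
}

#' Flag the most deviating sites that also differ from a reference
#'
#' Among columns where the target residue differs from the reference residue
#' (both non-gap), returns the `k` columns of highest divergence, ties broken
#' by lower column index; all eligible columns when fewer than `k`.
#'
#' @param divergence a [site_divergence_profile()] vector.
#' @param protein_msa the protein alignment the profile came from.
#' @param target,reference species labels.
#' @param k number of sites to flag (default 15).
#' @return sorted integer vector of flagged column indices.
#' @export
flag_top_deviating_sites <- function(divergence, protein_msa, target, reference,
                                     k = 15L) {
  m <- msa_matrix(protein_msa)
  for (sp in c(target, reference)) {
    if (!sp %in% rownames(m)) stop("'", sp, "' not in alignment", call. = FALSE)
  }
  tr <- m[target, ]; rf <- m[reference, ]
  eligible <- which(tr != rf & !(tr %in% GAP_CHARS) & !(rf %in% GAP_CHARS))
  if (!length(eligible)) return(integer(0))
  ord <- eligible[order(-divergence[eligible], eligible)]
  sort(utils::head(ord, k))
}

#' Full per-gene selection profile
#'
#' Convenience wrapper: per-site dN/dS (with runs) plus per-column amino-acid
#' divergence (with flagged sites), joined into one tidy table.
#'
#' @inheritParams site_dnds_profile
#' @param protein_msa the aligned protein MSA the codon alignment came from.
#' @param reference reference species for site flagging (default none).
#' @param threshold,min_len run detection parameters.
#' @param k number of top deviating sites to flag.
#' @return list with `profile` (tibble: `codon_column`, `dnds`, `capped`,
#'   `divergence`, `in_run`, `flagged`), `runs` (tibble) and `mean_dnds`.
#' @export
selection_profile <- function(aln, protein_msa, target, reference = NULL,
                              window = 1L, cap = 10, threshold = 1,
                              min_len = 10L, k = 15L) {
  prof <- site_dnds_profile(aln, target, window = window, cap = cap)
  runs <- detect_runs(prof$dnds, threshold = threshold, min_len = min_len)
  div <- site_divergence_profile(protein_msa, target)
  prof$divergence <- div
  prof$in_run <- FALSE
  for (i in seq_len(nrow(runs))) {
    prof$in_run[runs$start[i]:runs$end[i]] <- TRUE
  }
  prof$flagged <- FALSE
  if (!is.null(reference)) {
    fl <- flag_top_deviating_sites(div, protein_msa, target, reference, k)
    prof$flagged[fl] <- TRUE
  }
  list(profile = prof,
       runs = runs,
       mean_dnds = suppressWarnings(gene_average_dnds(aln, target)))
}
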