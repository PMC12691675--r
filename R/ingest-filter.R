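#' CDS validity filter
#'
#' Applies the ingest validity rules to every CDS of a genome record, in
#' order: not a pseudogene; not partial; nucleotide sequence free of ambiguity
#' (A/C/G/T only); length divisible by 3; annotated translation starts with
#' methionine; and re-translating the CDS with the bacterial genetic code
#' (initiator codon rendered as M regardless of identity, one terminal stop
#' dropped) reproduces the annotated translation exactly. Each rejected
#' feature carries the first failing rule as its reason.
#'
#' @param record a [parse_genome_gb()] genome record.
#' @param code_id genetic code table id (default `"11"`, bacterial).
#' @return list with `kept` (tibble of surviving CDS rows) and `rejections`
#'   (tibble: `feature_id`, `reason`).
#' @export
filter_cds <- function(record, code_id = "11") {
  cds <- record$cds
  code <- Biostrings::getGeneticCode(code_id)
  reasons <- vapply(seq_len(nrow(cds)), function(i) {
    row <- cds[i, ]
    if (isTRUE(row$is_pseudo)) return("pseudogene")
    if (isTRUE(row$is_partial)) return("partial")
    nt <- row$nt_seq
    if (nchar(nt) == 0 || grepl("[^ACGT]", nt)) return("ambiguous")
    if (nchar(nt) %% 3 != 0) return("not_triplet")
    if (!startsWith(row$annotated_translation, "M")) return("non_methionine_start")
    aa <- translate_cds(nt, code)
    if (is.null(aa) || paste(aa, collapse = "") != row$annotated_translation) {
      return("translation_mismatch")
    }
    NA_character_
  }, "")
  list(
    kept = cds[is.na(reasons), , drop = FALSE],
    rejections = tibble::tibble(
      feature_id = cds$feature_id[!is.na(reasons)],
      reason = reasons[!is.na(reasons)]))
}

# translate a clean in-frame CDS: initiator forced to M, one terminal stop
# dropped; returns NULL if an internal stop is hit
translate_cds <- function(nt, code) {
  codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
  aa <- unname(code[codons])
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (!length(aa)) return(NULL)
  aa[1] <- "M"
  if (any(aa == "*")) return(NULL)
  aa
}

#' Choose a genome's representative 16S rRNA copy
#'
#' When a genome carries several 16S copies, the representative is the copy
#' with the least mean distance to all other sequences in the dataset-wide
#' pool (all copies from all genomes, the candidate itself excluded from its
#' own mean). Ties are broken by the lexicographically lowest `copy_id`, so
#' the choice is order-invariant.
#'
#' @param copies named character vector: this genome's 16S copies, named by
#'   `copy_id`.
#' @param pool named character vector: all 16S sequences in the dataset
#'   (should include `copies` under the same names).
#' @param dist_fun function(seq1, seq2) -> distance; the default is the
#'   proportion of mismatching positions and requires equal-length (aligned)
#'   sequences.
#' @return list with `copy_id` and `sequence`.
#' @export
select_representative_16s <- function(copies, pool, dist_fun = NULL) {
  if (!length(copies)) stop("no 16S", call. = FALSE)
  if (is.null(names(copies)) || any(names(copies) == "")) {
    stop("copies must be named by copy_id", call. = FALSE)
  }
  if (length(copies) == 1L) {
    return(list(copy_id = names(copies), sequence = unname(copies)))
  }
  if (is.null(dist_fun)) dist_fun <- hamming_frac
  mean_dist <- vapply(names(copies), function(id) {
    others <- pool[names(pool) != id]
    if (!length(others)) stop("pool holds no other sequences", call. = FALSE)
    mean(vapply(others, function(o) dist_fun(o, copies[[id]]), 0))
  }, 0)
  ord <- order(mean_dist, names(copies))
  best <- ord[1]
  list(copy_id = names(copies)[best], sequence = unname(copies[[best]]))
}

hamming_frac <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) {
    stop("default 16S distance needs equal-length sequences; supply dist_fun",
         call. = FALSE)
  }
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  mean(a != b)
}

#' Write per-genome ingest outputs
#'
#' Protein FASTA, CDS FASTA and 16S FASTA for the kept features, plus a TSV
#' rejection log (`species_id`, `feature_id`, `reason`).
#'
#' @param record a genome record.
#' @param filtered result of [filter_cds()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_genome_outputs <- function(record, filtered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kept <- filtered$kept
  prot <- stats::setNames(kept$annotated_translation, kept$feature_id)
  cdss <- stats::setNames(kept$nt_seq, kept$feature_id)
  write_fasta(prot, file.path(dir, paste0(record$species_id, ".faa")))
  write_fasta(cdss, file.path(dir, paste0(record$species_id, ".fna")))
  if (nrow(record$rrna_16s)) {
    write_fasta(stats::setNames(record$rrna_16s$sequence, record$rrna_16s$copy_id),
                file.path(dir, paste0(record$species_id, ".16S.fna")))
  }
  readr::write_tsv(
    tibble::tibble(species_id = record$species_id,
                   feature_id = filtered$rejections$feature_id,
                   reason = filtered$rejections$reason),
    file.path(dir, paste0(record$species_id, ".rejections.tsv")))
  invisible(dir)
}
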