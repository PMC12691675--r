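#' Parse a 12-column tabular protein homology hit file
#'
#' The standard tab-separated alignment output dialect: query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, e-value, bitscore. Scientific-notation e-values are parsed.
#'
#' @param path hit file.
#' @return tibble with one row per hit: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `mismatches`, `gap_opens`, `qstart`,
#'   `qend`, `sstart`, `send`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1]
    stop(sprintf("line %d of %s has %d columns (expected 12)", bad, path, nf[bad]),
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric %s on line %d of %s", what, which(is.na(v))[1], path),
           call. = FALSE)
    }
    v
  }
  out <- tibble::tibble(
    query_id = m[, 1], subject_id = m[, 2],
    pct_identity = num(3, "percent identity"),
    aln_length = num(4, "alignment length"),
    mismatches = num(5, "mismatch count"),
    gap_opens = num(6, "gap-open count"),
    qstart = num(7, "qstart"), qend = num(8, "qend"),
    sstart = num(9, "sstart"), send = num(10, "send"),
    evalue = num(11, "e-value"), bitscore = num(12, "bitscore"))
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("percent identity outside [0, 100] in ", path, call. = FALSE)
  }
  if (any(out$evalue < 0)) stop("negative e-value in ", path, call. = FALSE)
  out
}

#' Assemble one-per-species ortholog groups from homology hits
#'
#' Discards hits failing the e-value or identity threshold, then keeps, for
#' every (species, reference gene) combination, the single best surviving hit
#' — highest bitscore, ties broken by lower e-value, then lexicographic
#' `query_id`. Every reference gene with at least one member becomes a group.
#' The species is parsed from the query id prefix (`species|protein` by
#' default).
#'
#' @param hits a [read_hit_table()] tibble.
#' @param evalue_max e-value cutoff (default 1e-5).
#' @param identity_min minimum percent identity (default 30).
#' @param delim delimiter separating species from protein in `query_id`.
#' @return tibble of group members: `group_id` (reference gene),
#'   `species_id`, `feature_id`, `pct_identity`, `evalue`, `bitscore`,
#'   sorted by group then species.
#' @export
build_ortholog_groups <- function(hits, evalue_max = 1e-5, identity_min = 30,
                                  delim = "|") {
  stopifnot(is.data.frame(hits))
  pos <- regexpr(delim, hits$query_id, fixed = TRUE)
  if (any(pos < 1)) {
    bad <- hits$query_id[pos < 1][1]
    stop("query_id '", bad, "' has no '", delim, "' species prefix", call. = FALSE)
  }
  hits |>
    dplyr::mutate(
      species_id = substr(.data$query_id, 1L, pos - 1L),
      feature_id = substr(.data$query_id, pos + nchar(delim), nchar(.data$query_id))) |>
    dplyr::filter(.data$evalue <= evalue_max, .data$pct_identity >= identity_min) |>
    dplyr::group_by(group_id = .data$subject_id, .data$species_id) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .data$evalue, .data$query_id,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::select("group_id", "species_id", "feature_id",
                  "pct_identity", "evalue", "bitscore") |>
    dplyr::arrange(.data$group_id, .data$species_id)
}

#' Keep groups usable for PD scoring of a target species
#'
#' Retains groups that contain the target species and at least `min_species`
#' members (the score needs several non-target species to define both the
#' in-cluster scale and the background cloud).
#'
#' @param groups a [build_ortholog_groups()] tibble.
#' @param target_species target species id.
#' @param min_species minimum member count (default 4).
#' @return the filtered tibble, sorted by `group_id`.
#' @export
filter_ortholog_groups <- function(groups, target_species, min_species = 4L) {
  if (!nrow(groups)) return(groups)
  groups |>
    dplyr::group_by(.data$group_id) |>
    dplyr::filter(any(.data$species_id == target_species),
                  dplyr::n() >= min_species) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group_id, .data$species_id)
}

#' Write per-group FASTA inputs and a membership table
#'
#' For every group, writes the member protein FASTA (`<group_id>.faa`) and
#' CDS FASTA (`<group_id>.fna`) — unaligned, ready for an external aligner —
#' plus a single `groups.tsv` membership log.
#'
#' @param groups a group membership tibble.
#' @param proteins named character vector (or function(species_id,
#'   feature_id)) resolving protein sequences by `species_id|feature_id`.
#' @param cds same, for CDS sequences.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_group_fastas <- function(groups, proteins, cds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lookup <- function(src, sp, ft) {
    if (is.function(src)) return(src(sp, ft))
    src[[paste0(sp, "|", ft)]]
  }
  for (gid in unique(groups$group_id)) {
    g <- groups[groups$group_id == gid, ]
    aa <- stats::setNames(
      vapply(seq_len(nrow(g)),
             function(i) lookup(proteins, g$species_id[i], g$feature_id[i]), ""),
      g$species_id)
    nt <- stats::setNames(
      vapply(seq_len(nrow(g)),
             function(i) lookup(cds, g$species_id[i], g$feature_id[i]), ""),
      g$species_id)
    write_fasta(aa, file.path(dir, paste0(gid, ".faa")))
    write_fasta(nt, file.path(dir, paste0(gid, ".fna")))
  }
  readr::write_tsv(groups, file.path(dir, "groups.tsv"))
  invisible(dir)
}
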