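#' Parse a GenBank flat file into a genome record
#'
#' Reads a (possibly multi-record) GenBank flat file and captures every CDS
#' and rRNA feature. Multi-contig files are merged into one genome under a
#' single `species_id`. Minus-strand CDS nucleotide sequences are
#' reverse-complemented to the coding strand; 16S copies are identified by an
#' rRNA `product` qualifier containing "16S". A CDS without a `translation`
#' qualifier is captured with an empty `annotated_translation` and left to the
#' validity filter.
#'
#' @param path GenBank flat file.
#' @param species_id genome label; defaults to the first LOCUS name.
#' @return a `genome_record`: list with `species_id`, `cds` (tibble:
#'   `feature_id`, `gene_name`, `nt_seq`, `annotated_translation`,
#'   `is_pseudo`, `is_partial`, `contig`) and `rrna_16s` (tibble: `copy_id`,
#'   `sequence`).
#' @export
parse_genome_gb <- function(path, species_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  starts <- which(startsWith(lines, "LOCUS"))
  ends <- which(trimws(lines) == "//")
  if (length(ends) < length(starts)) {
    stop("truncated GenBank file (record '",
         sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[starts[length(ends) + 1L]]),
         "' lacks a terminating //): ", path, call. = FALSE)
  }
  cds_list <- list()
  rrna_list <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    locus <- sub("^LOCUS\\s+(\\S+).*$", "\\1", block[1])
    parsed <- parse_gb_record(block, locus, path)
    cds_list[[r]] <- parsed$cds
    rrna_list[[r]] <- parsed$rrna
  }
  cds <- dplyr::bind_rows(cds_list)
  rrna <- dplyr::bind_rows(rrna_list)
  if (is.null(species_id)) {
    species_id <- sub("^LOCUS\\s+(\\S+).*$", "\\1", lines[starts[1]])
  }
  structure(list(species_id = species_id, cds = cds, rrna_16s = rrna),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d CDS, %d 16S copies\n",
              x$species_id, nrow(x$cds), nrow(x$rrna_16s)))
  invisible(x)
}

parse_gb_record <- function(block, locus, path) {
  fstart <- which(startsWith(block, "FEATURES"))
  ostart <- which(startsWith(block, "ORIGIN"))
  if (!length(ostart)) {
    stop("record '", locus, "' in ", path, " has no ORIGIN sequence", call. = FALSE)
  }
  seq_lines <- block[(ostart[1] + 1L):(length(block) - 1L)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  empty <- list(cds = NULL, rrna = NULL)
  if (!length(fstart)) return(empty)
  feat_lines <- block[(fstart[1] + 1L):(ostart[1] - 1L)]
  # feature keys start at column 6; qualifier/location continuations at column 22
  is_key <- grepl("^ {5}\\S", feat_lines)
  key_idx <- which(is_key)
  cds <- list(); rrna <- list(); n16 <- 0L
  for (fi in seq_along(key_idx)) {
    from <- key_idx[fi]
    to <- if (fi < length(key_idx)) key_idx[fi + 1L] - 1L else length(feat_lines)
    chunk <- feat_lines[from:to]
    key <- sub("^ {5}(\\S+).*$", "\\1", chunk[1])
    if (!key %in% c("CDS", "rRNA")) next
    feat <- parse_gb_feature(chunk, genome_seq, locus)
    if (key == "CDS") {
      cds[[length(cds) + 1L]] <- tibble::tibble(
        feature_id = feat$quals[["locus_tag"]] %||%
          sprintf("%s_cds%03d", locus, length(cds) + 1L),
        gene_name = feat$quals[["gene"]] %||% NA_character_,
        nt_seq = feat$seq,
        annotated_translation = gsub("\\s", "", feat$quals[["translation"]] %||% ""),
        is_pseudo = feat$is_pseudo,
        is_partial = feat$is_partial,
        contig = locus)
    } else {
      product <- feat$quals[["product"]] %||% ""
      if (grepl("16S", product, fixed = TRUE)) {
        n16 <- n16 + 1L
        rrna[[length(rrna) + 1L]] <- tibble::tibble(
          copy_id = feat$quals[["locus_tag"]] %||% sprintf("%s_16S_%02d", locus, n16),
          sequence = feat$seq)
      }
    }
  }
  list(cds = dplyr::bind_rows(cds), rrna = dplyr::bind_rows(rrna))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_gb_feature <- function(chunk, genome_seq, locus) {
  first_qual <- which(grepl("^ {21}/", chunk))[1]
  loc_end <- if (is.na(first_qual)) length(chunk) else first_qual - 1L
  location <- gsub("\\s", "", paste(c(
    sub("^ {5}\\S+\\s+", "", chunk[1]),
    trimws(chunk[seq_len(loc_end)[-1]])), collapse = ""))
  quals <- parse_gb_qualifiers(chunk[seq_along(chunk) >= first_qual & !is.na(first_qual)])
  loc <- parse_gb_location(location, locus)
  pieces <- vapply(seq_len(nrow(loc$spans)), function(i) {
    if (loc$spans[i, 2] > nchar(genome_seq)) {
      stop("feature location ", location, " exceeds sequence length in record '",
           locus, "'", call. = FALSE)
    }
    substr(genome_seq, loc$spans[i, 1], loc$spans[i, 2])
  }, "")
  s <- paste(pieces, collapse = "")
  if (loc$complement) s <- revcomp(s)
  list(seq = s, quals = quals,
       is_pseudo = "pseudo" %in% names(quals) || "pseudogene" %in% names(quals),
       is_partial = loc$partial)
}

parse_gb_qualifiers <- function(lines) {
  if (!length(lines)) return(list())
  starts <- grepl("^ {21}/", lines)
  grp <- cumsum(starts)
  quals <- list()
  for (g in unique(grp[starts])) {
    txt <- paste(trimws(lines[grp == g]), collapse = "")
    m <- regmatches(txt, regexec('^/([A-Za-z_0-9]+)(=(.*))?$', txt))[[1]]
    key <- m[2]
    val <- if (m[3] == "") TRUE else gsub('^"|"$', "", m[4])
    quals[[key]] <- val
  }
  quals
}

parse_gb_location <- function(loc, locus) {
  partial <- grepl("[<>]", loc)
  loc2 <- gsub("[<>]", "", loc)
  complement <- FALSE
  if (startsWith(loc2, "complement(")) {
    complement <- TRUE
    loc2 <- sub("^complement\\((.*)\\)$", "\\1", loc2)
  }
  if (startsWith(loc2, "join(") || startsWith(loc2, "order(")) {
    loc2 <- sub("^(join|order)\\((.*)\\)$", "\\2", loc2)
  }
  parts <- strsplit(loc2, ",", fixed = TRUE)[[1]]
  spans <- t(vapply(parts, function(p) {
    inner_comp <- startsWith(p, "complement(")
    if (inner_comp) p <- sub("^complement\\((.*)\\)$", "\\1", p)
    nums <- suppressWarnings(as.numeric(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums)) {
      stop("unparsable location '", p, "' in record '", locus, "'", call. = FALSE)
    }
    nums
  }, numeric(2)))
  list(spans = spans, complement = complement, partial = partial)
}

#' Reverse complement of a DNA string
#' @param x DNA string (IUPAC symbols allowed).
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
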