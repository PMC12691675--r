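#' Multiple sequence alignment container
#'
#' An `msa` is a named character vector of equal-length (gapped) sequences with
#' an `alphabet` attribute (`"protein"` or `"dna"`). It is the common currency
#' between the distance engine, the dN/dS profiler and the simulator.
#'
#' @param x named character vector of aligned sequences, one per species.
#' @param alphabet `"protein"` or `"dna"`.
#' @return an object of class `msa`.
#' @examples
#' as_msa(c(spA = "MKL-", spB = "MKLV"), "protein")
#' @export
as_msa <- function(x, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop("alignment rows must be named by species", call. = FALSE)
  }
  if (anyDuplicated(names(x))) {
    stop("duplicated species labels: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "),
         call. = FALSE)
  }
  x <- stats::setNames(toupper(as.character(x)), names(x))
  if (length(unique(nchar(x))) > 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  structure(x, alphabet = alphabet, class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d x %d (%s)\n", length(x), nchar(x[1]), attr(x, "alphabet")))
  shown <- utils::head(x, 6)
  for (nm in names(shown)) {
    s <- shown[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, substr(s, 1, 60),
                if (nchar(s) > 60) "..." else ""))
  }
  if (length(x) > 6) cat(sprintf("  ... %d more rows\n", length(x) - 6L))
  invisible(x)
}

#' Read/write aligned FASTA as an `msa`
#'
#' Thin wrappers over [Biostrings::readAAStringSet()] /
#' [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA file path.
#' @param alphabet `"protein"` or `"dna"`.
#' @return `read_fasta_msa()` an `msa`; `write_fasta()` the path, invisibly.
#' @export
read_fasta_msa <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  set <- if (alphabet == "protein") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  seqs <- as.character(set)
  # keep only the first whitespace-delimited token of each FASTA header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_msa(seqs, alphabet)
}

#' @param x named character vector of sequences (need not be aligned).
#' @rdname read_fasta_msa
#' @export
write_fasta <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(x)) {
    writeLines(c(paste0(">", nm), x[[nm]]), con)
  }
  invisible(path)
}

# character matrix view (rows = species, cols = alignment columns)
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

GAP_CHARS <- c("-", ".")
PROTEIN_AA <- c("A","R","N","D","C","Q","E","G","H","I",
                "L","K","M","F","P","S","T","W","Y","V")
DNA_NT <- c("A", "C", "G", "T")
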