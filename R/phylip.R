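#' Read / write PHYLIP distance matrices
#'
#' `read_phylip_dist()` accepts both the square and the lower-triangular
#' dialect (first line N, then one row per taxon: name, whitespace, values);
#' lower-triangular input is symmetrized. `write_phylip_dist()` writes the
#' square dialect with enough digits for a 1e-10 round trip.
#'
#' @param path file path.
#' @return `read_phylip_dist()` a [dist_matrix()]; `write_phylip_dist()` the
#'   path, invisibly.
#' @export
read_phylip_dist <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("bad taxon count header in ", path, call. = FALSE)
  rows <- lines[-1]
  if (length(rows) != n) {
    stop(sprintf("header says %d taxa but file has %d rows", n, length(rows)),
         call. = FALSE)
  }
  fields <- strsplit(trimws(rows), "\\s+")
  labels <- vapply(fields, `[[`, "", 1L)
  nvals <- lengths(fields) - 1L
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  if (all(nvals == n)) {                       # square
    for (i in seq_len(n)) {
      m[i, ] <- as.numeric(fields[[i]][-1])
    }
    if (any(abs(m - t(m)) > 1e-6)) {
      stop("square matrix in ", path, " is asymmetric beyond 1e-6", call. = FALSE)
    }
  } else if (all(nvals == seq_len(n) - 1L)) {  # lower triangular
    for (i in seq_len(n)[-1]) {
      vals <- as.numeric(fields[[i]][-1])
      m[i, seq_len(i - 1L)] <- vals
      m[seq_len(i - 1L), i] <- vals
    }
  } else {
    bad <- which(nvals != n & nvals != seq_len(n) - 1L)[1]
    stop(sprintf("row %d ('%s') has %d values; expected %d (square) or %d (lower-triangular)",
                 bad, labels[bad], nvals[bad], n, bad - 1L), call. = FALSE)
  }
  if (anyNA(m)) stop("non-numeric distance values in ", path, call. = FALSE)
  dist_matrix(m)
}

#' @param m a [dist_matrix()].
#' @rdname read_phylip_dist
#' @export
write_phylip_dist <- function(m, path) {
  stopifnot(is.matrix(m))
  n <- nrow(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  for (i in seq_len(n)) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.12e", unclass(m)[i, ])),
                     collapse = "  "), con)
  }
  invisible(path)
}

#' Write a distance matrix in long (tidy) form
#'
#' One row per unordered species pair: columns `a`, `b`, `distance`.
#'
#' @param m a [dist_matrix()].
#' @param path optional TSV path; when `NULL` only the tibble is returned.
#' @return a tibble, invisibly when written.
#' @export
dist_to_long <- function(m, path = NULL) {
  lab <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(a = lab[idx[, 1]], b = lab[idx[, 2]],
                        distance = unclass(m)[idx])
  out <- dplyr::arrange(out, .data$a, .data$b)
  if (!is.null(path)) {
    readr::write_tsv(out, path)
    return(invisible(out))
  }
  out
}
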