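# NG86-style fractional site counting and path-averaged codon differences.

codon_split <- function(codon) strsplit(codon, "", fixed = TRUE)[[1]]

is_sense_codon <- function(codon, code) {
  nchar(codon) == 3 && !grepl("[^ACGT]", codon) && !is.na(code[codon]) &&
    code[[codon]] != "*"
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Nei-Gojobori fractional site counts: at each of the three positions, the
#' single-nucleotide changes that do not create a stop codon are classified
#' as synonymous or nonsynonymous, and the position contributes the
#' synonymous fraction to S and the rest to N. A position whose three changes
#' all create stops contributes nothing.
#'
#' @param codon a sense codon (3 of A/C/G/T, not a stop).
#' @param code genetic code as a named character vector
#'   ([Biostrings::getGeneticCode()]); default bacterial (table 11).
#' @return named numeric vector `c(S = ..., N = ...)`, with `S + N <= 3`.
#' @examples
#' ng86_site_counts("TTT")  # S = 1/3, N = 8/3
#' @export
ng86_site_counts <- function(codon, code = Biostrings::getGeneticCode("11")) {
  if (!is_sense_codon(codon, code)) {
    stop("'", codon, "' is not a sense codon", call. = FALSE)
  }
  aa <- code[[codon]]
  nts <- codon_split(codon)
  S <- 0; N <- 0
  for (pos in 1:3) {
    syn <- 0L; tot <- 0L
    for (nt in setdiff(c("A", "C", "G", "T"), nts[pos])) {
      mut <- nts; mut[pos] <- nt
      mut_aa <- code[[paste(mut, collapse = "")]]
      if (mut_aa == "*") next
      tot <- tot + 1L
      if (mut_aa == aa) syn <- syn + 1L
    }
    if (tot > 0) {
      S <- S + syn / tot
      N <- N + (tot - syn) / tot
    }
  }
  c(S = S, N = N)
}

# site counts for all sense codons, memoized per code
ng86_site_table <- local({
  cache <- new.env(parent = emptyenv())
  function(code) {
    key <- paste(code, collapse = "")
    if (is.null(cache[[key]])) {
      codons <- names(code)[code != "*"]
      tab <- t(vapply(codons, ng86_site_counts, c(S = 0, N = 0), code = code))
      cache[[key]] <- tab
    }
    cache[[key]]
  }
})

#' Path-averaged synonymous/nonsynonymous differences between two codons
#'
#' Codons differing at q positions are connected by q! orderings of the
#' single-nucleotide steps; each step is synonymous or nonsynonymous and the
#' counts are averaged over orderings. Orderings passing through a stop codon
#' are excluded; if every ordering passes through a stop, the counts fall
#' back to averaging over all orderings with stop-passing steps classified as
#' nonsynonymous.
#'
#' @param c1,c2 sense codons.
#' @inheritParams ng86_site_counts
#' @return named numeric vector `c(Sd = ..., Nd = ...)`.
#' @examples
#' codon_pair_differences("TTT", "TTC")  # c(Sd = 1, Nd = 0)
#' @export
codon_pair_differences <- function(c1, c2, code = Biostrings::getGeneticCode("11")) {
  if (!is_sense_codon(c1, code)) stop("'", c1, "' is not a sense codon", call. = FALSE)
  if (!is_sense_codon(c2, code)) stop("'", c2, "' is not a sense codon", call. = FALSE)
  a <- codon_split(c1); b <- codon_split(c2)
  diff_pos <- which(a != b)
  q <- length(diff_pos)
  if (q == 0L) return(c(Sd = 0, Nd = 0))
  orderings <- all_permutations(diff_pos)
  walk <- function(order, count_stops_as_nonsyn) {
    cur <- a; Sd <- 0; Nd <- 0
    for (pos in order) {
      prev_aa <- code[[paste(cur, collapse = "")]]
      cur[pos] <- b[pos]
      cur_aa <- code[[paste(cur, collapse = "")]]
      if (cur_aa == "*" || prev_aa == "*") {
        if (!count_stops_as_nonsyn) return(NULL)
        Nd <- Nd + 1
      } else if (cur_aa == prev_aa) {
        Sd <- Sd + 1
      } else {
        Nd <- Nd + 1
      }
    }
    c(Sd, Nd)
  }
  res <- lapply(orderings, walk, count_stops_as_nonsyn = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) {
    res <- lapply(orderings, walk, count_stops_as_nonsyn = TRUE)
  }
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' Thread a protein alignment back onto its coding sequences
#'
#' Replaces every aligned residue by its source codon (gap columns become
#' `"---"`), producing a codon alignment in which ungapping a row and
#' concatenating reproduces that species' CDS minus the terminal stop.
#'
#' @param protein_msa an [as_msa()] protein alignment.
#' @param cds named character vector of unaligned CDS, one per alignment row.
#' @param code_id genetic code table id (default `"11"`).
#' @return a `codon_aln`: character matrix (species x codon columns) of
#'   3-character strings, with the code id as attribute.
#' @export
backtranslate <- function(protein_msa, cds, code_id = "11") {
  stopifnot(inherits(protein_msa, "msa"), attr(protein_msa, "alphabet") == "protein")
  code <- Biostrings::getGeneticCode(code_id)
  pm <- msa_matrix(protein_msa)
  ncol_aln <- ncol(pm)
  out <- matrix("---", nrow(pm), ncol_aln, dimnames = list(rownames(pm), NULL))
  for (sp in rownames(pm)) {
    if (is.null(cds[[sp]])) stop("no CDS for species ", sp, call. = FALSE)
    nt <- toupper(cds[[sp]])
    res_cols <- which(!pm[sp, ] %in% GAP_CHARS)
    n_res <- length(res_cols)
    nt_use <- nt
    if (nchar(nt) %% 3 != 0) {
      stop(sprintf("CDS of %s has length %d, not a codon multiple", sp, nchar(nt)),
           call. = FALSE)
    }
    n_codons <- nchar(nt) / 3
    last <- substr(nt, nchar(nt) - 2, nchar(nt))
    if (n_codons == n_res + 1 && !is.na(code[last]) && code[[last]] == "*") {
      nt_use <- substr(nt, 1, nchar(nt) - 3)
      n_codons <- n_codons - 1
    }
    if (n_codons != n_res) {
      stop(sprintf("%s: %d aligned residues but %d codons (CDS length %d)",
                   sp, n_res, n_codons, nchar(nt)), call. = FALSE)
    }
    codons <- substring(nt_use, seq(1, nchar(nt_use), 3), seq(3, nchar(nt_use), 3))
    internal <- !grepl("[^ACGT]", codons) & !is.na(code[codons]) & code[codons] == "*"
    if (any(internal)) {
      stop(sprintf("internal stop codon in threaded frame of %s (codon %d)",
                   sp, which(internal)[1]), call. = FALSE)
    }
    out[sp, res_cols] <- codons
  }
  structure(out, code_id = code_id, class = c("codon_aln", "matrix", "array"))
}
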