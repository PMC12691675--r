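# Synthetic benchmark: Yule species tree, 16S-like alignment, background gene
# families, and "specialized" families whose target terminal branch evolves at
# an accelerated rate — with truth labels, so the whole pipeline is testable
# without any downloads.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# small deterministic string hash, kept below 2^31
hash31 <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Rooted ultrametric binary tree with exponential waiting times
#' ([ape::rphylo()] with death rate 0); tips are labeled `sp01`, `sp02`, ...
#' Identical seeds give identical trees.
#'
#' @param n_species number of tips (>= 2).
#' @param birth_rate speciation rate (default 1).
#' @param seed RNG seed.
#' @return an [ape::phylo] tree with branch lengths.
#' @export
simulate_tree <- function(n_species, birth_rate = 1, seed = 1L) {
  if (n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  tree <- with_seed(seed, ape::rphylo(n_species, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Evolve an alignment along a tree
#'
#' Continuous-time Markov simulation: the root sequence is drawn from the
#' equilibrium frequencies and every branch evolves sites independently —
#' Jukes-Cantor for DNA, an equal-exchangeability model with JTT equilibrium
#' frequencies for protein. Branch lengths are scaled by `base_rate`
#' (expected substitutions/site/unit length) and, optionally, per-tip
#' terminal-branch multipliers (the lineage-specific acceleration knob). In
#' protein mode a consistent CDS is co-generated by sampling synonymous
#' codons uniformly per residue, with a terminal stop appended.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param length sites (DNA) or residues (protein).
#' @param alphabet `"dna"` or `"protein"`.
#' @param base_rate substitutions per site per unit branch length.
#' @param tip_multipliers optional named positive numeric vector: rate
#'   multipliers applied to the named tips' terminal branches.
#' @param seed RNG seed; identical seeds give identical alignments.
#' @param code_id genetic code for CDS co-generation.
#' @return list with `msa` (an [as_msa()] alignment over the tips) and `cds`
#'   (named character vector, protein mode only; otherwise `NULL`).
#' @export
evolve_alignment <- function(tree, length, alphabet = c("dna", "protein"),
                             base_rate = 0.1, tip_multipliers = NULL,
                             seed = 1L, code_id = "11") {
  alphabet <- match.arg(alphabet)
  stopifnot(length >= 1, base_rate >= 0)
  if (!is.null(tip_multipliers)) {
    if (any(tip_multipliers <= 0)) stop("multipliers must be positive", call. = FALSE)
    missing <- setdiff(names(tip_multipliers), tree$tip.label)
    if (length(missing)) stop("unknown tips: ", paste(missing, collapse = ", "),
                              call. = FALSE)
  }
  freq <- if (alphabet == "dna") stats::setNames(rep(0.25, 4), DNA_NT) else JTT_FREQ
  symbols <- names(freq)
  beta <- 1 / (1 - sum(freq^2))   # so branch length = expected subs/site
  tr <- stats::reorder(tree, "cladewise")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tr$Nnode
  with_seed(seed, {
    states <- matrix(0L, nnode, length)
    states[root, ] <- sample.int(length(freq), length, replace = TRUE, prob = freq)
    for (k in seq_len(nrow(tr$edge))) {
      par <- tr$edge[k, 1]; child <- tr$edge[k, 2]
      mult <- 1
      if (!is.null(tip_multipliers) && child <= ntip) {
        m <- tip_multipliers[tr$tip.label[child]]
        if (!is.na(m)) mult <- m
      }
      t <- base_rate * tr$edge.length[k] * mult
      p_event <- 1 - exp(-beta * t)
      s <- states[par, ]
      hit <- stats::runif(length) < p_event
      if (any(hit)) {
        s[hit] <- sample.int(length(freq), sum(hit), replace = TRUE, prob = freq)
      }
      states[child, ] <- s
    }
    leaf_seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1,
                       function(r) paste(symbols[r], collapse = ""))
    names(leaf_seqs) <- tr$tip.label
    msa <- as_msa(leaf_seqs, alphabet)
    cds <- NULL
    if (alphabet == "protein") {
      code <- Biostrings::getGeneticCode(code_id)
      syn <- split(names(code), code)
      stops <- syn[["*"]]
      cds <- vapply(seq_len(ntip), function(i) {
        aas <- symbols[states[i, ]]
        codons <- vapply(aas, function(a) {
          opts <- syn[[a]]
          opts[sample.int(length(opts), 1L)]
        }, "")
        paste(c(codons, stops[1]), collapse = "")
      }, "")
      names(cds) <- tr$tip.label
    }
    list(msa = msa, cds = cds)
  })
}

#' Benchmark configuration
#'
#' Defaults describe the standard study conditions of the synthetic
#' benchmark: 30 species, 300-residue genes, 50 background families plus 5
#' specialized families whose target terminal branch runs 8x faster, a
#' 1500-site 16S-like locus, and base rate 0.1 substitutions/site/unit
#' branch length.
#'
#' @param n_species,target_index,birth_rate,seq_len_16s,gene_len_aa,n_background,n_special,accel_factor,base_rate,seed
#'   see Details in the package vignette. `target_index = NULL` picks the tip
#'   with the longest terminal branch (a long-branch lineage, as a divergent
#'   symbiont would be).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 30L, target_index = NULL, birth_rate = 1,
                       seq_len_16s = 1500L, gene_len_aa = 300L,
                       n_background = 50L, n_special = 5L, accel_factor = 8,
                       base_rate = 0.1, seed = 1L) {
  stopifnot(n_species >= 4, seq_len_16s > 0, gene_len_aa > 0,
            n_background >= 0, n_special >= 0, accel_factor >= 1,
            base_rate > 0, birth_rate > 0)
  structure(list(n_species = as.integer(n_species), target_index = target_index,
                 birth_rate = birth_rate, seq_len_16s = as.integer(seq_len_16s),
                 gene_len_aa = as.integer(gene_len_aa),
                 n_background = as.integer(n_background),
                 n_special = as.integer(n_special), accel_factor = accel_factor,
                 base_rate = base_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a full synthetic benchmark with truth labels
#'
#' One Yule tree, one 16S-like DNA alignment (no acceleration),
#' `n_background` neutral protein families, and `n_special` families whose
#' target terminal branch rate is multiplied by `accel_factor`. Per-family
#' seeds are deterministic functions of the master seed and the group id, so
#' the whole output is byte-reproducible from the config.
#'
#' @param config a [sim_config()].
#' @return a `sim_benchmark` list: `tree`, `target`, `msa_16s`, `genes`
#'   (named list of `list(protein = msa, cds = ...)`), `truth` (tibble:
#'   `group_id`, `class`), `config`.
#' @export
generate_benchmark <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config$n_species, config$birth_rate, config$seed)
  term <- terminal_branch_lengths(tree)
  target <- if (is.null(config$target_index)) {
    names(term)[order(-term, names(term))][1]
  } else {
    tree$tip.label[config$target_index]
  }
  msa_16s <- evolve_alignment(tree, config$seq_len_16s, "dna",
                              base_rate = config$base_rate,
                              seed = derive_seed(config$seed, "16S"))$msa
  ids <- c(sprintf("bg%03d", seq_len(config$n_background)),
           sprintf("special%02d", seq_len(config$n_special)))
  classes <- rep(c("background", "special"),
                 c(config$n_background, config$n_special))
  genes <- purrr::map2(ids, classes, function(id, cls) {
    mult <- if (cls == "special") {
      stats::setNames(config$accel_factor, target)
    } else NULL
    g <- evolve_alignment(tree, config$gene_len_aa, "protein",
                          base_rate = config$base_rate, tip_multipliers = mult,
                          seed = derive_seed(config$seed, id))
    list(protein = g$msa, cds = g$cds)
  })
  names(genes) <- ids
  structure(list(tree = tree, target = target, msa_16s = msa_16s,
                 genes = genes,
                 truth = tibble::tibble(group_id = ids, class = classes),
                 config = config),
            class = "sim_benchmark")
}

derive_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 48271 + hash31(id)) %% 2147483647)
}

terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  idx <- match(seq_len(ntip), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}

#' @export
print.sim_benchmark <- function(x, ...) {
  cat(sprintf("<sim_benchmark> %d species (target %s), %d genes (%d special), 16S %d nt\n",
              x$config$n_species, x$target, length(x$genes),
              x$config$n_special, x$config$seq_len_16s))
  invisible(x)
}

#' Write a benchmark to disk in the pipeline's input formats
#'
#' Newick tree, 16S FASTA alignment, per-gene protein and CDS FASTA
#' (`<group_id>.faa` / `<group_id>.fna`), and a `truth.tsv` label table.
#'
#' @param sim a [generate_benchmark()] result.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "species.nwk"))
  write_fasta(unclass(sim$msa_16s), file.path(dir, "16S.aln.fna"))
  for (id in names(sim$genes)) {
    write_fasta(unclass(sim$genes[[id]]$protein),
                file.path(dir, paste0(id, ".faa")))
    write_fasta(sim$genes[[id]]$cds, file.path(dir, paste0(id, ".fna")))
  }
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  writeLines(jsonlite::toJSON(list(target = sim$target,
                                   config = unclass(sim$config)),
                              auto_unbox = TRUE, null = "null", pretty = TRUE),
             file.path(dir, "benchmark.json"))
  invisible(dir)
}
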