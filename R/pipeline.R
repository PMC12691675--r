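#' Score ortholog groups for phylogeny deviation
#'
#' The central computation: for every gene, the 16S distance matrix is
#' subset to the gene's species, both matrices are standardized over that
#' subset, the 2D distance space is built, and PD/CHI/DBI are computed for
#' the target species, followed by gene-level z-scores and ranking.
#'
#' @param gene_msas named list of protein [as_msa()] alignments (one per
#'   ortholog group).
#' @param msa_16s aligned 16S DNA [as_msa()] covering at least the species in
#'   the gene alignments.
#' @param target target species label.
#' @param min_species groups with fewer members (or lacking the target) are
#'   skipped (default 4).
#' @param nt_model,gamma_alpha 16S distance model (see [dist_nt()]).
#' @param z_threshold candidate flag threshold on the PD z-score (default 1).
#' @param gap_policy gap handling for both distance estimators.
#' @param subsample_other,seed optional out-cluster subsampling
#'   (see [pd_silhouette()]).
#' @return list with `scores` (a [score_genes()] tibble), `spaces` (named
#'   list of [distance_space()]), `phy` (the full 16S [dist_matrix()]), and
#'   `skipped` (tibble of skipped groups and reasons).
#' @export
pd_score_genes <- function(gene_msas, msa_16s, target, min_species = 4L,
                           nt_model = "k2p_gamma", gamma_alpha = 1,
                           z_threshold = 1,
                           gap_policy = "pairwise_deletion",
                           subsample_other = NULL, seed = 1L) {
  stopifnot(length(gene_msas) >= 1, inherits(msa_16s, "msa"))
  if (is.null(names(gene_msas))) {
    stop("gene_msas must be named by group_id", call. = FALSE)
  }
  phy <- dist_nt(msa_16s, model = nt_model, gamma_alpha = gamma_alpha,
                 gap_policy = gap_policy)
  spaces <- list()
  skipped <- list()
  for (id in names(gene_msas)) {
    msa <- gene_msas[[id]]
    sp <- names(msa)
    if (!target %in% sp) {
      skipped[[id]] <- "target absent"; next
    }
    if (length(sp) < min_species) {
      skipped[[id]] <- sprintf("only %d species", length(sp)); next
    }
    miss <- setdiff(sp, rownames(phy))
    if (length(miss)) {
      skipped[[id]] <- paste("no 16S for", paste(miss, collapse = ",")); next
    }
    og <- dist_ml_jtt(msa, gamma_alpha = gamma_alpha, gap_policy = gap_policy)
    phy_sub <- subset_dist(phy, sp)
    spaces[[id]] <- distance_space(standardize_dist(phy_sub),
                                   standardize_dist(og))
  }
  if (!length(spaces)) stop("no scorable groups", call. = FALSE)
  scores <- score_genes(spaces, target, z_threshold = z_threshold,
                        subsample_other = subsample_other, seed = seed)
  list(scores = scores, spaces = spaces, phy = phy,
       skipped = tibble::tibble(group_id = names(skipped),
                                reason = unlist(skipped, use.names = FALSE)))
}

#' Run the full pipeline from a directory of alignments
#'
#' Reads an aligned 16S FASTA and per-group aligned protein FASTA
#' (`<group_id>.faa`, optionally with `<group_id>.fna` CDS for dN/dS
#' profiling) — the formats [write_benchmark()] emits and external aligners
#' produce — scores every group, profiles the flagged genes, and writes the
#' result tables plus a reproducibility manifest.
#'
#' @param input_dir directory holding `16S.aln.fna` and `<group_id>.faa`
#'   (+ `.fna`) files.
#' @param target target species label.
#' @param out_dir output directory.
#' @param profile_flagged also compute per-site dN/dS + divergence profiles
#'   for genes flagged above the z threshold (needs `.fna` files).
#' @param run_min_len,dnds_window,top_k_sites selection-profile settings.
#' @param reference optional reference species for site flagging.
#' @inheritParams pd_score_genes
#' @return list with `scores`, `profiles` (named list), `skipped`, and the
#'   paths written, invisibly combined in `files`.
#' @export
run_pd_pipeline <- function(input_dir, target, out_dir,
                            min_species = 4L, nt_model = "k2p_gamma",
                            gamma_alpha = 1, z_threshold = 1,
                            profile_flagged = TRUE, run_min_len = 10L,
                            dnds_window = 1L, top_k_sites = 15L,
                            reference = NULL, seed = 1L) {
  sixteen <- file.path(input_dir, "16S.aln.fna")
  if (!file.exists(sixteen)) {
    stop("missing input: ", sixteen, call. = FALSE)
  }
  faa <- sort(list.files(input_dir, "\\.faa$", full.names = TRUE))
  if (!length(faa)) stop("no .faa group alignments in ", input_dir, call. = FALSE)
  gene_msas <- lapply(faa, read_fasta_msa, alphabet = "protein")
  names(gene_msas) <- sub("\\.faa$", "", basename(faa))
  msa_16s <- read_fasta_msa(sixteen, "dna")

  res <- pd_score_genes(gene_msas, msa_16s, target, min_species = min_species,
                        nt_model = nt_model, gamma_alpha = gamma_alpha,
                        z_threshold = z_threshold, seed = seed)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores_path <- file.path(out_dir, "gene_scores.tsv")
  readr::write_tsv(res$scores, scores_path)
  top_path <- file.path(out_dir, "top_genes.txt")
  writeLines(export_top_genes(res$scores), top_path)

  profiles <- list()
  if (profile_flagged) {
    flagged <- res$scores$group_id[res$scores$above_threshold]
    for (id in flagged) {
      sp <- res$spaces[[id]]
      part <- partition_points(sp, target)
      cloud <- tibble::as_tibble(sp)
      cloud$cluster <- "other"
      cloud$cluster[part$in_cluster] <- "target"
      readr::write_tsv(cloud, file.path(out_dir, paste0(id, ".space.tsv")))
    }
    for (id in flagged) {
      fna <- file.path(input_dir, paste0(id, ".fna"))
      if (!file.exists(fna)) next
      cds <- as.character(Biostrings::readDNAStringSet(fna))
      names(cds) <- sub("\\s.*$", "", names(cds))
      aln <- backtranslate(gene_msas[[id]], cds)
      profiles[[id]] <- selection_profile(
        aln, gene_msas[[id]], target, reference = reference,
        window = dnds_window, min_len = run_min_len, k = top_k_sites)
      readr::write_tsv(profiles[[id]]$profile,
                       file.path(out_dir, paste0(id, ".profile.tsv")))
    }
    runs_all <- purrr::imap_dfr(profiles, function(p, id) {
      if (!nrow(p$runs)) return(NULL)
      dplyr::mutate(p$runs, group_id = id, .before = 1)
    })
    readr::write_tsv(runs_all, file.path(out_dir, "runs.tsv"))
  }

  manifest <- list(
    package = "pdscore",
    version = as.character(utils::packageVersion("pdscore")),
    target = target,
    settings = list(min_species = min_species, nt_model = nt_model,
                    gamma_alpha = gamma_alpha, z_threshold = z_threshold,
                    run_min_len = run_min_len, dnds_window = dnds_window,
                    top_k_sites = top_k_sites, seed = seed),
    n_groups_scored = nrow(res$scores),
    n_groups_skipped = nrow(res$skipped),
    n_flagged = sum(res$scores$above_threshold))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null"),
             file.path(out_dir, "manifest.json"))

  invisible(list(scores = res$scores, profiles = profiles,
                 skipped = res$skipped,
                 files = c(scores_path, top_path,
                           file.path(out_dir, "manifest.json"))))
}

#' Export the top-ranked gene list
#'
#' @param scores a [score_genes()] table.
#' @param k how many genes (default 100); all when fewer.
#' @return character vector of `group_id` in rank order.
#' @export
export_top_genes <- function(scores, k = 100L) {
  stopifnot(nrow(scores) >= 1, k >= 0)
  ord <- scores$group_id[order(scores$rank_pd)]
  utils::head(ord, k)
}

#' Homologous recombination rate from qPCR cycle thresholds
#'
#' `2^(ct_universal) / 2^(ct_assay)`: the universal primer pair amplifies all
#' plasmids, the assay pair only the recombined one, so the CT difference
#' measures the recombined fraction.
#'
#' @param ct_universal,ct_assay finite cycle-threshold values.
#' @return the recombination rate, `2^(ct_universal - ct_assay)`.
#' @examples
#' recombination_rate(20, 25)  # 0.03125
#' @export
recombination_rate <- function(ct_universal, ct_assay) {
  if (!all(is.finite(ct_universal)) || !all(is.finite(ct_assay))) {
    stop("CT values must be finite", call. = FALSE)
  }
  2^(ct_universal - ct_assay)
}
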