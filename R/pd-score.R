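#' Build the 2D distance space for one ortholog group
#'
#' Combines a standardized 16S (phylogenetic) distance matrix and a
#' standardized per-gene protein distance matrix into the "distance space":
#' one point per unordered species pair, with x the standardized phylogenetic
#' distance and y the standardized protein distance. On a
#' phylogeny-concordant gene the points hug the y = x trend; a gene
#' specialized in one species pushes that species' pair-points off the trend.
#'
#' @param phy_std standardized phylogenetic distances ([standardize_dist()]).
#' @param og_std standardized protein distances for one ortholog group, over
#'   the same label set.
#' @return a `distance_space`: a tibble with columns `a`, `b`, `x`, `y` and a
#'   `species` attribute; N species give N(N-1)/2 rows.
#' @export
distance_space <- function(phy_std, og_std) {
  la <- rownames(phy_std); lb <- rownames(og_std)
  if (!setequal(la, lb)) {
    stop("label sets differ; only in phy: {",
         paste(setdiff(la, lb), collapse = ", "), "}, only in og: {",
         paste(setdiff(lb, la), collapse = ", "), "}", call. = FALSE)
  }
  og <- unclass(og_std)[la, la]
  phy <- unclass(phy_std)
  idx <- which(upper.tri(phy), arr.ind = TRUE)
  out <- tibble::tibble(a = la[idx[, 1]], b = la[idx[, 2]],
                        x = phy[idx], y = og[idx])
  if (any(!is.finite(out$x)) || any(!is.finite(out$y))) {
    stop("non-finite coordinates in distance space", call. = FALSE)
  }
  structure(out, species = la, class = c("distance_space", class(out)))
}

#' Partition distance-space points by a target species
#'
#' Splits the points into the in-cluster `C_c` (pairs containing the target
#' species c) and the out-cluster `C_other` (pairs not involving c).
#'
#' @param space a [distance_space()].
#' @param target target species label.
#' @return list with integer index vectors `in_cluster` (length N-1) and
#'   `out_cluster` (length (N-1)(N-2)/2).
#' @export
partition_points <- function(space, target) {
  species <- attr(space, "species")
  if (!target %in% species) {
    stop("target species '", target, "' not in distance space", call. = FALSE)
  }
  if (length(species) < 3) {
    stop("need at least 3 species (out-cluster would be empty)", call. = FALSE)
  }
  in_cluster <- which(space$a == target | space$b == target)
  list(in_cluster = in_cluster,
       out_cluster = setdiff(seq_len(nrow(space)), in_cluster))
}

#' Phylogeny-deviation (PD) score: mean silhouette of the target's pair-points
#'
#' For each in-cluster point i, `h_i` is its mean Euclidean distance to the
#' other in-cluster points, `f_i` its mean distance to all out-cluster points,
#' and the silhouette coefficient `s_i = (f_i - h_i) / max(f_i, h_i)` (0 when
#' both means are 0). The PD score is the mean of the `s_i`: near 1 when the
#' target's points separate cleanly from the background trend, near 0 when
#' they are embedded in it.
#'
#' @inheritParams partition_points
#' @param subsample_other optional integer: subsample the out-cluster to this
#'   size (seeded) for very large species sets. Off (`NULL`) by default, so
#'   standard runs are exact.
#' @param seed seed for the optional subsampling.
#' @return a `pd_silhouette` object: list with `pd` (the score), `target`, and
#'   `breakdown`, a tibble of per-point `a`, `b`, `h`, `f`, `s`.
#' @examples
#' phy <- standardize_dist(dist_matrix(as.matrix(dist(1:4)),
#'                                     labels = paste0("sp", 1:4)))
#' s <- distance_space(phy, phy)   # perfectly concordant gene
#' pd_silhouette(s, "sp1")$pd
#' @export
pd_silhouette <- function(space, target, subsample_other = NULL, seed = 1L) {
  part <- partition_points(space, target)
  pts <- cbind(space$x, space$y)
  ins <- part$in_cluster
  out <- part$out_cluster
  if (!is.null(subsample_other) && subsample_other < length(out)) {
    out <- withr_seed_sample(out, subsample_other, seed)
  }
  P_in <- pts[ins, , drop = FALSE]
  P_out <- pts[out, , drop = FALSE]
  # all in-vs-in and in-vs-out Euclidean distances, vectorized
  dii <- euclid_cross(P_in, P_in)
  dio <- euclid_cross(P_in, P_out)
  k <- length(ins)
  h <- if (k > 1) rowSums(dii) / (k - 1) else rep(0, k)
  f <- rowMeans(dio)
  denom <- pmax(f, h)
  s <- ifelse(denom == 0, 0, (f - h) / denom)
  breakdown <- tibble::tibble(a = space$a[ins], b = space$b[ins],
                              h = h, f = f, s = s)
  structure(list(pd = mean(s), target = target, breakdown = breakdown,
                 n_species = length(attr(space, "species")),
                 n_out_used = length(out)),
            class = "pd_silhouette")
}

euclid_cross <- function(A, B) {
  # ||a - b|| for all rows of A x rows of B; direct differences (not the
  # expanded quadratic form) to keep full double precision near ties
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  sqrt(dx * dx + dy * dy)
}

withr_seed_sample <- function(x, size, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sort(sample(x, size))
}

#' @export
print.pd_silhouette <- function(x, ...) {
  cat(sprintf("<pd_silhouette> target %s: PD = %.4f (%d species, %d in-cluster points)\n",
              x$target, x$pd, x$n_species, nrow(x$breakdown)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-point silhouette breakdown of a PD fit
#'
#' @param x a `pd_silhouette`.
#' @param ... unused.
#' @return tibble with one row per in-cluster point: `a`, `b`, `h`, `f`, `s`.
#' @method tidy pd_silhouette
#' @export
tidy.pd_silhouette <- function(x, ...) x$breakdown

#' @rdname tidy.pd_silhouette
#' @method glance pd_silhouette
#' @export
glance.pd_silhouette <- function(x, ...) {
  tibble::tibble(target = x$target, pd = x$pd, n_species = x$n_species,
                 n_points_in = nrow(x$breakdown), n_points_out = x$n_out_used)
}

#' Calinski-Harabasz index of the target-vs-rest partition
#'
#' Between-cluster over within-cluster sum of squares, scaled by degrees of
#' freedom, for the 2-cluster partition of the distance space. Zero within-SS
#' with distinct centroids returns `Inf`.
#'
#' @inheritParams partition_points
#' @return a single number.
#' @export
chi_score <- function(space, target) {
  part <- partition_points(space, target)
  pts <- cbind(space$x, space$y)
  g1 <- pts[part$in_cluster, , drop = FALSE]
  g2 <- pts[part$out_cluster, , drop = FALSE]
  n1 <- nrow(g1); n2 <- nrow(g2); n <- n1 + n2
  c1 <- colMeans(g1); c2 <- colMeans(g2); cc <- colMeans(pts)
  bss <- n1 * sum((c1 - cc)^2) + n2 * sum((c2 - cc)^2)
  wss <- sum(sweep(g1, 2, c1)^2) + sum(sweep(g2, 2, c2)^2)
  if (wss == 0) {
    if (bss == 0) return(0)
    return(Inf)
  }
  (bss / 1) / (wss / (n - 2))
}

#' Davies-Bouldin index of the target-vs-rest partition
#'
#' `(sigma_c + sigma_other) / ||centroid_c - centroid_other||` with sigma the
#' mean Euclidean distance of a cluster's points to its centroid. Low values
#' mean well-separated clusters; coincident centroids return `Inf`.
#'
#' @inheritParams partition_points
#' @return a single number.
#' @export
dbi_score <- function(space, target) {
  part <- partition_points(space, target)
  pts <- cbind(space$x, space$y)
  g1 <- pts[part$in_cluster, , drop = FALSE]
  g2 <- pts[part$out_cluster, , drop = FALSE]
  c1 <- colMeans(g1); c2 <- colMeans(g2)
  s1 <- mean(sqrt(rowSums(sweep(g1, 2, c1)^2)))
  s2 <- mean(sqrt(rowSums(sweep(g2, 2, c2)^2)))
  sep <- sqrt(sum((c1 - c2)^2))
  if (sep == 0) return(Inf)
  (s1 + s2) / sep
}

#' Score all ortholog groups for one target species
#'
#' Computes PD (mean silhouette), CHI and DBI per group, then gene-level
#' z-scores of PD across groups, a dense descending rank (ties broken by
#' `group_id`), and the candidate flag `above_threshold = z_pd >= z_threshold`.
#'
#' @param spaces named list of [distance_space()] objects, one per group.
#' @param target target species label.
#' @param z_threshold flag threshold on the PD z-score (default 1, roughly the
#'   top 16% under normality).
#' @param subsample_other,seed passed to [pd_silhouette()].
#' @return a `gene_score_table` tibble: `group_id`, `pd`, `chi`, `dbi`,
#'   `z_pd`, `rank_pd`, `above_threshold`, sorted by rank.
#' @export
score_genes <- function(spaces, target, z_threshold = 1,
                        subsample_other = NULL, seed = 1L) {
  stopifnot(length(spaces) >= 1)
  if (is.null(names(spaces)) || any(names(spaces) == "")) {
    stop("`spaces` must be a named list keyed by group_id", call. = FALSE)
  }
  rows <- purrr::map2_dfr(spaces, names(spaces), function(sp, id) {
    tibble::tibble(
      group_id = id,
      pd = pd_silhouette(sp, target, subsample_other, seed)$pd,
      chi = chi_score(sp, target),
      dbi = dbi_score(sp, target))
  })
  if (nrow(rows) >= 2) {
    rows$z_pd <- as.numeric(scale(rows$pd))
    if (stats::sd(rows$pd) == 0) rows$z_pd <- rep(NA_real_, nrow(rows))
  } else {
    warning("z-scores undefined with a single group", call. = FALSE)
    rows$z_pd <- NA_real_
  }
  rows <- dplyr::arrange(rows, dplyr::desc(.data$pd), .data$group_id)
  rows$rank_pd <- seq_len(nrow(rows))
  rows$above_threshold <- !is.na(rows$z_pd) & rows$z_pd >= z_threshold
  structure(rows, target = target, z_threshold = z_threshold,
            class = c("gene_score_table", class(rows)))
}
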