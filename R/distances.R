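#' Labeled symmetric distance matrices
#'
#' Constructor/validator for the pairwise evolutionary distance matrices used
#' throughout the package: square numeric matrices with species labels as
#' dimnames, a zero diagonal, symmetric and finite.
#'
#' @param values square numeric matrix.
#' @param labels optional character vector of species labels (defaults to the
#'   rownames of `values`).
#' @return the validated matrix with class `dist_matrix`.
#' @export
dist_matrix <- function(values, labels = rownames(values)) {
  values <- as.matrix(values)
  if (is.null(labels)) stop("distance matrix needs species labels", call. = FALSE)
  if (nrow(values) != ncol(values)) stop("matrix not square", call. = FALSE)
  if (anyDuplicated(labels)) stop("duplicated labels", call. = FALSE)
  dimnames(values) <- list(labels, labels)
  if (any(!is.finite(values))) stop("non-finite distances", call. = FALSE)
  if (any(abs(values - t(values)) > 1e-6)) stop("matrix not symmetric", call. = FALSE)
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (any(values < 0)) stop("negative distances", call. = FALSE)
  class(values) <- c("dist_matrix", "matrix", "array")
  values
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> %d species\n", nrow(x)))
  print(round(unclass(x), 4))
  invisible(x)
}

# pairwise index columns after applying the gap policy; valid = allowed symbols
pair_valid_matrix <- function(msa, gap_policy, valid) {
  m <- msa_matrix(msa)
  ok <- matrix(m %in% valid, nrow = nrow(m), dimnames = dimnames(m))
  if (gap_policy == "complete_deletion") {
    keep <- colSums(ok) == nrow(ok)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  list(chars = m, ok = ok)
}

#' Observed-proportion (p) distance
#'
#' Mismatches over compared columns for every pair of rows. Columns holding a
#' gap or an ambiguous symbol in either member of the pair
#' (`pairwise_deletion`) or in any row (`complete_deletion`) are excluded.
#'
#' @param msa an [as_msa()] alignment with at least two rows.
#' @param gap_policy `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @return a [dist_matrix()].
#' @examples
#' m <- as_msa(c(a = "AAAA", b = "AAAT"), "dna")
#' dist_p(m)["a", "b"]  # 0.25
#' @export
dist_p <- function(msa, gap_policy = c("pairwise_deletion", "complete_deletion")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(msa, "msa"), length(msa) >= 2)
  valid <- if (attr(msa, "alphabet") == "protein") PROTEIN_AA else DNA_NT
  pv <- pair_valid_matrix(msa, gap_policy, valid)
  n <- nrow(pv$chars)
  lab <- rownames(pv$chars)
  d <- matrix(0, n, n, dimnames = list(lab, lab))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- pv$ok[i, ] & pv$ok[j, ]
      if (!any(use)) {
        stop(sprintf("no comparable columns for pair %s / %s", lab[i], lab[j]),
             call. = FALSE)
      }
      p <- mean(pv$chars[i, use] != pv$chars[j, use])
      d[i, j] <- d[j, i] <- p
    }
  }
  dist_matrix(d)
}

# 20 x 20 pair count vector (length 400) for one pair of index rows,
# symmetrized so the likelihood is exactly invariant to row order
pair_counts <- function(ai, aj) {
  use <- !is.na(ai) & !is.na(aj)
  tabulate((ai[use] - 1L) * 20L + aj[use], nbins = 400L) +
    tabulate((aj[use] - 1L) * 20L + ai[use], nbins = 400L)
}

# negative log-likelihood of a pair count vector at distance d under the
# given eigen-decomposed model with discrete-Gamma rates
nll_pair <- function(d, counts, e, rates) {
  M <- matrix(0, 20, 20)
  for (r in rates) M <- M + transition_prob(e, d * r)
  M <- (e$freq / length(rates)) * M       # row i scaled by pi_i
  lm <- log(pmax(as.vector(t(M)), 1e-300))  # vectorized as (i-1)*20 + j
  -sum(counts * lm)
}

#' Pairwise maximum-likelihood protein distance under JTT + Gamma
#'
#' For every pair of rows, finds the evolutionary distance maximizing the
#' likelihood of the gap-stripped pair under the Jones-Taylor-Thornton
#' substitution model with discrete-Gamma among-site rate variation. The 1-D
#' search is a shared likelihood grid over all pairs followed by local
#' refinement with [stats::optimize()].
#'
#' @inheritParams dist_p
#' @param gamma_alpha Gamma shape parameter (rate heterogeneity; default 1;
#'   `Inf` means rate homogeneity).
#' @param gamma_categories number of discrete Gamma categories (default 4).
#' @param d_max upper search bound; saturated pairs report `d_max` with a
#'   warning (default 10 substitutions/site).
#' @param model `"jtt"` (default) or `"poisson"` (equal exchangeabilities and
#'   frequencies, mostly useful as an analytic cross-check limit).
#' @return a [dist_matrix()].
#' @export
dist_ml_jtt <- function(msa, gamma_alpha = 1, gamma_categories = 4L,
                        d_max = 10,
                        gap_policy = c("pairwise_deletion", "complete_deletion"),
                        model = c("jtt", "poisson")) {
  gap_policy <- match.arg(gap_policy)
  model <- match.arg(model)
  stopifnot(inherits(msa, "msa"), length(msa) >= 2, gamma_alpha > 0, d_max > 0)
  if (attr(msa, "alphabet") != "protein") {
    stop("dist_ml_jtt requires a protein alignment", call. = FALSE)
  }
  pv <- pair_valid_matrix(msa, gap_policy, PROTEIN_AA)
  idx <- matrix(match(pv$chars, JTT_AA), nrow = nrow(pv$chars),
                dimnames = dimnames(pv$chars))
  n <- nrow(idx)
  lab <- rownames(idx)
  e <- if (model == "jtt") jtt_eigen() else {
    rate_matrix_eigen(rep(1, 190), stats::setNames(rep(0.05, 20), JTT_AA))
  }
  rates <- if (is.finite(gamma_alpha)) {
    discrete_gamma_rates(gamma_alpha, gamma_categories)
  } else 1

  pairs <- utils::combn(n, 2)
  counts <- matrix(0, ncol(pairs), 400L)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cnt <- pair_counts(idx[i, ], idx[j, ])
    if (sum(cnt) == 0) {
      stop(sprintf("no comparable columns for pair %s / %s", lab[i], lab[j]),
           call. = FALSE)
    }
    counts[p, ] <- cnt
  }

  # shared coarse grid, then per-pair bracketed refinement
  grid <- exp(seq(log(d_max / 2000), log(d_max), length.out = 60L))
  logM <- vapply(grid, function(d) {
    M <- matrix(0, 20, 20)
    for (r in rates) M <- M + transition_prob(e, d * r)
    M <- (e$freq / length(rates)) * M
    log(pmax(as.vector(t(M)), 1e-300))
  }, numeric(400L))
  nll_grid <- -counts %*% logM

  d <- matrix(0, n, n, dimnames = list(lab, lab))
  saturated <- character(0)
  same_cells <- (seq_len(20) - 1L) * 20L + seq_len(20)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    cnt <- counts[p, ]
    if (sum(cnt[-same_cells]) == 0) next  # identical sequences: d = 0
    k <- which.min(nll_grid[p, ])
    if (k == length(grid)) {
      est <- d_max
      saturated <- c(saturated, sprintf("%s/%s", lab[i], lab[j]))
    } else {
      lo <- if (k == 1L) 1e-9 else grid[k - 1L]
      hi <- grid[k + 1L]
      est <- stats::optimize(nll_pair, c(lo, hi), counts = cnt, e = e,
                             rates = rates, tol = 1e-8)$minimum
      if (est < 1e-7) est <- 0
    }
    d[i, j] <- d[j, i] <- est
  }
  if (length(saturated)) {
    warning("saturated pairs reported at d_max = ", d_max, ": ",
            paste(saturated, collapse = ", "), call. = FALSE)
  }
  dist_matrix(d)
}

#' Nucleotide distances (p, Jukes-Cantor, Kimura 2-parameter + Gamma)
#'
#' `"jc"` applies the Jukes-Cantor correction `-3/4 * log(1 - 4p/3)`;
#' `"k2p_gamma"` the Gamma-corrected Kimura two-parameter distance
#' `a/2 * ((1-2P-Q)^(-1/a) + (1-2Q)^(-1/a)/2 - 3/2)` with transition
#' proportion P and transversion proportion Q. Saturated pairs (correction out
#' of domain) report `d_max` with a warning.
#'
#' @inheritParams dist_ml_jtt
#' @param model `"p"`, `"jc"` or `"k2p_gamma"`.
#' @return a [dist_matrix()].
#' @examples
#' # p = 0.3 under JC: -0.75 * log(1 - 0.4) = 0.38299...
#' @export
dist_nt <- function(msa, model = c("k2p_gamma", "jc", "p"), gamma_alpha = 1,
                    d_max = 10,
                    gap_policy = c("pairwise_deletion", "complete_deletion")) {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(msa, "msa"), length(msa) >= 2)
  if (attr(msa, "alphabet") != "dna") {
    stop("dist_nt requires a dna alignment", call. = FALSE)
  }
  if (model == "p") return(dist_p(msa, gap_policy))
  pv <- pair_valid_matrix(msa, gap_policy, DNA_NT)
  n <- nrow(pv$chars)
  lab <- rownames(pv$chars)
  purine <- matrix(pv$chars %in% c("A", "G"), nrow = nrow(pv$chars))
  d <- matrix(0, n, n, dimnames = list(lab, lab))
  saturated <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- pv$ok[i, ] & pv$ok[j, ]
      if (!any(use)) {
        stop(sprintf("no comparable columns for pair %s / %s", lab[i], lab[j]),
             call. = FALSE)
      }
      ci <- pv$chars[i, use]; cj <- pv$chars[j, use]
      diff <- ci != cj
      if (model == "jc") {
        p <- mean(diff)
        arg <- 1 - 4 * p / 3
        if (arg <= 0) {
          est <- d_max; saturated <- c(saturated, sprintf("%s/%s", lab[i], lab[j]))
        } else est <- -0.75 * log(arg)
      } else {
        ts <- mean(diff & (purine[i, use] == purine[j, use]))  # A<->G, C<->T
        tv <- mean(diff) - ts
        a1 <- 1 - 2 * ts - tv
        a2 <- 1 - 2 * tv
        if (a1 <= 0 || a2 <= 0) {
          est <- d_max; saturated <- c(saturated, sprintf("%s/%s", lab[i], lab[j]))
        } else {
          a <- gamma_alpha
          est <- a / 2 * (a1^(-1 / a) + a2^(-1 / a) / 2 - 3 / 2)
          if (!is.finite(est) || est > d_max) {
            est <- d_max; saturated <- c(saturated, sprintf("%s/%s", lab[i], lab[j]))
          }
        }
      }
      d[i, j] <- d[j, i] <- est
    }
  }
  if (length(saturated)) {
    warning("saturated pairs reported at d_max = ", d_max, ": ",
            paste(unique(saturated), collapse = ", "), call. = FALSE)
  }
  dist_matrix(d)
}

#' Standardize a distance matrix to zero mean and unit variance
#'
#' Centers and scales a distance matrix using the mean and sample standard
#' deviation (denominator n-1) of its strict upper-triangle entries, so every
#' gene's distances live on a common scale regardless of its evolutionary
#' rate. The diagonal is set to 0 by convention and never consumed downstream.
#'
#' @param m a [dist_matrix()] with at least 3 labels and non-constant
#'   off-diagonal entries.
#' @return a `std_dist` matrix with `center` and `scale` attributes.
#' @examples
#' m <- dist_matrix(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
#'                         dimnames = list(letters[1:3], letters[1:3])))
#' standardize_dist(m)  # upper triangle {1,2,3} -> {-1, 0, 1}
#' @export
standardize_dist <- function(m) {
  stopifnot(inherits(m, "dist_matrix") || (is.matrix(m) && !is.null(rownames(m))))
  v <- unclass(m)
  if (nrow(v) < 3) stop("need at least 3 labels to standardize", call. = FALSE)
  ut <- v[upper.tri(v)]
  center <- mean(ut)
  scale <- stats::sd(ut)
  if (!is.finite(scale) || scale == 0) {
    stop("degenerate distance matrix", call. = FALSE)
  }
  z <- (v - center) / scale
  diag(z) <- 0
  structure(z, center = center, scale = scale,
            class = c("std_dist", "matrix", "array"))
}

#' @export
print.std_dist <- function(x, ...) {
  cat(sprintf("<std_dist> %d species (center %.4g, scale %.4g)\n",
              nrow(x), attr(x, "center"), attr(x, "scale")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' Subset a distance matrix to a label set
#'
#' @param m a `dist_matrix` (or plain labeled matrix).
#' @param labels labels to keep (order preserved as given).
#' @return a [dist_matrix()] over `labels`.
#' @export
subset_dist <- function(m, labels) {
  missing <- setdiff(labels, rownames(m))
  if (length(missing)) {
    stop("labels absent from matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dist_matrix(unclass(m)[labels, labels, drop = FALSE])
}
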