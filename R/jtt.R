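# Jones-Taylor-Thornton (1992) empirical amino-acid substitution model:
# 190 relative exchangeabilities (lower triangle, column-major, amino acids in
# ARNDCQEGHILKMFPSTWYV order) and equilibrium frequencies, as distributed in
# PAML's jones.dat and used by MEGA/phangorn.

JTT_AA <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")

JTT_EXCH <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

JTT_FREQ <- c(
  A = 0.076748, R = 0.051691, N = 0.042645, D = 0.051544, C = 0.019803,
  Q = 0.040752, E = 0.061830, G = 0.073152, H = 0.022944, I = 0.053761,
  L = 0.091904, K = 0.058676, M = 0.023826, F = 0.040126, P = 0.050901,
  S = 0.068765, T = 0.058565, W = 0.014261, Y = 0.032102, V = 0.066005)
JTT_FREQ <- JTT_FREQ / sum(JTT_FREQ)

# Mean rates of the K equiprobable categories of a Gamma(shape, rate = shape)
# distribution (mean 1), Yang's mean-category discretization.
discrete_gamma_rates <- function(shape, k = 4L) {
  stopifnot(shape > 0, k >= 1)
  if (k == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  p <- stats::pgamma(b, shape = shape + 1, rate = shape)
  k * diff(p)
}

# Build a normalized reversible rate matrix Q[i,j] = s_ij * pi_j (rows sum to
# zero, expected rate 1 substitution/site/unit time) and eigen-decompose it via
# the symmetric form B = diag(sqrt(pi)) Q diag(1/sqrt(pi)).
rate_matrix_eigen <- function(exch, freq) {
  n <- length(freq)
  S <- matrix(0, n, n)
  S[lower.tri(S)] <- exch
  S <- S + t(S)
  Q <- S * rep(freq, each = n)        # Q[i,j] = S[i,j] * freq[j]
  diag(Q) <- -rowSums(Q)
  beta <- -sum(freq * diag(Q))
  Q <- Q / beta
  sp <- sqrt(freq)
  B <- Q * (sp / rep(sp, each = n))   # B[i,j] = sqrt(pi_i)/sqrt(pi_j) * Q[i,j]
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors, freq = freq,
       inv_sp = 1 / sp, sp = sp)
}

jtt_eigen_cache <- new.env(parent = emptyenv())

jtt_eigen <- function() {
  if (is.null(jtt_eigen_cache$e)) {
    jtt_eigen_cache$e <- rate_matrix_eigen(JTT_EXCH, JTT_FREQ)
  }
  jtt_eigen_cache$e
}

# Transition probability matrix P(t) = exp(Qt) from an eigen decomposition.
transition_prob <- function(e, t) {
  W <- e$vectors * exp(e$values * t)[col(e$vectors)]  # vectors %*% diag(exp)
  P <- W %*% t(e$vectors)
  P <- P * (e$inv_sp %o% e$sp)
  P[P < 0] <- 0
  P
}
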