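## GY94-style codon rate matrices, their eigendecompositions, and the
## Markov-modulated (switching) extension used by the M3+S1 model.

#' GY94 codon rate matrix
#'
#' Off-diagonal rate `q_ij` is zero unless codons i and j differ at exactly
#' one nucleotide; otherwise it is the target-codon frequency `pi_j`,
#' multiplied by `kappa` for transitions and by `omega` for nonsynonymous
#' changes. The diagonal makes rows sum to zero.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi Codon frequency vector over the 61 sense codons.
#' @param scale If `TRUE`, scale so the expected substitution rate at
#'   stationarity is 1 (branch lengths then read as substitutions/codon).
#' @return 61 x 61 rate matrix.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi, scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  tab <- codon_tables()
  Q <- matrix(0, 61, 61, dimnames = list(tab$codons, tab$codons))
  nb <- tab$diffpos > 0
  Q[nb] <- rep(pi, each = 61)[nb]          # pi_j, column-wise target freq
  Q[nb & tab$is_ts] <- Q[nb & tab$is_ts] * kappa
  Q[nb & !tab$is_syn] <- Q[nb & !tab$is_syn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    if (rate <= 0) stop("degenerate rate matrix (zero total rate)")
    Q <- Q / rate
  }
  Q
}

# Fraction of the stationary substitution flux that is nonsynonymous,
# plus the total rate, for a (possibly unscaled) GY94 matrix.
flux_fractions <- function(Q, pi) {
  tab <- codon_tables()
  flux <- pi * Q
  diag(flux) <- 0
  total <- sum(flux)
  nonsyn <- sum(flux[tab$diffpos > 0 & !tab$is_syn])
  list(f_nonsyn = nonsyn / total, f_syn = 1 - nonsyn / total, total = total)
}

# Eigendecomposition of a reversible generator with stationary vector pi,
# via the symmetrized matrix D^{1/2} Q D^{-1/2}.  Returns the pieces needed
# to form P(t) = D^{-1/2} U exp(L t) U' D^{1/2} cheaply per branch.
rev_eigen <- function(Q, pi) {
  sq <- sqrt(pi)
  S <- t(t(sq * Q) / sq)        # S_ij = sq_i Q_ij / sq_j, symmetric for reversible Q
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, sq = sq)
}

# Transition probability matrix P(t) from a rev_eigen decomposition.
prob_matrix <- function(ed, t) {
  if (t < 0) stop("negative branch length")
  if (t == 0) return(diag(length(ed$lambda)))
  P <- ed$U %*% (exp(ed$lambda * t) * t(ed$U))
  P <- (1 / ed$sq) * t(t(P) * ed$sq)  # D^{-1/2} ... D^{1/2}
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Markov-modulated switching generator (M3+S1 state space)
#'
#' Builds the expanded generator over `61 * K` states (site class x codon).
#' Within a class the process follows the class's GY94 matrix; between
#' classes the codon is unchanged and the rate of switching from class k to
#' class l is `delta * p_l`, which makes the chain reversible with
#' stationary distribution `p_k * pi_c` while keeping a single switching
#' parameter. The whole generator is scaled so the expected *codon
#' substitution* flux (class switches excluded) is 1 per unit branch length,
#' which reduces to the standard mixture scaling of M3 when `delta = 0`.
#'
#' @param kappa,pi As in [gy94_rate_matrix()].
#' @param omegas Numeric vector of K class omega values.
#' @param probs Numeric vector of K class weights (sum to 1).
#' @param delta Switching rate (>= 0).
#' @return List with `G` (the 61K x 61K generator), `stat` (its stationary
#'   vector), `K`, and the scale factor applied.
#' @export
switching_generator <- function(kappa, omegas, probs, delta, pi) {
  K <- length(omegas)
  stopifnot(length(probs) == K, abs(sum(probs) - 1) < 1e-8, delta >= 0)
  Qs <- lapply(omegas, function(w) gy94_rate_matrix(kappa, w, pi, scale = FALSE))
  # mixture scaling: expected codon-substitution rate across classes = 1
  rho <- sum(vapply(seq_len(K), function(k) {
    probs[k] * (-sum(pi * diag(Qs[[k]])))
  }, numeric(1)))
  n <- 61L
  G <- matrix(0, n * K, n * K)
  for (k in seq_len(K)) {
    idx <- ((k - 1L) * n + 1L):(k * n)
    G[idx, idx] <- Qs[[k]] / rho
    for (l in seq_len(K)) {
      if (l == k) next
      jdx <- ((l - 1L) * n + 1L):(l * n)
      sw <- delta * probs[l]
      G[cbind(idx, jdx)] <- sw
      G[cbind(idx, idx)] <- G[cbind(idx, idx)] - sw
    }
  }
  stat <- as.vector(outer(pi, probs))  # order: class blocks of 61 codons
  rowsum_err <- max(abs(rowSums(G)))
  if (rowsum_err > 1e-9) stop("switching generator rows do not sum to 0")
  list(G = G, stat = stat, K = K, scale = rho)
}
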