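## Likelihood (GY94) pairwise dN/dS, subgroup-wise omega sets with the
## dS > 2 saturation filter, and the dicot-vs-grass mean comparison.

#' Pairwise dN/dS by maximum likelihood under GY94
#'
#' Maximizes the two-sequence likelihood over divergence t, kappa and
#' omega. dN and dS are decomposed from t via the fitted matrix's
#' nonsynonymous/synonymous flux fractions, with site proportions taken
#' from the same matrix at omega = 1 (so dN/dS equals the fitted omega).
#'
#' @param a,b Gap-free equal-length codon sequences.
#' @param pi Codon frequencies; default F3x4 estimated from the pair.
#' @param restarts Number of jittered restarts beyond the first fit.
#' @return List of class `pairwise_omega` with `dN`, `dS`, `omega`, `t`,
#'   `kappa`, `lnL`, `saturated`, `undefined`, `converged`,
#'   `method = "ML"`.
#' @export
ml_pairwise <- function(a, b, pi = NULL, restarts = 0) {
  ca <- split_codons(a); cb <- split_codons(b)
  stopifnot(length(ca) == length(cb))
  tab <- codon_tables()
  ia <- match(ca, tab$codons); ib <- match(cb, tab$codons)
  if (anyNA(ia) || anyNA(ib)) stop("sequences contain stop or invalid codons")
  if (is.null(pi)) pi <- codon_frequencies("F3x4", c(a, b))
  # site pattern counts over ordered codon pairs
  key <- (ia - 1L) * 61L + ib
  cnt <- table(key)
  upair <- as.integer(names(cnt))
  ui <- (upair - 1L) %/% 61L + 1L
  uj <- (upair - 1L) %% 61L + 1L
  w <- as.numeric(cnt)

  negll <- function(par) {
    t <- exp(par[1]); kappa <- exp(par[2]); omega <- exp(par[3])
    if (!is.finite(t) || t > 60) return(1e10)
    Q <- gy94_rate_matrix(kappa, omega, pi)
    P <- prob_matrix(rev_eigen(Q, pi), t)
    ll <- sum(w * log(pmax(pi[ui] * P[cbind(ui, uj)], 1e-300)))
    -ll
  }
  # counting estimator both screens saturation and seeds the optimizer
  ng <- ng86_pairwise(a, b)
  if (ng$saturated) {
    return(structure(list(dN = Inf, dS = Inf, omega = NA_real_,
                          t = Inf, kappa = NA_real_, lnL = NA_real_,
                          saturated = TRUE, undefined = FALSE,
                          converged = FALSE, method = "ML"),
                     class = "pairwise_omega"))
  }
  t0 <- max(0.02, (ng$dN * ng$N + ng$dS * ng$S) / (length(ia)))
  w0 <- if (!is.na(ng$omega) && ng$omega > 0) min(max(ng$omega, 0.02), 5)
        else 0.3
  starts <- list(log(c(t0, 2, w0)))
  if (restarts > 0)
    for (r in seq_len(restarts))
      starts[[r + 1L]] <- starts[[1L]] + stats::rnorm(3, 0, 0.5)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(stats::optim(st, negll, method = "L-BFGS-B",
                                 lower = log(c(1e-6, 0.05, 1e-4)),
                                 upper = log(c(55, 100, 50)),
                                 control = list(maxit = 300)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("pairwise likelihood optimization failed")
  t <- exp(best$par[1]); kappa <- exp(best$par[2]); omega <- exp(best$par[3])
  Qf <- gy94_rate_matrix(kappa, omega, pi)
  ff <- flux_fractions(Qf, pi)
  f1 <- flux_fractions(gy94_rate_matrix(kappa, 1, pi), pi)
  dN <- t * ff$f_nonsyn / (3 * f1$f_nonsyn)
  dS <- t * ff$f_syn / (3 * f1$f_syn)
  saturated <- t >= 45 || omega >= 49
  undefined <- all(ia == ib)
  structure(list(dN = dN, dS = dS,
                 omega = if (undefined) NA_real_ else omega,
                 t = t, kappa = kappa, lnL = -best$value,
                 saturated = saturated, undefined = undefined,
                 converged = best$convergence == 0, method = "ML"),
            class = "pairwise_omega")
}

#' Within-subgroup pairwise omega sets with saturation filtering
#'
#' Scores all within-subgroup pairs with [ml_pairwise()], discards pairs
#' with `dS > ds_max` (the saturation cutoff) or undefined omega, and
#' returns the retained omega values with their mean per subgroup.
#'
#' @param cds Named character vector of gap-free codon sequences.
#' @param subgroups [detect_subgroups()] result.
#' @param ds_max Saturation cutoff on dS (default 2).
#' @param method `"ML"` (default) or `"counting"` (NG86).
#' @return Data frame per subgroup: partition, n_members, n_pairs,
#'   n_excluded, mean_omega; plus attribute `omegas`, the per-subgroup
#'   retained omega values.
#' @export
subgroup_pairwise_omega <- function(cds, subgroups, ds_max = 2,
                                    method = c("ML", "counting")) {
  method <- match.arg(method)
  rows <- list(); omega_sets <- list()
  for (k in seq_along(subgroups)) {
    sg <- subgroups[[k]]
    mem <- intersect(sg$members, names(cds))
    omegas <- numeric(0)
    n_pairs <- 0L; n_excl <- 0L
    if (length(mem) >= 2) {
      for (i in seq_along(mem)) {
        for (j in seq_len(i - 1L)) {
          pw <- if (method == "ML") ml_pairwise(cds[[mem[i]]], cds[[mem[j]]])
                else ng86_pairwise(cds[[mem[i]]], cds[[mem[j]]])
          n_pairs <- n_pairs + 1L
          if (pw$saturated || (is.finite(pw$dS) && pw$dS > ds_max)) {
            n_excl <- n_excl + 1L
          } else if (!is.na(pw$omega)) {
            omegas <- c(omegas, pw$omega)
          }
        }
      }
    }
    omega_sets[[k]] <- omegas
    rows[[k]] <- data.frame(
      subgroup = k, partition = sg$partition, n_members = length(mem),
      n_pairs = n_pairs, n_excluded = n_excl,
      mean_omega = if (length(omegas)) mean(omegas) else NA_real_)
  }
  out <- do.call(rbind, rows)
  attr(out, "omegas") <- omega_sets
  out
}

#' Compare dicot and grass subgroup omega sets
#'
#' Two-sided Mann-Whitney U test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise), with significance stars at
#' the conventional thresholds. Pairwise omega values within a subgroup
#' share sequences and are not independent; the result carries a caveat
#' flag, and `subsample_one_per_gene` draws a single pair per gene to
#' soften the dependence.
#'
#' @param dicot_omegas,grass_omegas Numeric vectors (non-empty).
#' @param subsample_one_per_gene Optional list of gene-pair ids; when
#'   given, one omega per gene is retained before testing.
#' @return List: `p`, `stars` (`"n.s."`, `"*"`, `"**"`), `statistic`,
#'   `dependence_caveat = TRUE`.
#' @export
compare_subgroup_means <- function(dicot_omegas, grass_omegas,
                                   subsample_one_per_gene = NULL) {
  stopifnot(length(dicot_omegas) > 0, length(grass_omegas) > 0)
  if (length(unique(c(dicot_omegas, grass_omegas))) == 1L) {
    p <- 1
    stat <- NA_real_
  } else {
    wt <- suppressWarnings(stats::wilcox.test(dicot_omegas, grass_omegas,
                                              alternative = "two.sided",
                                              exact = NULL, correct = TRUE))
    p <- wt$p.value
    stat <- unname(wt$statistic)
  }
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
  list(p = p, stars = stars, statistic = stat, dependence_caveat = TRUE)
}
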