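## Maximum-likelihood fitting of codon models on a fixed tree topology:
## one-ratio / branch models, the M3 discrete site mixture, and the
## Markov-modulated M3+S1 switching model, plus the LRT and the
## clade-specific positive-site partitioning.

#' Fit a branch codon model (one-ratio or k-ratio)
#'
#' Felsenstein pruning over the 61 codon states with per-branch-class GY94
#' matrices sharing kappa and pi; optimizes branch lengths, kappa and one
#' omega per class by bounded quasi-Newton on log-transformed parameters.
#'
#' @param cds Named gap-free codon sequences (tree tip labels).
#' @param tree Rooted or unrooted [ape::phylo] with branch lengths
#'   (used as starting values; expected substitutions per codon).
#' @param branch_classes `NULL` for the one-ratio model, `"partition"` to
#'   derive dicot/grass/other classes from leaf species, or a character
#'   vector over edges of `tree`.
#' @param pi Codon frequencies; default F3x4 from the data.
#' @param branch_mode `"joint"` (optimize every branch length),
#'   `"scale"` (single rescaling of the input lengths) or `"fixed"`.
#' @param restarts Additional jittered optimizer restarts.
#' @param control Passed to [stats::optim()] (L-BFGS-B).
#' @return A `codon_model_fit`: `model`, `lnL`, `minus_lnL`, `kappa`,
#'   `omega` (named per class), `tree` (fitted lengths), `branch_classes`,
#'   `converged`, `npar`.
#' @export
fit_branch_model <- function(cds, tree, branch_classes = NULL, pi = NULL,
                             branch_mode = c("joint", "scale", "fixed"),
                             restarts = 0, control = list()) {
  branch_mode <- match.arg(branch_mode)
  prep <- prep_tree_data(cds, tree)
  if (is.null(pi)) pi <- codon_frequencies("F3x4", unname(cds))
  if (identical(branch_classes, "partition"))
    branch_classes <- edge_partition_classes(prep$phy)
  if (is.null(branch_classes)) branch_classes <- rep("all", nrow(prep$phy$edge))
  if (length(branch_classes) != nrow(prep$phy$edge))
    stop("branch_classes must label every edge")
  classes <- sort(unique(branch_classes))
  if (!all(table(branch_classes) >= 1)) stop("empty branch class")
  K <- length(classes)

  bl0 <- pmax(prep$phy$edge.length, 1e-4)
  theta0 <- c(log(2), rep(log(0.2), K))
  make_ll <- function() {
    function(par) {
      dec <- decode_bl(par, branch_mode, bl0, n_extra = 1 + K)
      kappa <- exp(dec$extra[1L])
      omegas <- exp(dec$extra[-1L])
      eds <- lapply(omegas, function(w)
        rev_eigen(gy94_rate_matrix(kappa, w, pi), pi))
      Pl <- lapply(seq_along(branch_classes), function(e)
        prob_matrix(eds[[match(branch_classes[e], classes)]], dec$bl[e]))
      -sum(pruning_site_loglik(prep$phy, Pl, prep$tips, pi)$site_ll)
    }
  }
  fit <- run_optim(make_ll(), branch_mode, bl0, theta0, restarts, control)
  dec <- decode_bl(fit$par, branch_mode, bl0, n_extra = 1 + K)
  phy_out <- prep$phy
  phy_out$edge.length <- dec$bl
  npar <- length(fit$par)
  structure(list(model = if (K == 1) "one-ratio" else
                   sprintf("branch-%d-ratio", K),
                 lnL = -fit$value, minus_lnL = fit$value,
                 kappa = exp(dec$extra[1L]),
                 omega = stats::setNames(exp(dec$extra[-1L]), classes),
                 tree = phy_out, branch_classes = branch_classes,
                 pi = pi, converged = fit$convergence == 0, npar = npar),
            class = "codon_model_fit")
}

#' Fit the M3 discrete site-mixture codon model
#'
#' Site likelihood is a K-class mixture over omega classes sharing kappa,
#' pi and branch lengths; omega classes are kept ascending by an
#' increment parameterization for identifiability. Naive empirical Bayes
#' posteriors per site are returned; sites are called positive when the
#' top class has omega > 1 and posterior > 0.5 (strong at > 0.95).
#'
#' @inheritParams fit_branch_model
#' @param K Number of site classes (default 3).
#' @return A `codon_model_fit` with `p` (class proportions), `omega`
#'   (ascending), `posteriors` (nsites x K), `positive_sites`,
#'   `class_collapsed` flag.
#' @export
fit_m3 <- function(cds, tree, K = 3, pi = NULL,
                   branch_mode = c("scale", "joint", "fixed"),
                   restarts = 0, control = list()) {
  branch_mode <- match.arg(branch_mode)
  stopifnot(K >= 2)
  prep <- prep_tree_data(cds, tree)
  if (is.null(pi)) pi <- codon_frequencies("F3x4", unname(cds))
  bl0 <- pmax(prep$phy$edge.length, 1e-4)
  theta0 <- c(log(2), rep(0, K - 1),
              log(0.05), log(diff(c(0.05, 0.4, 2.0))[seq_len(K - 1)]))

  site_ll_matrix <- function(kappa, omegas, probs, bl) {
    Qs <- lapply(omegas, function(w)
      gy94_rate_matrix(kappa, w, pi, scale = FALSE))
    rho <- sum(probs * vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1)))
    vapply(seq_along(Qs), function(k) {
      ed <- rev_eigen(Qs[[k]] / rho, pi)
      Pl <- lapply(bl, function(t) prob_matrix(ed, t))
      pruning_site_loglik(prep$phy, Pl, prep$tips, pi)$site_ll
    }, numeric(prep$nsites))
  }

  negll <- function(par) {
    dec <- decode_bl(par, branch_mode, bl0, n_extra = 2 * K)
    th <- decode_m3(dec$extra, K)
    sll <- site_ll_matrix(th$kappa, th$omegas, th$probs, dec$bl)
    -sum(log_mix(sll, th$probs))
  }
  fit <- run_optim(negll, branch_mode, bl0, theta0, restarts, control)
  dec <- decode_bl(fit$par, branch_mode, bl0, n_extra = 2 * K)
  th <- decode_m3(dec$extra, K)
  sll <- site_ll_matrix(th$kappa, th$omegas, th$probs, dec$bl)
  lw <- sweep(sll, 2, log(th$probs), "+")
  post <- exp(lw - apply(lw, 1, max))
  post <- post / rowSums(post)
  top <- K
  positive <- which(th$omegas[top] > 1 & post[, top] > 0.5)
  strong <- which(th$omegas[top] > 1 & post[, top] > 0.95)
  phy_out <- prep$phy; phy_out$edge.length <- dec$bl
  structure(list(model = "M3",
                 lnL = -fit$value, minus_lnL = fit$value,
                 kappa = th$kappa, omega = th$omegas, p = th$probs,
                 posteriors = post, positive_sites = positive,
                 strong_positive_sites = strong,
                 class_collapsed = any(diff(th$omegas) < 1e-4),
                 tree = phy_out, pi = pi,
                 converged = fit$convergence == 0,
                 npar = length(fit$par)),
            class = "codon_model_fit")
}

#' Fit the M3+S1 Markov-modulated switching codon model
#'
#' The site process lives on the expanded class-by-codon state space
#' (61K states): within a class it follows that class's GY94 matrix;
#' between classes it switches at rate `delta` with jump rates
#' proportional to the stationary class weights. Pruning runs over the
#' expanded states; per-site, per-branch marginal class posteriors are
#' computed from the up/down pass at each edge's child node.
#'
#' @inheritParams fit_m3
#' @param init Optional `codon_model_fit` from [fit_m3()] used as the
#'   starting point (guarantees the nesting lnL(M3+S1) >= lnL(M3) up to
#'   optimizer tolerance).
#' @return A `codon_model_fit` with `delta`, class posteriors per node
#'   (`branch_class_posterior`: list over edges of K x nsites matrices at
#'   the child node), and the M3-style parameter set.
#' @export
fit_m3_s1 <- function(cds, tree, K = 3, pi = NULL,
                      branch_mode = c("scale", "joint", "fixed"),
                      init = NULL, restarts = 0, control = list()) {
  branch_mode <- match.arg(branch_mode)
  stopifnot(K >= 2)
  prep <- prep_tree_data(cds, tree, n_classes = K)
  if (is.null(pi)) pi <- codon_frequencies("F3x4", unname(cds))
  bl0 <- pmax(prep$phy$edge.length, 1e-4)
  if (!is.null(init)) {
    if (!is.null(init$tree)) bl0 <- pmax(init$tree$edge.length, 1e-4)
    om <- pmax(init$omega, 1e-4)
    theta0 <- c(log(init$kappa),
                log(init$p[-K] / init$p[K]),
                log(om[1L]), log(pmax(diff(om), 1e-4)),
                log(0.05))
  } else {
    theta0 <- c(log(2), rep(0, K - 1),
                log(0.05), log(diff(c(0.05, 0.4, 2.0))[seq_len(K - 1)]),
                log(0.05))
  }

  expanded <- function(kappa, omegas, probs, delta) {
    gen <- switching_generator(kappa, omegas, probs, delta, pi)
    rev_eigen(gen$G, gen$stat)
  }
  negll <- function(par) {
    dec <- decode_bl(par, branch_mode, bl0, n_extra = 2 * K + 1)
    th <- decode_m3(dec$extra[seq_len(2 * K)], K)
    delta <- exp(dec$extra[2 * K + 1])
    gen <- switching_generator(th$kappa, th$omegas, th$probs, delta, pi)
    ed <- rev_eigen(gen$G, gen$stat)
    Pl <- lapply(dec$bl, function(t) prob_matrix(ed, t))
    -sum(pruning_site_loglik(prep$phy, Pl, prep$tips, gen$stat)$site_ll)
  }
  fit <- run_optim(negll, branch_mode, bl0, theta0, restarts, control)
  dec <- decode_bl(fit$par, branch_mode, bl0, n_extra = 2 * K + 1)
  th <- decode_m3(dec$extra[seq_len(2 * K)], K)
  delta <- exp(dec$extra[2 * K + 1])
  gen <- switching_generator(th$kappa, th$omegas, th$probs, delta, pi)
  ed <- rev_eigen(gen$G, gen$stat)
  Pl <- lapply(dec$bl, function(t) prob_matrix(ed, t))
  up <- pruning_site_loglik(prep$phy, Pl, prep$tips, gen$stat,
                            keep_partials = TRUE)
  marg <- node_marginals(prep$phy, Pl, up, gen$stat)
  # collapse 61K-state marginals to K class posteriors
  collapse <- function(m) {
    K_rows <- nrow(m) / 61L
    out <- matrix(0, K_rows, ncol(m))
    for (k in seq_len(K_rows))
      out[k, ] <- colSums(m[((k - 1L) * 61L + 1L):(k * 61L), , drop = FALSE])
    out
  }
  edge_post <- lapply(seq_len(nrow(prep$phy$edge)), function(e)
    collapse(marg[[prep$phy$edge[e, 2]]]))
  phy_out <- prep$phy; phy_out$edge.length <- dec$bl
  structure(list(model = "M3+S1",
                 lnL = -fit$value, minus_lnL = fit$value,
                 kappa = th$kappa, omega = th$omegas, p = th$probs,
                 delta = delta,
                 branch_class_posterior = edge_post,
                 tree = phy_out, pi = pi,
                 converged = fit$convergence == 0,
                 npar = length(fit$par)),
            class = "codon_model_fit")
}

#' Likelihood ratio test between nested codon model fits
#'
#' @param null_fit,alt_fit `codon_model_fit` objects (null nested in alt).
#' @param df Degrees of freedom; `NULL` computes the free-parameter
#'   difference (override available to mirror reported analyses that used
#'   a different parameter accounting).
#' @return List of class `lrt_result`: `statistic`, `df`, `p`, `clipped`.
#' @export
lrt <- function(null_fit, alt_fit, df = NULL) {
  stat <- 2 * (alt_fit$lnL - null_fit$lnL)
  clipped <- FALSE
  if (stat < 0) {
    if (stat < -1e-3)
      stop("negative LRT statistic (", format(stat),
           "): alternative fit did not converge; refit with restarts")
    stat <- 0; clipped <- TRUE
  }
  if (is.null(df)) df <- alt_fit$npar - null_fit$npar
  if (df < 1) stop("df must be >= 1")
  structure(list(statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 clipped = clipped),
            class = "lrt_result")
}

#' Partition positive-selection sites into dicot- and grass-specific lists
#'
#' For every site, the mean posterior of the highest-omega class is taken
#' over dicot-subtree branches and over grass-subtree branches (posterior
#' at each edge's child node). A site is dicot-specific when the dicot
#' mean exceeds `threshold` and the grass mean does not; symmetric for
#' grass; sites exceeding both are listed shared. Indices are reported in
#' original-alignment coordinates when a kept-column map is given.
#'
#' @param fit A `codon_model_fit` from [fit_m3_s1()].
#' @param stree A [species_tree()] giving the partition.
#' @param threshold Posterior threshold (default 0.5).
#' @param kept Optional kept-column map from [filter_columns()].
#' @return List: `dicot`, `grass`, `shared` (site indices), `omega_top`,
#'   plus per-site mean posteriors in `detail`.
#' @export
partition_positive_sites <- function(fit, stree, threshold = 0.5,
                                     kept = NULL) {
  K <- length(fit$omega)
  top <- K
  omega_top <- fit$omega[top]
  phy <- fit$tree
  part <- stree$partition
  idx <- tree_index(phy)
  edge_side <- vapply(seq_len(nrow(phy$edge)), function(e) {
    sp <- unique(part[species_of_gene(idx$tipsets[[phy$edge[e, 2]]])])
    if (length(sp) == 1L) sp else "mixed"
  }, character(1))
  nsites <- ncol(fit$branch_class_posterior[[1L]])
  mean_post <- function(side) {
    es <- which(edge_side == side)
    if (!length(es)) return(rep(NA_real_, nsites))
    rowMeans(do.call(cbind, lapply(es, function(e)
      fit$branch_class_posterior[[e]][top, ])))
  }
  dic <- mean_post("dicot"); gra <- mean_post("grass")
  to_coord <- function(sites) if (is.null(kept)) sites else kept[sites]
  if (omega_top <= 1) {
    sel_d <- integer(0); sel_g <- integer(0); sel_s <- integer(0)
  } else {
    sel_d <- which(dic > threshold & gra <= threshold)
    sel_g <- which(gra > threshold & dic <= threshold)
    sel_s <- which(dic > threshold & gra > threshold)
  }
  if (is.null(kept))
    warning("no kept-column map given; site indices are in filtered ",
            "alignment coordinates", call. = FALSE)
  list(dicot = to_coord(sel_d), grass = to_coord(sel_g),
       shared = to_coord(sel_s), omega_top = omega_top,
       detail = data.frame(site = if (is.null(kept)) seq_len(nsites)
                           else kept[seq_len(nsites)],
                           dicot_mean = dic, grass_mean = gra))
}

#' Read a newick tree with branch class labels (`#k` dialect)
#'
#' Parses the label convention in which a tip or internal node name is
#' suffixed with `#k` to assign the branch leading into it to class `k`
#' (unlabeled branches form class 0, the background).
#'
#' @param path Path to the newick file (or a newick string via `text`).
#' @param text Optional newick string instead of a file.
#' @return List with `tree` (labels stripped) and `branch_classes`
#'   (character vector over edges: `"0"`, `"1"`, ...).
#' @export
read_labeled_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  sentinel <- gsub("#([0-9]+)", "__CLASS\\1", text)
  tr <- ape::read.tree(text = sentinel)
  if (is.null(tr)) stop("could not parse newick input")
  cls_of <- function(labels) {
    k <- sub("^.*__CLASS([0-9]+)$", "\\1", labels)
    ifelse(grepl("__CLASS[0-9]+$", labels), k, "0")
  }
  tipcls <- cls_of(tr$tip.label)
  nodecls <- if (!is.null(tr$node.label)) cls_of(tr$node.label)
             else rep("0", tr$Nnode)
  tr$tip.label <- sub("__CLASS[0-9]+$", "", tr$tip.label)
  if (!is.null(tr$node.label))
    tr$node.label <- sub("__CLASS[0-9]+$", "", tr$node.label)
  ntip <- ape::Ntip(tr)
  branch_classes <- vapply(seq_len(nrow(tr$edge)), function(e) {
    child <- tr$edge[e, 2]
    if (child <= ntip) tipcls[child] else nodecls[child - ntip]
  }, character(1))
  list(tree = tr, branch_classes = branch_classes)
}

## ---- internal fitting helpers ------------------------------------------

prep_tree_data <- function(cds, tree, n_classes = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, names(cds)))
    stop("tree tip labels and sequence names differ")
  phy <- ape::reorder.phylo(tree, "postorder")
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  st <- codon_states(cds[phy$tip.label])
  nstates <- 61L * n_classes
  tips <- lapply(seq_len(ape::Ntip(phy)), function(i)
    tip_partial(st[i, ], nstates, n_classes))
  list(phy = phy, tips = tips, nsites = ncol(st))
}

# Branch-length block decoding for the three modes.
decode_bl <- function(par, branch_mode, bl0, n_extra) {
  if (branch_mode == "joint") {
    nb <- length(bl0)
    list(bl = exp(par[seq_len(nb)]), extra = par[nb + seq_len(n_extra)])
  } else if (branch_mode == "scale") {
    list(bl = bl0 * exp(par[1L]), extra = par[1L + seq_len(n_extra)])
  } else {
    list(bl = bl0, extra = par[seq_len(n_extra)])
  }
}

encode_start <- function(branch_mode, bl0, theta0) {
  if (branch_mode == "joint") c(log(bl0), theta0)
  else if (branch_mode == "scale") c(0, theta0)
  else theta0
}

bounds_for <- function(branch_mode, bl0, n_extra) {
  if (branch_mode == "joint") {
    list(lower = c(rep(log(1e-6), length(bl0)), rep(log(1e-4), n_extra)),
         upper = c(rep(log(30), length(bl0)), rep(log(100), n_extra)))
  } else if (branch_mode == "scale") {
    list(lower = c(log(1e-3), rep(log(1e-4), n_extra)),
         upper = c(log(1e3), rep(log(100), n_extra)))
  } else {
    list(lower = rep(log(1e-4), n_extra), upper = rep(log(100), n_extra))
  }
}

run_optim <- function(negll, branch_mode, bl0, theta0, restarts, control) {
  start <- encode_start(branch_mode, bl0, theta0)
  n_extra <- length(theta0)
  b <- bounds_for(branch_mode, bl0, n_extra)
  # mixture-weight logits (and any unconstrained coordinates) must not be
  # clamped at the positive-parameter bounds; widen for safety
  b$lower <- pmin(b$lower, -12); b$upper <- pmax(b$upper, 12)
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e8), control)
  best <- NULL
  for (r in seq_len(restarts + 1L)) {
    st <- if (r == 1L) start else start + stats::rnorm(length(start), 0, 0.3)
    st <- pmin(pmax(st, b$lower), b$upper)
    fit <- tryCatch(stats::optim(st, negll, method = "L-BFGS-B",
                                 lower = b$lower, upper = b$upper,
                                 control = ctrl),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("codon model optimization failed")
  best
}

# M3 parameter block: log kappa, (K-1) weight logits, log omega1 and
# (K-1) log increments -> kappa, ascending omegas, simplex probs.
decode_m3 <- function(extra, K) {
  kappa <- exp(extra[1L])
  logits <- extra[1L + seq_len(K - 1)]
  z <- c(exp(logits), 1)
  probs <- z / sum(z)
  om_par <- extra[K + seq_len(K)]
  omegas <- cumsum(exp(om_par))
  list(kappa = kappa, probs = probs, omegas = omegas)
}

# log of mixture likelihood per site from an nsites x K class log-lik matrix
log_mix <- function(sll, probs) {
  lw <- sweep(sll, 2, log(probs), "+")
  m <- apply(lw, 1, max)
  m + log(rowSums(exp(lw - m)))
}
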