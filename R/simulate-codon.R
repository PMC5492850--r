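## Codon alignment simulation along a gene tree under the GY94 family of
## models: one-ratio, branch-specific omega, M3 site mixtures, the
## Markov-modulated M3+S1 switching process, and a planted branch-site
## scenario used to exercise clade-specific positive-site detection.

#' Simulate a codon alignment with known truth
#'
#' Root codons are drawn from `pi`; evolution follows the GY94 rate matrix
#' (zero for multi-nucleotide changes, `kappa` for transitions, omega for
#' nonsynonymous changes, target-codon frequency multiplier), scaled so
#' branch lengths are expected substitutions per codon. Site classes are
#' i.i.d. from `probs` under M3; under M3+S1 the per-site class additionally
#' switches along branches at rate `delta` (simulated on the expanded
#' class-by-codon state space). The `branch_site` regime plants positive
#' selection (`omegas[3]`) at chosen sites on chosen branches only,
#' purifying selection elsewhere.
#'
#' @param gene_tree Rooted [ape::phylo] with branch lengths in expected
#'   substitutions per codon (see `branch_scale` in [sim_config()]).
#' @param cfg A [sim_config()]; regime and model parameters are read from it.
#' @param branch_classes Optional character vector over edges (`"dicot"`,
#'   `"grass"`, `"other"`) for the `branch` regime; derived from leaf
#'   species partitions when omitted.
#' @param site_indices Planted positive sites (`branch_site` regime).
#' @param fg_edges Edge indices under positive selection (`branch_site`).
#' @return List of class `codon_alignment_truth`: `cds` (named character
#'   vector of gap-free codon sequences), `protein`, `site_class` (true
#'   class per site at the root; for M3+S1 also `node_class`, a per-node by
#'   site matrix), `regime`, and regime-specific truth annotations.
#' @export
simulate_codon_alignment <- function(gene_tree, cfg, branch_classes = NULL,
                                     site_indices = NULL, fg_edges = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), !is.null(gene_tree$edge.length))
  set.seed(cfg$seed)
  simulate_codon_alignment_impl(gene_tree, cfg, branch_classes,
                                site_indices, fg_edges)
}

simulate_codon_alignment_impl <- function(gene_tree, cfg, branch_classes = NULL,
                                          site_indices = NULL, fg_edges = NULL) {
  phy <- ape::reorder.phylo(gene_tree, "cladewise")
  nsite <- cfg$n_codons
  pi <- cfg$pi
  tab <- codon_tables()
  regime <- cfg$regime

  if (regime == "M3S1") {
    res <- sim_switching(phy, cfg, nsite)
  } else {
    # per-site class assignment and per-edge-class rate matrices
    if (regime == "one_ratio") {
      site_class <- rep(1L, nsite)
      omega_for <- function(edge, class) cfg$omega[[1L]]
    } else if (regime == "M3") {
      site_class <- sample.int(length(cfg$probs), nsite, replace = TRUE,
                               prob = cfg$probs)
      omega_for <- function(edge, class) cfg$omegas[class]
    } else if (regime == "branch") {
      if (is.null(branch_classes))
        branch_classes <- edge_partition_classes(phy)
      site_class <- rep(1L, nsite)
      omega_for <- function(edge, class) {
        w <- cfg$omega[[branch_classes[edge]]]
        if (is.null(w)) cfg$omega[["other"]] else w
      }
    } else { # branch_site
      if (is.null(site_indices)) site_indices <- seq_len(min(10L, nsite))
      if (is.null(fg_edges)) stop("branch_site regime needs fg_edges")
      site_class <- rep(1L, nsite)
      site_class[site_indices] <- 2L
      omega_for <- function(edge, class) {
        if (class == 2L && edge %in% fg_edges) cfg$omegas[3L] else cfg$omegas[1L]
      }
    }
    res <- sim_classwise(phy, cfg, nsite, site_class, omega_for)
    res$site_class <- site_class
  }

  cds <- vapply(seq_len(ape::Ntip(phy)), function(i)
    paste(tab$codons[res$tip_states[i, ]], collapse = ""), character(1))
  names(cds) <- phy$tip.label
  out <- list(cds = cds, protein = translate_cds(cds),
              site_class = res$site_class, node_class = res$node_class,
              regime = regime, site_indices = site_indices,
              fg_edges = fg_edges, config = cfg)
  class(out) <- "codon_alignment_truth"
  out
}

# Derive an edge class from the leaf partition of the default species set:
# an edge is "dicot" ("grass") if every descendant leaf is a dicot (grass).
edge_partition_classes <- function(phy) {
  part <- ifelse(species_of_gene(phy$tip.label) %in% DICOT_LEAVES, "dicot",
                 ifelse(species_of_gene(phy$tip.label) %in% GRASS_LEAVES,
                        "grass", "other"))
  idx <- tree_index(phy)
  vapply(seq_len(nrow(phy$edge)), function(e) {
    tips <- idx$tipsets[[phy$edge[e, 2]]]
    cls <- unique(part[match(tips, phy$tip.label)])
    if (length(cls) == 1L) cls else "other"
  }, character(1))
}

# Simulate sites grouped by (site class); within a class all sites share
# the per-edge transition matrices, so states can be sampled vectorized.
# Matrix scaling must mirror the corresponding likelihood model: branch
# models scale each class's matrix to rate 1 on its own (branch lengths
# read as expected substitutions under that branch's omega); site-mixture
# models share one mixture scaling across classes; the planted branch-site
# scenario is anchored to the purifying background class.
sim_classwise <- function(phy, cfg, nsite, site_class, omega_for) {
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  states <- matrix(NA_integer_, nnode, nsite)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L, nsite, replace = TRUE, prob = cfg$pi)
  own_rate <- function(w)
    -sum(cfg$pi * diag(gy94_rate_matrix(cfg$kappa, w, cfg$pi, scale = FALSE)))
  rho_for <- switch(cfg$regime,
    M3 = {
      rho <- sum(cfg$probs * vapply(cfg$omegas, own_rate, numeric(1)))
      function(w) rho
    },
    branch_site = {
      rho <- own_rate(cfg$omegas[1L])
      function(w) rho
    },
    function(w) own_rate(w))
  eds <- list()  # cache eigendecompositions per omega value
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    t <- phy$edge.length[e]
    for (k in sort(unique(site_class))) {
      cols <- which(site_class == k)
      w <- omega_for(e, k)
      key <- sprintf("%.12g", w)
      if (is.null(eds[[key]]))
        eds[[key]] <- rev_eigen(
          gy94_rate_matrix(cfg$kappa, w, cfg$pi, scale = FALSE) / rho_for(w),
          cfg$pi)
      P <- prob_matrix(eds[[key]], t)
      ps <- states[parent, cols]
      for (s in unique(ps)) {
        sel <- cols[ps == s]
        states[child, sel] <- sample.int(61L, length(sel), replace = TRUE,
                                         prob = P[s, ])
      }
    }
  }
  list(tip_states = states[seq_len(ntip), , drop = FALSE],
       site_class = site_class, node_class = NULL)
}

# M3+S1: evolve the joint (class, codon) chain on 61*K states; record the
# class occupied at every node so class switches along branches are truth.
sim_switching <- function(phy, cfg, nsite) {
  K <- length(cfg$omegas)
  gen <- switching_generator(cfg$kappa, cfg$omegas, cfg$probs, cfg$delta, cfg$pi)
  ed <- rev_eigen(gen$G, gen$stat)
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  states <- matrix(NA_integer_, nnode, nsite)
  root <- ntip + 1L
  states[root, ] <- sample.int(61L * K, nsite, replace = TRUE, prob = gen$stat)
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1]; child <- phy$edge[e, 2]
    P <- prob_matrix(ed, phy$edge.length[e])
    ps <- states[parent, ]
    for (s in unique(ps)) {
      sel <- which(ps == s)
      states[child, sel] <- sample.int(61L * K, length(sel), replace = TRUE,
                                       prob = P[s, ])
    }
  }
  node_class <- (states - 1L) %/% 61L + 1L
  codon_states <- (states - 1L) %% 61L + 1L
  list(tip_states = codon_states[seq_len(ntip), , drop = FALSE],
       site_class = node_class[root, ], node_class = node_class)
}
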