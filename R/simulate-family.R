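## Gene family birth-death simulation along the species tree.  Every extant
## gene lineage duplicates at rate lambda and dies at rate mu as it travels
## down a species-tree branch; at a speciation node every live lineage
## enters both daughter branches.  The full event log (including events on
## subtrees that later went extinct) is kept, with an observability flag.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generator: the gene birth-death
#' process, the codon substitution regime, and the planted-artifact settings
#' exercised by the sequence filters.
#'
#' @param lambda Duplication (birth) rate per lineage per unit time.
#' @param mu Loss (death) rate per lineage per unit time.
#' @param n0 Founder gene count at the species-tree root (>= 1).
#' @param n_codons Alignment length in codons.
#' @param regime Codon model regime: `"one_ratio"`, `"branch"`, `"M3"`,
#'   `"M3S1"`, or `"branch_site"` (planted clade-specific positive sites).
#' @param kappa Transition/transversion ratio.
#' @param omega Single omega (one-ratio) or named vector for `"branch"`
#'   regimes (`dicot`, `grass`, `other`).
#' @param omegas,probs Site-class omega values and proportions (M3/M3+S1).
#' @param delta Class switching rate (M3+S1).
#' @param pi Codon frequencies; default F3x4 of uniform composition.
#' @param branch_scale Expected codon substitutions per unit of species-tree
#'   time; gene-tree branch lengths are time * branch_scale.
#' @param allele_identity Identity of planted allele-like copies (0, 1].
#' @param fragment_length Length (nt) of planted short fragments.
#' @param lineage_cap Abort threshold for the live lineage count.
#' @param seed Integer seed; fixed seed implies byte-identical outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(lambda = 0.1, mu = 0.05, n0 = 1, n_codons = 200,
                       regime = c("one_ratio", "branch", "M3", "M3S1", "branch_site"),
                       kappa = 2, omega = 0.2,
                       omegas = c(0.02, 0.5, 2.5), probs = c(0.6, 0.3, 0.1),
                       delta = 0.1, pi = NULL, branch_scale = 0.06,
                       allele_identity = 0.97, fragment_length = 300,
                       lineage_cap = 10000, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(lambda >= 0, mu >= 0, is.finite(lambda), is.finite(mu),
            n0 >= 1, n_codons >= 1, kappa > 0,
            allele_identity > 0, allele_identity <= 1)
  if (is.null(pi)) pi <- codon_frequencies("F3x4")
  if (abs(sum(pi) - 1) > 1e-8 || length(pi) != 61)
    stop("pi must be 61 sense-codon frequencies summing to 1")
  if (abs(sum(probs) - 1) > 1e-8) stop("class proportions must sum to 1")
  if (delta < 0) stop("negative switching rate")
  cfg <- list(lambda = lambda, mu = mu, n0 = n0, n_codons = n_codons,
              regime = regime, kappa = kappa, omega = omega, omegas = omegas,
              probs = probs, delta = delta, pi = pi,
              branch_scale = branch_scale, allele_identity = allele_identity,
              fragment_length = fragment_length, lineage_cap = lineage_cap,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene family history along the species tree
#'
#' Gillespie birth-death simulation of gene lineages travelling down the
#' species tree. Returns the pruned gene tree (extant lineages only, with
#' branch lengths in time units), the complete event log, and truth
#' copy-number counts at every species-tree node.
#'
#' @param stree A [species_tree()].
#' @param cfg A [sim_config()]; `lambda`, `mu`, `n0`, `lineage_cap`, `seed`
#'   are used here.
#' @param family_id Identifier used in gene names
#'   (`<species>_<family_id>_<serial>`).
#' @return A list of class `gene_family_history` with elements `tree`
#'   (pruned [ape::phylo] or `NULL` if the family went extinct), `events`
#'   (data.frame: event, species_branch_child, time, observable),
#'   `counts` (data.frame per species-tree node: node, n_true, n_observable),
#'   `observable_losses` (integer per species node: losses on the branch
#'   into that node that are visible from the pruned tree, i.e. whose
#'   lineage had a surviving sibling and whose branch lies within the
#'   species subtree spanned by the surviving family), and `genes`
#'   (data.frame: gene, species).
#' @export
simulate_family <- function(stree, cfg, family_id = "fam1") {
  set.seed(cfg$seed)
  simulate_family_impl(stree, cfg, family_id)
}

# Internal: does not touch the RNG seed, so callers can draw several
# families from one stream.
simulate_family_impl <- function(stree, cfg, family_id = "fam1") {
  phy <- stree$phylo
  idx <- tree_index(phy)
  lambda <- cfg$lambda; mu <- cfg$mu
  env <- new.env(parent = emptyenv())
  env$nodes <- list()   # gene-tree nodes: list(parent, type, sbranch, time, length)
  env$events <- list()
  # per-species-branch live-lineage counter backing the explosion guard
  env$branch_live <- integer(ape::Ntip(phy) + phy$Nnode)

  new_node <- function(parent, type, sbranch) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(id = id, parent = parent, type = type,
                            sbranch = sbranch, length = 0, species = NA_character_,
                            children = integer(0))
    if (!is.na(parent))
      env$nodes[[parent]]$children <- c(env$nodes[[parent]]$children, id)
    id
  }

  # evolve one lineage (gene node `gid`) along species branch into `snode`,
  # starting at `t0` (time from branch top), branch length L.
  evolve <- function(gid, snode, t0) {
    env$branch_live[snode] <- env$branch_live[snode] + 1L
    if (env$branch_live[snode] > cfg$lineage_cap)
      stop("birth-death explosion: live lineage count exceeded cap (",
           cfg$lineage_cap, "); lower lambda or the tree depth")
    is_leaf <- snode <= ape::Ntip(phy)
    L <- phy$edge.length[match(snode, phy$edge[, 2])]
    t <- t0
    repeat {
      rate <- lambda + mu
      wait <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (t + wait >= L) {
        env$nodes[[gid]]$length <- env$nodes[[gid]]$length + (L - t)
        if (is_leaf) {
          env$nodes[[gid]]$type <- "leaf"
          env$nodes[[gid]]$species <- phy$tip.label[snode]
        } else {
          env$nodes[[gid]]$type <- "speciation"
          for (child in idx$children[[snode]]) {
            cid <- new_node(gid, "pending", child)
            evolve(cid, child, 0)
          }
        }
        return(invisible())
      }
      t <- t + wait
      env$nodes[[gid]]$length <- env$nodes[[gid]]$length + wait
      if (stats::runif(1) < lambda / rate) {
        env$events[[length(env$events) + 1L]] <-
          list(event = "duplication", sbranch = snode, time = t, gnode = gid)
        env$nodes[[gid]]$type <- "duplication"
        c1 <- new_node(gid, "pending", snode)
        c2 <- new_node(gid, "pending", snode)
        # record which event produced this node, for observability flagging
        env$nodes[[gid]]$event_id <- length(env$events)
        evolve(c1, snode, t)
        evolve(c2, snode, t)
        return(invisible())
      } else {
        env$events[[length(env$events) + 1L]] <-
          list(event = "loss", sbranch = snode, time = t, gnode = gid)
        env$nodes[[gid]]$type <- "dead"
        return(invisible())
      }
    }
  }

  sroot <- idx$root
  roots <- integer(cfg$n0)
  for (f in seq_len(cfg$n0)) {
    rid <- new_node(NA_integer_, "speciation", NA_integer_)
    roots[f] <- rid
    for (child in idx$children[[sroot]]) {
      cid <- new_node(rid, "pending", child)
      evolve(cid, child, 0)
    }
  }

  nodes <- env$nodes
  n <- length(nodes)
  # survival: a node survives if it is an extant leaf or any child survives
  surv <- logical(n)
  ord <- order(vapply(nodes, function(x) x$id, integer(1)))  # ids are creation order
  for (id in rev(seq_len(n))) {
    nd <- nodes[[id]]
    surv[id] <- (nd$type == "leaf") || any(surv[nd$children])
  }

  # observability of duplication events: both daughter lineages survive
  events <- nodes_events_df(env$events, nodes, surv)

  # truth copy numbers per species node: lineages alive at the node
  counts <- truth_counts(phy, idx, nodes, surv)

  # observable losses per species branch: a surviving speciation lineage
  # whose daughter in one species branch left no extant descendants is a
  # loss that reconciliation of the pruned tree can recover -- provided
  # the branch lies inside the frame of the surviving family (the species
  # subtree under the LCA of surviving species).  A loss outside that
  # frame (e.g. a whole partition going extinct) leaves no trace in the
  # pruned tree and no inference method can see it.
  obs_loss <- integer(ape::Ntip(phy) + phy$Nnode)
  surviving_sp <- unique(vapply(nodes[vapply(nodes, function(x)
    x$type == "leaf", logical(1))], function(x) x$species, character(1)))
  if (length(surviving_sp)) {
    frame_root <- lca_nodes(idx, match(surviving_sp, phy$tip.label))
    for (nd in nodes) {
      if (nd$type == "speciation" && surv[nd$id]) {
        for (cid in nd$children) {
          if (!surv[cid]) {
            b <- nodes[[cid]]$sbranch
            if (b != frame_root && frame_root %in% idx$anc[[b]])
              obs_loss[b] <- obs_loss[b] + 1L
          }
        }
      }
    }
  }

  genes <- name_genes(nodes, surv, family_id)
  tree <- prune_gene_tree(nodes, surv, genes)

  res <- list(tree = tree, events = events, counts = counts,
              observable_losses = obs_loss,
              genes = genes$df, config = cfg, family_id = family_id)
  class(res) <- "gene_family_history"
  res
}

nodes_events_df <- function(events, nodes, surv) {
  if (!length(events)) {
    return(data.frame(event = character(0), species_branch_child = integer(0),
                      time = numeric(0), gnode = integer(0),
                      observable = logical(0)))
  }
  df <- do.call(rbind, lapply(events, function(e)
    data.frame(event = e$event, species_branch_child = e$sbranch,
               time = e$time, gnode = e$gnode)))
  df$observable <- vapply(seq_len(nrow(df)), function(i) {
    nd <- nodes[[df$gnode[i]]]
    if (df$event[i] == "duplication") {
      sum(surv[nd$children]) == 2L
    } else {
      FALSE  # a lineage that died left no extant descendants, by definition
    }
  }, logical(1))
  df
}

# Lineages crossing each species node.  n_true counts every live lineage;
# n_observable counts lineages with extant descendants within that node's
# subtree (what reconciliation of the pruned tree can recover).
truth_counts <- function(phy, idx, nodes, surv) {
  n_snode <- ape::Ntip(phy) + phy$Nnode
  n_true <- integer(n_snode)
  n_obs <- integer(n_snode)
  for (nd in nodes) {
    if (nd$type == "speciation" && !is.na(nd$sbranch)) {
      # reached the bottom of branch into snode nd$sbranch (an internal node)
      n_true[nd$sbranch] <- n_true[nd$sbranch] + 1L
      if (surv[nd$id]) n_obs[nd$sbranch] <- n_obs[nd$sbranch] + 1L
    } else if (nd$type == "leaf") {
      sp <- match(nd$species, phy$tip.label)
      n_true[sp] <- n_true[sp] + 1L
      n_obs[sp] <- n_obs[sp] + 1L
    } else if (is.na(nd$sbranch) && nd$type == "speciation") {
      n_true[idx$root] <- n_true[idx$root] + 1L
      if (surv[nd$id]) n_obs[idx$root] <- n_obs[idx$root] + 1L
    }
  }
  data.frame(node = seq_len(n_snode), n_true = n_true, n_observable = n_obs)
}

name_genes <- function(nodes, surv, family_id) {
  leaf_ids <- which(vapply(nodes, function(x) x$type == "leaf", logical(1)))
  sp <- vapply(leaf_ids, function(i) nodes[[i]]$species, character(1))
  serial <- stats::ave(seq_along(leaf_ids), sp, FUN = seq_along)
  labels <- sprintf("%s_%s_%d", sp, family_id, serial)
  df <- data.frame(gene = labels, species = sp)
  list(df = df, by_node = stats::setNames(labels, leaf_ids))
}

# Collapse the full simulated node set into a pruned ape::phylo over extant
# leaves, suppressing non-surviving children and unifurcations.
prune_gene_tree <- function(nodes, surv, genes) {
  leaf_nodes <- which(vapply(nodes, function(x) x$type == "leaf", logical(1)))
  if (!length(leaf_nodes)) return(NULL)
  roots <- which(vapply(nodes, function(x) is.na(x$parent), logical(1)) & surv)
  # Build one tree if a single founder survives; multiple founders yield a
  # forest returned as a list of phylo trees.
  build <- function(rid) {
    # recursive newick construction with accumulated lengths
    rec <- function(id, acc) {
      nd <- nodes[[id]]
      len <- acc + nd$length
      kids <- nd$children[surv[nd$children]]
      if (nd$type == "leaf") {
        return(sprintf("%s:%.10g", genes$by_node[[as.character(id)]], len))
      }
      if (length(kids) == 1L) return(rec(kids, len))
      paste0("(", paste(vapply(kids, rec, character(1), acc = 0),
                        collapse = ","), "):", sprintf("%.10g", len))
    }
    nd <- nodes[[rid]]
    kids <- nd$children[surv[nd$children]]
    if (length(kids) == 1L) {
      txt <- rec(kids, 0)
      if (!grepl("^\\(", txt)) {  # single surviving leaf: degenerate tree
        return(NULL)
      }
    } else {
      txt <- paste0("(", paste(vapply(kids, rec, character(1), acc = 0),
                               collapse = ","), ")")
    }
    # strip trailing root branch length if present
    txt <- sub(":[0-9.eE+-]+$", "", txt)
    ape::read.tree(text = paste0(txt, ";"))
  }
  trees <- Filter(Negate(is.null), lapply(roots, build))
  if (!length(trees)) return(NULL)
  if (length(trees) == 1L) trees[[1L]] else trees
}

#' Species of a gene identifier
#'
#' Gene identifiers follow `<species>_<familyid>_<serial>`; the species tag
#' is the first underscore-delimited field.
#'
#' @param gene Character vector of gene ids.
#' @return Character vector of species tags.
#' @export
species_of_gene <- function(gene) {
  sub("_.*$", "", gene)
}
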