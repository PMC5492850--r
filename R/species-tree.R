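## The fixed 11-taxon reference species tree (six dicots, five grasses) and
## utilities for navigating it during reconciliation.

DICOT_LEAVES <- c("Ath", "Bra", "Gma", "Mtr", "Ptr", "Rco")
GRASS_LEAVES <- c("Bdi", "Osa", "Sit", "Sbi", "Zma")

#' Build the default dicot/grass species tree
#'
#' Returns the fixed rooted 11-taxon species tree used as the reference frame
#' for orthology, reconciliation and event classification: six dicots
#' (Arabidopsis thaliana, Brassica rapa, Glycine max, Medicago truncatula,
#' Populus trichocarpa, Ricinus communis) and five grasses (Brachypodium
#' distachyon, Oryza sativa, Setaria italica, Sorghum bicolor, Zea mays),
#' each partition monophyletic, joined at the root.
#'
#' @param branch_length Length assigned to every branch (abstract time
#'   units; the tree is not calibrated in Mya). Default 1.
#' @return An object of class `species_tree`: a list with elements `phylo`
#'   (an [ape::phylo]), `partition` (named character vector mapping each leaf
#'   to `"dicot"` or `"grass"`), and the node numbers `mrca_all`,
#'   `mrca_dicot`, `mrca_grass`.
#' @export
build_default_species_tree <- function(branch_length = 1) {
  stopifnot(branch_length > 0)
  nwk <- "(((Ath,Bra),((Gma,Mtr),(Ptr,Rco))),((Bdi,Osa),(Sit,(Sbi,Zma))));"
  phy <- ape::read.tree(text = nwk)
  phy$edge.length <- rep(branch_length, nrow(phy$edge))
  species_tree(phy, partition = c(stats::setNames(rep("dicot", 6), DICOT_LEAVES),
                                  stats::setNames(rep("grass", 5), GRASS_LEAVES)))
}

#' Construct a species_tree object from a rooted phylo
#'
#' @param phy Rooted binary [ape::phylo] with positive branch lengths.
#' @param partition Named character vector leaf -> `"dicot"`/`"grass"`.
#' @return A `species_tree` object.
#' @export
species_tree <- function(phy, partition) {
  if (!ape::is.rooted(phy) || !ape::is.binary(phy))
    stop("species tree must be rooted and binary")
  if (!setequal(names(partition), phy$tip.label))
    stop("partition labels must cover exactly the tree's leaves")
  if (!is.null(phy$edge.length) && any(phy$edge.length <= 0))
    stop("species tree branch lengths must be > 0")
  partition <- partition[phy$tip.label]
  st <- list(phylo = phy, partition = partition,
             mrca_all = ape::Ntip(phy) + 1L,
             mrca_dicot = clade_mrca(phy, names(partition)[partition == "dicot"]),
             mrca_grass = clade_mrca(phy, names(partition)[partition == "grass"]))
  class(st) <- "species_tree"
  st
}

#' @export
print.species_tree <- function(x, ...) {
  cat("species_tree:", ape::Ntip(x$phylo), "leaves (",
      sum(x$partition == "dicot"), "dicot /",
      sum(x$partition == "grass"), "grass )\n")
  invisible(x)
}

clade_mrca <- function(phy, tips) {
  if (length(tips) == 1L) return(match(tips, phy$tip.label))
  ape::getMRCA(phy, tips)
}

# Per-node ancestor chains (node -> vector of ancestors, self first, root
# last) and node depths.  Used for LCA lookups during reconciliation.
tree_index <- function(phy) {
  n_node <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, n_node)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- ape::Ntip(phy) + 1L
  anc <- vector("list", n_node)
  depth <- integer(n_node)
  for (v in seq_len(n_node)) {
    chain <- v
    while (!is.na(parent[chain[length(chain)]]))
      chain <- c(chain, parent[chain[length(chain)]])
    anc[[v]] <- chain
    depth[v] <- length(chain) - 1L
  }
  # leaf sets below each node
  tipsets <- vector("list", n_node)
  for (i in seq_len(ape::Ntip(phy))) tipsets[[i]] <- phy$tip.label[i]
  ord <- rev(postorder_nodes(phy))
  for (v in rev(ord)) {
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    if (length(ch)) tipsets[[v]] <- unlist(tipsets[ch], use.names = FALSE)
  }
  list(parent = parent, anc = anc, depth = depth, root = root,
       tipsets = tipsets, children = lapply(seq_len(n_node), function(v)
         phy$edge[phy$edge[, 1] == v, 2]))
}

# Internal+tip nodes in postorder (children before parents).
postorder_nodes <- function(phy) {
  phy <- ape::reorder.phylo(phy, "postorder")
  unique(c(phy$edge[, 2], ape::Ntip(phy) + 1L))
}

# LCA of a set of nodes using precomputed ancestor chains.
lca_nodes <- function(idx, nodes) {
  chain <- idx$anc[[nodes[1L]]]
  for (v in nodes[-1L]) chain <- chain[chain %in% idx$anc[[v]]]
  chain[1L]
}
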