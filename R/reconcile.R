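## Gene-tree/species-tree reconciliation by LCA mapping, duplication/loss
## inference with ancient vs recent classification, minimize-duplication
## rooting, and dicot/grass subgroup detection.

#' Reconcile a rooted gene tree against the species tree
#'
#' Maps every gene-tree node to the species-tree LCA of the species under
#' it. A node is a duplication iff it maps to the same species node as one
#' of its children (equivalently, its children's species sets overlap).
#' Implied losses are counted and placed on species-tree branches: when a
#' lineage maps from species node `a` down to descendant `d`, each species
#' node passed on the way contributes one loss on its off-path daughter
#' branch (for a duplication, the branch below `a` itself is also passed).
#'
#' @param gtree Rooted [ape::phylo]; tip labels parse to species via
#'   [species_of_gene()].
#' @param stree A [species_tree()].
#' @return List of class `reconciled_tree`: `gtree`, `map` (species node per
#'   gene node), `is_dup` (logical per gene node), `n_dup`, `n_loss`,
#'   `loss_by_branch` (integer per species node = losses on the branch into
#'   it), `gain_by_branch` (duplications mapped to each species node;
#'   root-mapped duplications are "pre-split").
#' @export
reconcile <- function(gtree, stree) {
  sphy <- stree$phylo
  sidx <- tree_index(sphy)
  ntip <- ape::Ntip(gtree)
  nnode_all <- ntip + gtree$Nnode
  leafsp <- match(species_of_gene(gtree$tip.label), sphy$tip.label)
  if (anyNA(leafsp))
    stop("gene tree contains species absent from the species tree: ",
         paste(unique(species_of_gene(gtree$tip.label)[is.na(leafsp)]),
               collapse = ", "))
  M <- integer(nnode_all)
  M[seq_len(ntip)] <- leafsp
  is_dup <- logical(nnode_all)
  children <- lapply(seq_len(nnode_all), function(v)
    gtree$edge[gtree$edge[, 1] == v, 2])
  for (v in postorder_nodes(gtree)) {
    ch <- children[[v]]
    if (!length(ch)) next
    M[v] <- lca_nodes(sidx, M[ch])
    is_dup[v] <- any(M[ch] == M[v])
  }
  n_snode <- ape::Ntip(sphy) + sphy$Nnode
  loss_by_branch <- integer(n_snode)
  gain_by_branch <- integer(n_snode)
  pre_split_gains <- 0L
  for (v in which(is_dup)) {
    if (M[v] == sidx$root) pre_split_gains <- pre_split_gains + 1L
    else gain_by_branch[M[v]] <- gain_by_branch[M[v]] + 1L
  }
  n_loss <- 0L
  for (v in seq_len(nnode_all)) {
    ch <- children[[v]]
    for (c in ch) {
      path <- path_down(sidx, M[v], M[c])  # nodes from M[v] to M[c]
      # species nodes whose off-path daughter receives a loss:
      # intermediate nodes always; M[v] itself additionally when v is a
      # duplication (the copy was already present at M[v])
      if (length(path) < 2 && !is_dup[v]) next
      pass <- if (is_dup[v]) path[-length(path)] else
        path[-c(1L, length(path))]
      for (k in seq_along(pass)) {
        s <- pass[k]
        onpath <- path[match(s, path) + 1L]
        off <- setdiff(sidx$children[[s]], onpath)
        for (o in off) loss_by_branch[o] <- loss_by_branch[o] + 1L
        n_loss <- n_loss + length(off)
      }
    }
  }
  structure(list(gtree = gtree, map = M, is_dup = is_dup,
                 n_dup = sum(is_dup), n_loss = n_loss,
                 loss_by_branch = loss_by_branch,
                 gain_by_branch = gain_by_branch,
                 pre_split_gains = pre_split_gains,
                 species_tree = stree),
            class = "reconciled_tree")
}

# Nodes on the species-tree path from ancestor a down to descendant d
# (inclusive both ends). a must be an ancestor-or-equal of d.
path_down <- function(sidx, a, d) {
  chain <- sidx$anc[[d]]
  pos <- match(a, chain)
  if (is.na(pos)) stop("invalid reconciliation path")
  rev(chain[seq_len(pos)])
}

#' Root a gene tree against the species tree
#'
#' Default method roots on the edge minimizing total inferred duplications
#' plus losses under LCA reconciliation; ties prefer a root whose two sides
#' split dicot species from grass species cleanly, then the edge leading to
#' the smallest leaf id. Alternatives: midpoint rooting, or an explicit
#' outgroup.
#'
#' @param gtree An [ape::phylo] (unrooted or arbitrarily rooted).
#' @param stree A [species_tree()] (required for `"minimize-duplication"`).
#' @param method `"minimize-duplication"` (default), `"midpoint"`, or
#'   `"outgroup"`.
#' @param outgroup Tip label for `method = "outgroup"`.
#' @return Rooted [ape::phylo].
#' @export
root_gene_tree <- function(gtree, stree = NULL,
                           method = c("minimize-duplication", "midpoint",
                                      "outgroup"),
                           outgroup = NULL) {
  method <- match.arg(method)
  if (method == "midpoint") return(phangorn::midpoint(gtree))
  if (method == "outgroup") {
    if (is.null(outgroup) || !outgroup %in% gtree$tip.label)
      stop("outgroup id absent from the gene tree")
    return(ape::root(gtree, outgroup = outgroup, resolve.root = TRUE))
  }
  if (is.null(stree)) stop("minimize-duplication rooting needs a species tree")
  un <- ape::unroot(gtree)
  if (is.null(un$edge.length)) un$edge.length <- rep(1, nrow(un$edge))
  cands <- lapply(seq_len(nrow(un$edge)), function(e)
    root_on_edge(un, e))
  part <- stree$partition
  best <- NULL
  for (cand in cands) {
    rec <- reconcile(cand, stree)
    cost <- rec$n_dup + rec$n_loss
    clean <- root_bipartition_cleanliness(cand, part)
    first_tip <- min(root_side_min_tips(cand))
    key <- list(cost = cost, clean = clean, tip = first_tip)
    if (is.null(best) || cost < best$key$cost ||
        (cost == best$key$cost && clean > best$key$clean) ||
        (cost == best$key$cost && clean == best$key$clean &&
         first_tip < best$key$tip)) {
      best <- list(tree = cand, key = key)
    }
  }
  tr <- best$tree
  attr(tr, "rooting") <- "minimize-duplication"
  tr
}

# Root an unrooted phylo in the middle of edge e.
root_on_edge <- function(un, e) {
  child <- un$edge[e, 2]
  len <- un$edge.length[e]
  phytools::reroot(un, node.number = child, position = len / 2)
}

# 1 if the root bipartition separates dicot species from grass species
# exactly (each side pure at the species-partition level), else 0.
root_bipartition_cleanliness <- function(rooted, part) {
  ch <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  idx <- tree_index(rooted)
  sides <- lapply(ch, function(v)
    unique(part[species_of_gene(idx$tipsets[[v]])]))
  if (all(lengths(sides) == 1L) &&
      length(unique(unlist(sides))) == length(sides)) 1 else 0
}

root_side_min_tips <- function(rooted) {
  ch <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  idx <- tree_index(rooted)
  vapply(ch, function(v) min(idx$tipsets[[v]]), character(1))
}

#' Detect maximal dicot/grass subgroups in a rooted gene tree
#'
#' Returns the maximal monophyletic clades whose leaves are all dicot or
#' all grass. Singleton leaves form singleton subgroups. Clades under
#' `min_support` are returned but flagged low-support.
#'
#' @param rooted Rooted [ape::phylo] (optionally with `node.label`
#'   bootstrap supports).
#' @param stree A [species_tree()] giving the partition.
#' @param min_support Support threshold for the low-support flag.
#' @return List of subgroups: `partition`, `members`, `species`, `node`,
#'   `support`, `low_support`.
#' @export
detect_subgroups <- function(rooted, stree, min_support = 0) {
  part <- stree$partition
  ntip <- ape::Ntip(rooted)
  nnode_all <- ntip + rooted$Nnode
  idx <- tree_index(rooted)
  leafpart <- part[species_of_gene(rooted$tip.label)]
  purity <- character(nnode_all)  # "dicot", "grass" or "" (mixed)
  for (v in postorder_nodes(rooted)) {
    ch <- idx$children[[v]]
    if (!length(ch)) purity[v] <- leafpart[v]
    else {
      u <- unique(purity[ch])
      purity[v] <- if (length(u) == 1L && nzchar(u)) u else ""
    }
  }
  maximal <- which(nzchar(purity) &
                     vapply(seq_len(nnode_all), function(v) {
                       p <- idx$parent[v]
                       is.na(p) || !nzchar(purity[p])
                     }, logical(1)))
  supports <- node_supports(rooted)
  lapply(maximal, function(v) {
    members <- idx$tipsets[[v]]
    sup <- if (v > ntip) supports[v - ntip] else NA_real_
    list(partition = purity[v], members = members,
         species = unique(species_of_gene(members)), node = v,
         support = sup,
         low_support = !is.na(sup) && sup < min_support)
  })
}

node_supports <- function(rooted) {
  if (is.null(rooted$node.label)) return(rep(NA_real_, rooted$Nnode))
  suppressWarnings(as.numeric(rooted$node.label))
}
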