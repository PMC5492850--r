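## Event tables (duplications classified ancient/recent, losses by the
## subgroup-absence rule and by reconciliation), ancestral copy-number
## profiles, and Table-1-style family summaries.

#' Infer duplication and loss events for one COG tree
#'
#' Duplications come from LCA reconciliation and are classified by where
#' they map: the species root gives `pre-split`; within the dicot (grass)
#' side, a duplication spanning at most `recent_max_species` extant species
#' is `recent-dicot` (`recent-grass`), otherwise `ancient-dicot`
#' (`ancient-grass`). Losses are reported two ways: (a) the
#' subgroup-absence rule - within each dicot (grass) subgroup, every
#' partition species missing from the subgroup counts one loss - and (b)
#' reconciliation-implied per-branch losses, used for copy-number profiles.
#'
#' @param rooted Rooted gene tree ([ape::phylo]).
#' @param stree A [species_tree()].
#' @param subgroups Optional precomputed [detect_subgroups()] result.
#' @param recent_max_species Largest number of extant species a
#'   duplication may span and still be called recent (default 2).
#' @param confirmed_absent Optional named list (or NULL): per partition
#'   (`dicot`, `grass`), the species whose absences have been externally
#'   confirmed. When supplied, subgroup-absence losses are only called for
#'   confirmed species — the hook for manual validation of losses.
#' @param cog_id Identifier written into the event rows.
#' @return List of class `event_inference`: `events` (data.frame: cog_id,
#'   event, class, species, gnode), `reconciliation` (the
#'   `reconciled_tree`), `subgroups`.
#' @export
infer_events <- function(rooted, stree, subgroups = NULL,
                         recent_max_species = 2, confirmed_absent = NULL,
                         cog_id = "COG") {
  rec <- reconcile(rooted, stree)
  if (is.null(subgroups)) subgroups <- detect_subgroups(rooted, stree)
  sidx <- tree_index(stree$phylo)
  gidx <- tree_index(rooted)
  part <- stree$partition
  rows <- list()
  for (v in which(rec$is_dup)) {
    s <- rec$map[v]
    spset <- unique(species_of_gene(gidx$tipsets[[v]]))
    if (s == sidx$root) {
      cls <- "pre-split"
    } else {
      side <- if (stree$mrca_dicot %in% sidx$anc[[s]]) "dicot" else "grass"
      age <- if (length(spset) <= recent_max_species) "recent" else "ancient"
      cls <- paste(age, side, sep = "-")
    }
    rows[[length(rows) + 1L]] <-
      data.frame(cog_id = cog_id, event = "duplication", class = cls,
                 species = paste(sort(spset), collapse = ","), gnode = v)
  }
  for (sg in subgroups) {
    have <- sg$species
    all_sp <- names(part)[part == sg$partition]
    missing_sp <- setdiff(all_sp, have)
    if (!is.null(confirmed_absent))
      missing_sp <- intersect(missing_sp,
                              confirmed_absent[[sg$partition]])
    for (miss in missing_sp) {
      rows[[length(rows) + 1L]] <-
        data.frame(cog_id = cog_id, event = "loss",
                   class = sg$partition, species = miss,
                   gnode = sg$node)
    }
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cog_id = character(0), event = character(0),
               class = character(0), species = character(0),
               gnode = integer(0))
  structure(list(events = events, reconciliation = rec,
                 subgroups = subgroups),
            class = "event_inference")
}

#' Reconstruct ancestral copy numbers and per-branch gains/losses
#'
#' Sums reconciliations over COGs into a per-species-tree-node gene count
#' with per-branch gains and losses. For each COG the founding lineage
#' contributes one gene at its mapped origin; a COG whose root maps below
#' the species root enters as a gain on the branch into its origin node, so
#' the balance `count(child) = count(parent) + gains - losses` holds on
#' every branch. Leaf counts are cross-checked against the genes actually
#' present; any violation is an internal error naming the COG.
#'
#' @param reconciliations List of `reconciled_tree` objects (one per COG).
#' @param stree A [species_tree()].
#' @return List of class `copy_number_profile`: `counts` (data.frame: node,
#'   label, count), `branches` (data.frame: child node, gains, losses).
#' @export
reconstruct_copy_numbers <- function(reconciliations, stree) {
  sphy <- stree$phylo
  sidx <- tree_index(sphy)
  n_snode <- ape::Ntip(sphy) + sphy$Nnode
  gains <- integer(n_snode)
  losses <- integer(n_snode)
  root_count <- 0L
  for (rec in reconciliations) {
    gains <- gains + rec$gain_by_branch
    losses <- losses + rec$loss_by_branch
    origin <- rec$map[ape::Ntip(rec$gtree) + 1L]
    if (origin == sidx$root) {
      root_count <- root_count + 1L + rec$pre_split_gains
    } else {
      # family origin enters as a gain on the branch into its origin node
      gains[origin] <- gains[origin] + 1L + rec$pre_split_gains
    }
  }
  counts <- integer(n_snode)
  counts[sidx$root] <- root_count
  for (v in rev(postorder_nodes(sphy))) {
    for (c in sidx$children[[v]]) {
      counts[c] <- counts[v] + gains[c] - losses[c]
    }
  }
  # balance is enforced by construction; verify leaf counts against the
  # genes present in each reconciled tree
  leaf_truth <- integer(ape::Ntip(sphy))
  for (rec in reconciliations) {
    sp <- match(species_of_gene(rec$gtree$tip.label), sphy$tip.label)
    tb <- table(factor(sp, levels = seq_len(ape::Ntip(sphy))))
    leaf_truth <- leaf_truth + as.integer(tb)
  }
  bad <- which(counts[seq_len(ape::Ntip(sphy))] != leaf_truth)
  if (length(bad))
    stop("inconsistent reconciliation: leaf count mismatch for species ",
         paste(sphy$tip.label[bad], collapse = ", "))
  labels <- c(sphy$tip.label, rep(NA_character_, sphy$Nnode))
  labels[sidx$root] <- "MRCA_all"
  labels[stree$mrca_dicot] <- "MRCA_dicot"
  labels[stree$mrca_grass] <- "MRCA_grass"
  structure(list(
    counts = data.frame(node = seq_len(n_snode), label = labels,
                        count = counts),
    branches = data.frame(child = setdiff(seq_len(n_snode), sidx$root),
                          gains = gains[setdiff(seq_len(n_snode), sidx$root)],
                          losses = losses[setdiff(seq_len(n_snode),
                                                  sidx$root)])),
    class = "copy_number_profile")
}

#' Annotate a reconciled gene tree with event labels
#'
#' Returns the gene tree with internal node labels `D` (duplication) or
#' `S` (speciation), suitable for writing as an annotated newick.
#'
#' @param rec A `reconciled_tree` from [reconcile()].
#' @return An [ape::phylo] with `node.label` set.
#' @export
annotate_events <- function(rec) {
  gt <- rec$gtree
  ntip <- ape::Ntip(gt)
  lab <- ifelse(rec$is_dup[(ntip + 1L):(ntip + gt$Nnode)], "D", "S")
  gt$node.label <- lab
  gt
}

#' Summarize event tables per COG and overall
#'
#' Produces the duplication/loss summary with the conventional column
#' structure: ancient dicot- and grass-specific duplications, recent dicot
#' and grass species-specific duplications, dicot- and grass-specific
#' losses, plus a grand totals row.
#'
#' @param event_tables List of data.frames as produced by [infer_events()]
#'   (the `events` element), or one combined data.frame.
#' @return Data frame with one row per COG and a `TOTAL` row.
#' @export
summarize_family <- function(event_tables) {
  if (is.data.frame(event_tables)) event_tables <- list(event_tables)
  ev <- do.call(rbind, event_tables)
  cols <- c(ancient_dicot = "ancient-dicot", ancient_grass = "ancient-grass",
            recent_dicot = "recent-dicot", recent_grass = "recent-grass",
            pre_split = "pre-split")
  cogs <- if (!is.null(ev) && nrow(ev)) sort(unique(ev$cog_id)) else character(0)
  out <- lapply(cogs, function(cid) {
    e <- ev[ev$cog_id == cid, , drop = FALSE]
    dup <- e[e$event == "duplication", , drop = FALSE]
    loss <- e[e$event == "loss", , drop = FALSE]
    row <- data.frame(cog_id = cid)
    for (nm in names(cols)) row[[nm]] <- sum(dup$class == cols[[nm]])
    row$loss_dicot <- sum(loss$class == "dicot")
    row$loss_grass <- sum(loss$class == "grass")
    row
  })
  out <- if (length(out)) do.call(rbind, out) else
    data.frame(cog_id = character(0), ancient_dicot = integer(0),
               ancient_grass = integer(0), recent_dicot = integer(0),
               recent_grass = integer(0), pre_split = integer(0),
               loss_dicot = integer(0), loss_grass = integer(0))
  total <- out[0, ]
  if (nrow(out)) {
    total <- data.frame(cog_id = "TOTAL",
                        t(colSums(out[, -1, drop = FALSE])))
    names(total) <- names(out)
  } else {
    total <- data.frame(cog_id = "TOTAL", ancient_dicot = 0L,
                        ancient_grass = 0L, recent_dicot = 0L,
                        recent_grass = 0L, pre_split = 0L,
                        loss_dicot = 0L, loss_grass = 0L)
  }
  rbind(out, total)
}
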