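## COG construction from the BeT graph: triangles of reciprocal BeT edges
## spanning three species are enumerated and merged while they share an
## edge; genes attached only by asymmetric edges become satellites.

#' Build Clusters of Orthologous Groups from a BeT graph
#'
#' Enumerates all triangles of reciprocal BeT edges spanning three distinct
#' species, merges triangles transitively while they share an edge, and
#' attaches genes connected only by asymmetric BeT edges as non-core
#' satellites. COGs are ordered deterministically by smallest core member
#' id; no gene appears in two COGs' core sets.
#'
#' @param bets A `bet_graph` from [compute_bets()].
#' @return List of `cog` objects: each a list with `id`, `core` (gene ids),
#'   `satellites`, `species` (table over core members), `edges` (the BeT
#'   edges among members).
#' @export
build_cogs <- function(bets) {
  if (!nrow(bets)) return(list())
  sp <- stats::setNames(species_of_gene(unique(c(bets$from, bets$to))),
                        unique(c(bets$from, bets$to)))
  # undirected reciprocal edge set
  rec <- bets[bets$reciprocal, , drop = FALSE]
  if (!nrow(rec)) return(list())
  und <- unique(data.frame(
    a = pmin(rec$from, rec$to), b = pmax(rec$from, rec$to)))
  g <- igraph::graph_from_data_frame(und, directed = FALSE)
  tri <- igraph::triangles(g)
  if (!length(tri)) return(list())
  vn <- igraph::V(g)$name
  tri <- matrix(vn[as.integer(tri)], ncol = 3, byrow = TRUE)
  # keep triangles spanning three distinct species
  keep <- apply(tri, 1L, function(r) length(unique(sp[r])) == 3L)
  tri <- tri[keep, , drop = FALSE]
  if (!nrow(tri)) return(list())
  # merge triangles sharing an (undirected) edge: connected components of
  # the triangle-overlap relation, found by hashing each triangle's edges
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  tri_edges <- cbind(ekey(tri[, 1], tri[, 2]),
                     ekey(tri[, 1], tri[, 3]),
                     ekey(tri[, 2], tri[, 3]))
  edge_ids <- unique(as.vector(tri_edges))
  inc <- igraph::make_empty_graph(n = nrow(tri) + length(edge_ids),
                                  directed = FALSE)
  # bipartite graph triangle <-> edge; components give the merge
  eidx <- match(as.vector(tri_edges), edge_ids) + nrow(tri)
  tidx <- rep(seq_len(nrow(tri)), times = 3L)
  inc <- igraph::add_edges(inc, rbind(tidx, eidx))
  comp <- igraph::components(inc)$membership[seq_len(nrow(tri))]

  cogs <- lapply(sort(unique(comp)), function(k) {
    genes <- sort(unique(as.vector(tri[comp == k, , drop = FALSE])))
    genes
  })
  # attach satellites: genes outside every core, linked by any BeT edge to
  # exactly one COG's core
  core_of <- stats::setNames(rep(seq_along(cogs), lengths(cogs)),
                             unlist(cogs))
  sats <- vector("list", length(cogs))
  noncore <- setdiff(unique(c(bets$from, bets$to)), names(core_of))
  for (gid in noncore) {
    nb <- unique(c(bets$to[bets$from == gid], bets$from[bets$to == gid]))
    hit <- unique(core_of[intersect(nb, names(core_of))])
    if (length(hit) == 1L) sats[[hit]] <- c(sats[[hit]], gid)
  }
  out <- lapply(seq_along(cogs), function(k) {
    members <- c(cogs[[k]], sats[[k]])
    ed <- bets[bets$from %in% members & bets$to %in% members, , drop = FALSE]
    structure(list(id = NA_character_, core = cogs[[k]],
                   satellites = sort(unique(sats[[k]])),
                   species = table(species_of_gene(cogs[[k]])),
                   edges = ed),
              class = "cog")
  })
  # deterministic order by smallest core member
  out <- out[order(vapply(out, function(x) x$core[1L], character(1)))]
  for (k in seq_along(out)) out[[k]]$id <- sprintf("COG%03d", k)
  out
}

#' Per-COG coverage report
#'
#' Flags, per COG, how many of the six dicot and five grass species are
#' represented among core members, and whether the expectation of at least
#' six dicot and five grass members holds. Never filters.
#'
#' @param cogs List of `cog` objects from [build_cogs()].
#' @param stree A [species_tree()] giving the dicot/grass partition.
#' @return Data frame: cog_id, n_core, n_satellite, dicot_species (of 6),
#'   grass_species (of 5), dicot_members, grass_members, flag
#'   (`"complete"`/`"incomplete"`).
#' @export
cog_report <- function(cogs, stree) {
  if (!length(cogs))
    return(data.frame(cog_id = character(0), n_core = integer(0),
                      n_satellite = integer(0), dicot_species = integer(0),
                      grass_species = integer(0), dicot_members = integer(0),
                      grass_members = integer(0), flag = character(0)))
  part <- stree$partition
  n_dicot <- sum(part == "dicot"); n_grass <- sum(part == "grass")
  do.call(rbind, lapply(cogs, function(cg) {
    sp <- species_of_gene(cg$core)
    pt <- part[sp]
    ds <- length(unique(sp[pt == "dicot"]))
    gs <- length(unique(sp[pt == "grass"]))
    dm <- sum(pt == "dicot", na.rm = TRUE)
    gm <- sum(pt == "grass", na.rm = TRUE)
    data.frame(cog_id = cg$id, n_core = length(cg$core),
               n_satellite = length(cg$satellites),
               dicot_species = ds, grass_species = gs,
               dicot_members = dm, grass_members = gm,
               flag = if (dm >= n_dicot && gm >= n_grass) "complete"
                      else "incomplete")
  }))
}

#' Write COG membership as TSV and per-COG DOT graphs
#'
#' @param cogs List of `cog` objects.
#' @param out_dir Output directory.
#' @return Invisibly, the membership TSV path.
#' @export
write_cog_membership <- function(cogs, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- do.call(rbind, lapply(cogs, function(cg) {
    rbind(
      if (length(cg$core))
        data.frame(cog_id = cg$id, gene_id = cg$core,
                   species = species_of_gene(cg$core), role = "core")
      else NULL,
      if (length(cg$satellites))
        data.frame(cog_id = cg$id, gene_id = cg$satellites,
                   species = species_of_gene(cg$satellites),
                   role = "satellite")
      else NULL)
  }))
  if (is.null(rows))
    rows <- data.frame(cog_id = character(0), gene_id = character(0),
                       species = character(0), role = character(0))
  path <- file.path(out_dir, "cog_membership.tsv")
  write_tsv(rows, path)
  for (cg in cogs) {
    lines <- c(sprintf("graph %s {", cg$id))
    ed <- cg$edges
    if (nrow(ed)) {
      und <- unique(data.frame(a = pmin(ed$from, ed$to),
                               b = pmax(ed$from, ed$to),
                               rec = ed$reciprocal))
      lines <- c(lines, sprintf('  "%s" -- "%s" [style=%s];', und$a, und$b,
                                ifelse(und$rec, "solid", "dashed")))
    }
    lines <- c(lines, "}")
    writeLines(lines, file.path(out_dir, paste0(cg$id, ".dot")))
  }
  invisible(path)
}
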