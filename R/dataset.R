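## Dataset assembly and deterministic on-disk serialization: CDS/protein
## FASTA, newick trees, and TSV truth tables.

#' Simulate a complete synthetic dataset
#'
#' Convenience orchestrator: simulates `n_families` gene family histories
#' along the species tree, evolves a codon alignment for each surviving
#' family, and optionally plants allele/fragment artifacts.
#'
#' @param stree A [species_tree()].
#' @param cfg A [sim_config()].
#' @param n_families Number of independent families to simulate.
#' @param artifacts If `TRUE`, plant artifacts per [plant_artifacts()].
#' @param n_alleles,n_fragments Artifact counts passed through.
#' @return A list of class `synthetic_dataset`: `species_tree`, `families`
#'   (list of `gene_family_history`), `alignments` (list of
#'   `codon_alignment_truth`), `cds`, `protein` (named vectors over all
#'   genes incl. artifacts), `artifact_truth`.
#' @export
simulate_dataset <- function(stree, cfg, n_families = 1, artifacts = FALSE,
                             n_alleles = 2, n_fragments = 1) {
  set.seed(cfg$seed)
  families <- list()
  alignments <- list()
  cds <- character(0)
  for (f in seq_len(n_families)) {
    fid <- sprintf("fam%d", f)
    fam <- simulate_family_impl(stree, cfg, family_id = fid)
    families[[fid]] <- fam
    trees <- if (inherits(fam$tree, "phylo")) list(fam$tree) else fam$tree
    if (is.null(trees)) next
    seqs <- character(0)
    for (tr in trees) {
      tr$edge.length <- tr$edge.length * cfg$branch_scale
      if (ape::Ntip(tr) < 2) next
      aln <- simulate_codon_alignment_impl(tr, cfg)
      seqs <- c(seqs, aln$cds)
      alignments[[length(alignments) + 1L]] <- aln
      names(alignments)[length(alignments)] <- fid
    }
    cds <- c(cds, seqs)
  }
  artifact_truth <- data.frame(id = character(0), source = character(0),
                               kind = character(0))
  if (artifacts && length(cds)) {
    pl <- plant_artifacts(cds, cfg, n_alleles = n_alleles,
                          n_fragments = n_fragments)
    cds <- pl$cds
    artifact_truth <- pl$truth
  }
  out <- list(species_tree = stree, families = families,
              alignments = alignments, cds = cds,
              protein = if (length(cds)) translate_cds(cds) else character(0),
              artifact_truth = artifact_truth, config = cfg)
  class(out) <- "synthetic_dataset"
  out
}

#' Write a synthetic dataset to disk
#'
#' Emits CDS FASTA, protein FASTA, species and gene trees in newick, and
#' the truth tables (events, site classes, planted artifacts) as TSV.
#' Identical seed + config produce byte-identical files.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest: file, sha256.
#' @export
write_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (length(dataset$protein)) {
    bad <- grepl("\\*", dataset$protein)
    if (any(bad)) stop("internal stop codon in translation of: ",
                       paste(names(dataset$protein)[bad], collapse = ", "))
  }
  paths <- character(0)
  write_fasta(dataset$cds, file.path(out_dir, "cds.fasta"))
  write_fasta(dataset$protein, file.path(out_dir, "protein.fasta"))
  paths <- c(paths, "cds.fasta", "protein.fasta")
  ape::write.tree(dataset$species_tree$phylo,
                  file.path(out_dir, "species_tree.nwk"))
  paths <- c(paths, "species_tree.nwk")
  gene_trees <- list()
  for (fid in names(dataset$families)) {
    tr <- dataset$families[[fid]]$tree
    if (is.null(tr)) next
    trees <- if (inherits(tr, "phylo")) list(tr) else tr
    gene_trees <- c(gene_trees, trees)
  }
  if (length(gene_trees)) {
    class(gene_trees) <- "multiPhylo"
    ape::write.tree(gene_trees, file.path(out_dir, "gene_trees.nwk"))
    paths <- c(paths, "gene_trees.nwk")
  }
  events <- do.call(rbind, lapply(names(dataset$families), function(fid) {
    ev <- dataset$families[[fid]]$events
    if (nrow(ev)) cbind(family = fid, ev) else NULL
  }))
  if (is.null(events))
    events <- data.frame(family = character(0), event = character(0),
                         species_branch_child = integer(0), time = numeric(0),
                         gnode = integer(0), observable = logical(0))
  write_tsv(events, file.path(out_dir, "events.tsv"))
  paths <- c(paths, "events.tsv")
  sc <- do.call(rbind, lapply(seq_along(dataset$alignments), function(i) {
    a <- dataset$alignments[[i]]
    data.frame(family = names(dataset$alignments)[i],
               site = seq_along(a$site_class), class = a$site_class)
  }))
  if (is.null(sc)) sc <- data.frame(family = character(0), site = integer(0),
                                    class = integer(0))
  write_tsv(sc, file.path(out_dir, "site_classes.tsv"))
  write_tsv(dataset$artifact_truth, file.path(out_dir, "artifacts.tsv"))
  paths <- c(paths, "site_classes.tsv", "artifacts.tsv")
  files <- file.path(out_dir, paths)
  data.frame(file = paths,
             sha256 = vapply(files, function(f)
               digest::digest(f, algo = "sha256", file = TRUE), character(1)),
             row.names = NULL)
}

#' Write sequences as FASTA
#'
#' Plain single-line-per-record FASTA writer with LF line endings, so that
#' output bytes are stable across platforms and runs.
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(seqs))
    writeLines(paste0(">", names(seqs), "\n", unname(seqs)), con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA path (nucleotide or protein).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
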