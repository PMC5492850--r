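# Shared fixtures: species trees, small simulated families, and handy
# constructors used across the suite.

default_st <- build_default_species_tree()

st6 <- local({
  keep <- c("Ath", "Gma", "Ptr", "Osa", "Sbi", "Zma")
  species_tree(ape::keep.tip(default_st$phylo, keep),
               stats::setNames(c("dicot", "dicot", "dicot",
                                 "grass", "grass", "grass"), keep))
})

st4 <- local({
  keep <- c("Ath", "Gma", "Osa", "Zma")
  species_tree(ape::keep.tip(default_st$phylo, keep),
               stats::setNames(c("dicot", "dicot", "grass", "grass"), keep))
})

# a gene tree congruent with the full species tree, one gene per species
congruent_gene_tree <- function(seed = 1, branch_scale = 1) {
  cfg <- sim_config(lambda = 0, mu = 0, n0 = 1, seed = seed)
  tr <- simulate_family(default_st, cfg)$tree
  tr$edge.length <- tr$edge.length * branch_scale
  tr
}

# random rooted gene tree over the species of a species_tree: each leaf is
# assigned a species uniformly; duplicates get serial suffixes
random_gene_tree <- function(n_leaves, stree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- sample(stree$phylo$tip.label, n_leaves, replace = TRUE)
  serial <- stats::ave(seq_along(sp), sp, FUN = seq_along)
  tr <- ape::rtree(n_leaves)
  tr$tip.label <- sprintf("%s_r_%d", sp, serial)
  tr
}

# simulate a codon alignment on a gene tree under a one-ratio model
quick_alignment <- function(tree, omega = 0.2, n_codons = 300, seed = 1,
                            kappa = 2) {
  cfg <- sim_config(regime = "one_ratio", omega = omega, kappa = kappa,
                    n_codons = n_codons, seed = seed)
  simulate_codon_alignment(tree, cfg)
}

# collapse a phangorn phyDat simulation to named protein strings
phydat_rows <- function(s) {
  m <- as.character(s)
  stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
}

random_cds <- function(n_codons, seed = 1) {
  set.seed(seed)
  codons <- sense_codons()
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}
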