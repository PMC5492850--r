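# Sequence filtering, built-in similarity scoring, BeT graphs and COG
# construction.

test_that("length filter removes short fragments with reason 'short'", {
  cds <- c(Ath_f_1 = random_cds(200, 1), Ath_f_2 = random_cds(100, 2),
           Osa_f_1 = random_cds(150, 3))
  fl <- filter_sequences(cds, min_len_nt = 400)
  expect_setequal(fl$removed$id, "Ath_f_2")
  expect_equal(fl$removed$reason, "short")
  expect_setequal(names(fl$kept), c("Ath_f_1", "Osa_f_1"))
})

test_that("indel-free near-identical same-species pairs collapse as alleles", {
  src <- random_cds(200, 4)
  cfg <- sim_config(allele_identity = 0.97)
  allele <- cogevol:::mutate_to_identity(src, 0.97)
  cds <- c(Ath_f_1 = src, Ath_f_2 = allele, Osa_f_1 = random_cds(200, 5))
  fl <- filter_sequences(cds, min_len_nt = 400, allele_identity = 0.95)
  expect_equal(nrow(fl$removed), 1L)
  expect_equal(fl$removed$reason, "allele")
  # the longest (here: equal length, lexicographically smallest id) stays
  expect_true("Ath_f_1" %in% names(fl$kept))
  expect_false("Ath_f_2" %in% names(fl$kept))
})

test_that("a 97%-identical pair whose optimal alignment needs gaps is kept", {
  # same species, same length, but homologous only up to a 3-nt shift:
  # the gap-free identity is low while the gapped alignment is ~97%
  base <- random_cds(60, 6)                      # 180 nt
  v <- strsplit(base, "")[[1]]
  shifted <- c(v[4:180], v[1:3])                 # remove codon 1, append it
  cds <- c(Ath_f_1 = base, Ath_f_2 = paste(shifted, collapse = ""))
  fl <- filter_sequences(cds, min_len_nt = 100, allele_identity = 0.95)
  expect_equal(nrow(fl$removed), 0L)
  expect_length(fl$kept, 2L)
})

test_that("filtering twice equals filtering once", {
  set.seed(41)
  cds <- stats::setNames(vapply(1:6, function(i) random_cds(160, i + 10),
                                character(1)),
                         c(sprintf("Ath_f_%d", 1:3), sprintf("Osa_f_%d", 1:3)))
  cds["Ath_f_2"] <- cogevol:::mutate_to_identity(cds[["Ath_f_1"]], 0.98)
  f1 <- filter_sequences(cds)
  f2 <- filter_sequences(f1$kept)
  expect_identical(f2$kept, f1$kept)
  expect_equal(nrow(f2$removed), 0L)
})

test_that("built-in Smith-Waterman matches an independent DP oracle", {
  pairs <- list(c("MKVLDEWHRT", "MKVLDQWHRT"),
                c("ACDEFGHIKL", "ACDFGHIKLM"),
                c("WWWWWCCCCC", "WWWWACCCC"))
  for (p in pairs) {
    prot <- stats::setNames(p, c("Ath_f_1", "Osa_f_1"))
    ht <- score_all_pairs(prot)
    expect_equal(ht$score[1], oracle_sw_score(p[1], p[2]))
  }
})

test_that("similarity scores are symmetric and maximal for identity", {
  prot <- c(Ath_f_1 = "MKVLDEWHRTACDEFGHIKL",
            Osa_f_1 = "MKVLDEWHRTACDEFGHIKL",
            Bra_f_1 = "MKVVDEWHRTACDEFGHIRL")
  ht <- score_all_pairs(prot)
  s <- function(q, x) ht$score[ht$query == q & ht$subject == x]
  expect_equal(s("Ath_f_1", "Osa_f_1"), s("Osa_f_1", "Ath_f_1"))
  # the identical pair outscores the mismatched ones
  expect_gt(s("Ath_f_1", "Osa_f_1"), s("Ath_f_1", "Bra_f_1"))
  expect_false(any(ht$query == ht$subject))
})

test_that("BeTs pick the top foreign hit and classify reciprocity", {
  # 3 species, 1 gene each, all mutually best: 3 reciprocal edges
  ht <- data.frame(
    query = c("Ath_f_1", "Osa_f_1", "Ath_f_1", "Bra_f_1", "Osa_f_1",
              "Bra_f_1"),
    subject = c("Osa_f_1", "Ath_f_1", "Bra_f_1", "Ath_f_1", "Bra_f_1",
                "Osa_f_1"),
    score = c(100, 100, 90, 90, 80, 80), pident = 90, length = 100)
  class(ht) <- c("hit_table", "data.frame")
  bg <- compute_bets(ht)
  expect_equal(nrow(bg), 6L)
  expect_true(all(bg$reciprocal))

  # g's best in B is h, but h's best back is g2: edge g -> h asymmetric
  ht2 <- data.frame(
    query = c("Ath_f_1", "Osa_f_1", "Osa_f_1", "Ath_f_2"),
    subject = c("Osa_f_1", "Ath_f_2", "Ath_f_1", "Osa_f_1"),
    score = c(50, 90, 40, 90), pident = 90, length = 100)
  class(ht2) <- c("hit_table", "data.frame")
  bg2 <- compute_bets(ht2)
  e <- bg2[bg2$from == "Ath_f_1" & bg2$to == "Osa_f_1", ]
  expect_false(e$reciprocal)
  e2 <- bg2[bg2$from == "Osa_f_1" & bg2$to == "Ath_f_2", ]
  expect_true(e2$reciprocal)
})

test_that("orthologous singletons give all-reciprocal BeTs", {
  cfg <- sim_config(lambda = 0, mu = 0, n_codons = 150, seed = 31,
                    branch_scale = 0.05)
  ds <- simulate_dataset(default_st, cfg, n_families = 1)
  ht <- score_all_pairs(ds$protein)
  bg <- compute_bets(ht)
  expect_true(all(bg$reciprocal))
  expect_equal(nrow(bg), 11 * 10)  # one edge per ordered species pair
})

test_that("COG construction merges edge-sharing triangles", {
  # complete reciprocal graph over 4 genes of 4 species: one COG
  genes <- c("Ath_f_1", "Bra_f_1", "Osa_f_1", "Zma_f_1")
  full <- expand.grid(from = genes, to = genes, stringsAsFactors = FALSE)
  full <- full[full$from != full$to, ]
  full$score <- 10; full$reciprocal <- TRUE
  class(full) <- c("bet_graph", "data.frame")
  cogs <- build_cogs(full)
  expect_length(cogs, 1L)
  expect_setequal(cogs[[1]]$core, genes)

  # two vertex-disjoint triangles: two COGs
  t1 <- c("Ath_f_1", "Bra_f_1", "Osa_f_1")
  t2 <- c("Gma_f_1", "Mtr_f_1", "Zma_f_1")
  mk <- function(g) {
    e <- expand.grid(from = g, to = g, stringsAsFactors = FALSE)
    e <- e[e$from != e$to, ]
    e$score <- 5; e$reciprocal <- TRUE
    e
  }
  both <- rbind(mk(t1), mk(t2))
  class(both) <- c("bet_graph", "data.frame")
  cogs2 <- build_cogs(both)
  expect_length(cogs2, 2L)
  expect_setequal(cogs2[[1]]$core, sort(t1))
  expect_setequal(cogs2[[2]]$core, sort(t2))
})

test_that("triangle merging equals brute-force on random instances", {
  skip_if_not_installed("igraph")
  species <- default_st$phylo$tip.label
  for (seed in 1:8) {
    set.seed(seed)
    genes <- sprintf("%s_f_%d", sample(species, 12, replace = TRUE), 1:12)
    # random reciprocal graph
    pairs <- t(utils::combn(genes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.35
    e <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                    score = 1, reciprocal = TRUE)
    e <- rbind(e, data.frame(from = e$to, to = e$from, score = 1,
                             reciprocal = TRUE))
    class(e) <- c("bet_graph", "data.frame")
    cogs <- build_cogs(e)
    # brute force: enumerate species-distinct triangles, then connected
    # components of the shares-an-edge relation
    tri <- list()
    cmb <- utils::combn(genes, 3)
    has <- function(a, b) any(e$from == a & e$to == b)
    for (k in seq_len(ncol(cmb))) {
      g3 <- cmb[, k]
      if (length(unique(species_of_gene(g3))) != 3) next
      if (has(g3[1], g3[2]) && has(g3[1], g3[3]) && has(g3[2], g3[3]))
        tri[[length(tri) + 1L]] <- sort(g3)
    }
    if (!length(tri)) {
      expect_length(cogs, 0L)
      next
    }
    nt <- length(tri)
    adj <- matrix(FALSE, nt, nt)
    share_edge <- function(x, y) {
      ex <- utils::combn(x, 2); ey <- utils::combn(y, 2)
      kx <- apply(ex, 2, paste, collapse = "|")
      ky <- apply(ey, 2, paste, collapse = "|")
      length(intersect(kx, ky)) > 0
    }
    for (i in seq_len(nt)) for (j in seq_len(nt))
      adj[i, j] <- share_edge(tri[[i]], tri[[j]])
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))
    expected <- sort(vapply(seq_len(comp$no), function(k) {
      paste(sort(unique(unlist(tri[comp$membership == k]))), collapse = ",")
    }, character(1)))
    got <- sort(vapply(cogs, function(cg) paste(cg$core, collapse = ","),
                       character(1)))
    expect_equal(got, expected)
  }
})

test_that("no gene sits in two COG cores; satellites attach by asymmetry", {
  e <- data.frame(
    from = c("Ath_f_1", "Bra_f_1", "Ath_f_1", "Osa_f_1", "Bra_f_1",
             "Osa_f_1", "Zma_f_1"),
    to = c("Bra_f_1", "Ath_f_1", "Osa_f_1", "Ath_f_1", "Osa_f_1",
           "Bra_f_1", "Ath_f_1"),
    score = 1, reciprocal = c(rep(TRUE, 6), FALSE))
  class(e) <- c("bet_graph", "data.frame")
  cogs <- build_cogs(e)
  expect_length(cogs, 1L)
  expect_setequal(cogs[[1]]$satellites, "Zma_f_1")
  allcore <- unlist(lapply(cogs, `[[`, "core"))
  expect_false(anyDuplicated(allcore) > 0)
})

test_that("cog_report flags coverage without filtering", {
  full <- sprintf("%s_f_1", default_st$phylo$tip.label)
  part <- setdiff(full, "Mtr_f_1")
  mk_cog <- function(genes, id) structure(
    list(id = id, core = genes, satellites = character(0),
         species = table(species_of_gene(genes)),
         edges = data.frame(from = character(0), to = character(0),
                            score = numeric(0), reciprocal = logical(0))),
    class = "cog")
  rep <- cog_report(list(mk_cog(full, "COG001"), mk_cog(part, "COG002")),
                    default_st)
  expect_equal(rep$flag, c("complete", "incomplete"))
  expect_equal(rep$dicot_species, c(6L, 5L))
  empty <- cog_report(list(), default_st)
  expect_equal(nrow(empty), 0L)
})

test_that("external hit tables are validated on ingest", {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(q = "Ath_f_1", s = "Osa_f_1", pid = 90, len = 100,
                   mm = 5, go = 0, qs = 1, qe = 100, ss = 1, se = 100,
                   ev = 1e-50, bits = 200)
  utils::write.table(df, tmp, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  ht <- read_hit_table(tmp, known_ids = c("Ath_f_1", "Osa_f_1"))
  expect_equal(ht$score, 200)
  expect_error(read_hit_table(tmp, known_ids = "Ath_f_1"), "unknown ids")
  utils::write.table(df[, 1:5], tmp, sep = "\t", col.names = FALSE,
                     row.names = FALSE, quote = FALSE)
  expect_error(read_hit_table(tmp), "12")
})
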