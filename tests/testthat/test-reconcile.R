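# LCA reconciliation, rooting, subgroup detection, event classification
# and copy-number reconstruction, checked against exhaustive oracles.

test_that("a congruent gene tree reconciles with no events", {
  gt <- congruent_gene_tree(seed = 1)
  rec <- reconcile(gt, default_st)
  expect_equal(rec$n_dup, 0L)
  expect_equal(rec$n_loss, 0L)
  expect_true(all(rec$loss_by_branch == 0L))
})

test_that("duplication counts match exhaustive reconciliation", {
  # random gene trees (3-6 leaves vectorize comfortably; a couple of
  # 7-leaf cases stress the enumeration) against the 4-taxon species tree
  sizes <- c(rep(3:6, each = 6), 7, 7)
  for (k in seq_along(sizes)) {
    gt <- random_gene_tree(sizes[k], st4, seed = 1000 + k)
    rec <- reconcile(gt, st4)
    orc <- oracle_reconcile_min(gt, st4)
    expect_equal(rec$n_dup, orc$min_dup,
                 info = sprintf("tree %d (n=%d)", k, sizes[k]))
    expect_equal(rec$n_dup + rec$n_loss, orc$min_dup_plus_loss,
                 info = sprintf("tree %d losses", k))
  }
})

test_that("minimize-duplication rooting equals brute force over edges", {
  for (k in 1:8) {
    gt <- ape::unroot(random_gene_tree(sample(4:8, 1), st4,
                                       seed = 2000 + k))
    rooted <- root_gene_tree(gt, st4)
    got <- reconcile(rooted, st4)
    best <- Inf
    for (e in seq_len(nrow(gt$edge))) {
      cand <- cogevol:::root_on_edge(gt, e)
      orc <- oracle_reconcile_min(cand, st4)
      best <- min(best, orc$min_dup_plus_loss)
    }
    expect_equal(got$n_dup + got$n_loss, best, info = paste("case", k))
  }
})

test_that("congruent unrooted trees root between the partitions", {
  gt <- ape::unroot(congruent_gene_tree(seed = 5))
  rooted <- root_gene_tree(gt, default_st)
  rec <- reconcile(rooted, default_st)
  expect_equal(rec$n_dup + rec$n_loss, 0L)
  ch <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1L, 2]
  sides <- lapply(ch, function(v) {
    sp <- species_of_gene(
      if (v <= ape::Ntip(rooted)) rooted$tip.label[v]
      else ape::extract.clade(rooted, v)$tip.label)
    unique(unname(default_st$partition[sp]))
  })
  expect_setequal(unlist(lapply(sides, paste, collapse = "+")),
                  c("dicot", "grass"))
})

test_that("midpoint rooting splits a two-leaf path at its center", {
  gt <- ape::read.tree(text = "(Ath_f_1:3,Osa_f_1:1);")
  rooted <- root_gene_tree(gt, method = "midpoint")
  d <- ape::dist.nodes(rooted)
  root <- ape::Ntip(rooted) + 1L
  expect_equal(unname(d[root, 1]), unname(d[root, 2]))
  expect_error(root_gene_tree(gt, method = "outgroup", outgroup = "nope"),
               "absent")
})

test_that("subgroups are the maximal pure clades (exhaustive check)", {
  gt <- congruent_gene_tree(seed = 2)
  sg <- detect_subgroups(gt, default_st)
  expect_length(sg, 2L)
  expect_setequal(vapply(sg, `[[`, character(1), "partition"),
                  c("dicot", "grass"))
  for (k in 1:10) {
    tr <- random_gene_tree(sample(4:10, 1), default_st, seed = 3000 + k)
    got <- detect_subgroups(tr, default_st)
    want <- oracle_subgroups(tr, default_st)
    key <- function(x) paste(x$partition, paste(sort(x$members),
                                                collapse = ","))
    expect_setequal(vapply(got, function(x)
      paste(x$partition, paste(sort(x$members), collapse = ",")),
      character(1)),
      vapply(want, key, character(1)))
  }
})

test_that("event classification follows the subgroup and LCA rules", {
  gt <- congruent_gene_tree(seed = 3)
  inf <- infer_events(gt, default_st, cog_id = "X")
  expect_equal(nrow(inf$events), 0L)

  # duplicate Ath, drop Mtr: at least one recent dicot duplication and a
  # dicot loss attributed to Mtr
  gt2 <- gt
  gt2 <- ape::drop.tip(gt2, "Mtr_fam1_1")
  ath <- which(gt2$tip.label == "Ath_fam1_1")
  gt2 <- phytools::bind.tip(gt2, "Ath_fam1_2", where = ath,
                            edge.length = 0.1, position = 0.2)
  inf2 <- infer_events(gt2, default_st, cog_id = "X")
  dup <- inf2$events[inf2$events$event == "duplication", ]
  expect_gte(sum(dup$class == "recent-dicot"), 1L)
  loss <- inf2$events[inf2$events$event == "loss", ]
  expect_true(any(loss$class == "dicot" & loss$species == "Mtr"))
})

test_that("ancient vs recent classification keys on species breadth", {
  # a duplication at the base of the dicots (all 6 species on both sides
  # would need 12 leaves; 2 full dicot clades of 3+ species suffice)
  txt <- paste0("(((((Ath_f_1,Bra_f_1),(Gma_f_1,Ptr_f_1)),",
                "((Mtr_f_2,Rco_f_2),(Ath_f_2,Gma_f_2))),",
                "((Bdi_f_1,Osa_f_1),(Sbi_f_1,Zma_f_1))));")
  gt <- ape::read.tree(text = txt)
  gt$edge.length <- rep(1, nrow(gt$edge))
  inf <- infer_events(gt, default_st, cog_id = "A")
  dup <- inf$events[inf$events$event == "duplication", ]
  expect_true(any(dup$class == "ancient-dicot"))
  # single-species tandem pair is recent
  txt2 <- "(((Ath_f_1,Ath_f_2),Bra_f_1),(Osa_f_1,Zma_f_1));"
  gt2 <- ape::read.tree(text = txt2)
  gt2$edge.length <- rep(1, nrow(gt2$edge))
  inf2 <- infer_events(gt2, default_st, cog_id = "B")
  dup2 <- inf2$events[inf2$events$event == "duplication", ]
  expect_true("recent-dicot" %in% dup2$class)
})

test_that("copy-number profiles balance and match simple cases", {
  gt <- congruent_gene_tree(seed = 4)
  prof <- reconstruct_copy_numbers(list(reconcile(gt, default_st)),
                                   default_st)
  expect_true(all(prof$counts$count == 1L))
  expect_true(all(prof$branches$gains == 0L))
  expect_true(all(prof$branches$losses == 0L))

  # one ancient dicot duplication, no losses: 2 at MRCA_dicot, 1 at root,
  # gain of 1 on the root -> MRCA_dicot branch
  dic <- "((Ath_f_1,Bra_f_1),((Gma_f_1,Mtr_f_1),(Ptr_f_1,Rco_f_1)))"
  dic2 <- gsub("_f_1", "_f_2", dic)
  gra <- "((Bdi_f_1,Osa_f_1),(Sit_f_1,(Sbi_f_1,Zma_f_1)))"
  gt2 <- ape::read.tree(text = sprintf("((%s,%s),%s);", dic, dic2, gra))
  gt2$edge.length <- rep(1, nrow(gt2$edge))
  prof2 <- reconstruct_copy_numbers(list(reconcile(gt2, default_st)),
                                    default_st)
  cn <- prof2$counts
  expect_equal(cn$count[which(cn$label == "MRCA_all")], 1L)
  expect_equal(cn$count[which(cn$label == "MRCA_dicot")], 2L)
  mrca_d <- cn$node[which(cn$label == "MRCA_dicot")]
  expect_equal(prof2$branches$gains[prof2$branches$child == mrca_d], 1L)
})

test_that("copy-number balance holds on stochastic histories", {
  cfg_seeds <- c(5, 17, 29, 61)
  for (sd in cfg_seeds) {
    cfg <- sim_config(lambda = 0.2, mu = 0.1, seed = sd)
    fam <- simulate_family(default_st, cfg)
    if (is.null(fam$tree) || !inherits(fam$tree, "phylo")) next
    rec <- reconcile(fam$tree, default_st)
    prof <- reconstruct_copy_numbers(list(rec), default_st)
    sidx <- cogevol:::tree_index(default_st$phylo)
    for (r in seq_len(nrow(prof$branches))) {
      child <- prof$branches$child[r]
      parent <- sidx$parent[child]
      expect_equal(prof$counts$count[child],
                   prof$counts$count[parent] + prof$branches$gains[r] -
                     prof$branches$losses[r])
    }
  }
})

test_that("family summaries add up and reproduce planted truth", {
  empty <- summarize_family(list())
  expect_equal(nrow(empty), 1L)  # totals row only
  expect_true(all(empty[, -1] == 0))

  ev <- data.frame(
    cog_id = c("A", "A", "A", "A", "A", "B"),
    event = c(rep("duplication", 4), "loss", "loss"),
    class = c("ancient-grass", "ancient-grass", "recent-dicot",
              "recent-dicot", "grass", "dicot"),
    species = "x", gnode = 1:6)
  s <- summarize_family(ev)
  a <- s[s$cog_id == "A", ]
  expect_equal(a$ancient_grass, 2L)
  expect_equal(a$recent_dicot, 2L)
  expect_equal(a$loss_grass, 1L)
  tot <- s[s$cog_id == "TOTAL", ]
  expect_equal(tot$ancient_grass, sum(s$ancient_grass[s$cog_id != "TOTAL"]))
  expect_equal(tot$loss_dicot, 1L)
})

test_that("simulated histories are recovered event-for-event", {
  # a no-loss simulation reconciles to exactly the true duplication count
  ok <- 0; n <- 25
  for (sd in seq_len(n)) {
    cfg <- sim_config(lambda = 0.15, mu = 0, seed = 400 + sd)
    fam <- simulate_family(default_st, cfg)
    if (!inherits(fam$tree, "phylo")) next
    rec <- reconcile(fam$tree, default_st)
    truth <- sum(fam$events$event == "duplication")
    if (rec$n_dup == truth) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

test_that("annotated trees carry D/S labels at internal nodes", {
  txt2 <- "(((Ath_f_1,Ath_f_2),Bra_f_1),(Osa_f_1,Zma_f_1));"
  gt <- ape::read.tree(text = txt2)
  gt$edge.length <- rep(1, nrow(gt$edge))
  ann <- annotate_events(reconcile(gt, default_st))
  expect_length(ann$node.label, gt$Nnode)
  expect_true(all(ann$node.label %in% c("D", "S")))
  expect_equal(sum(ann$node.label == "D"), 1L)  # the Ath tandem pair
})

test_that("the confirmed-absent whitelist restricts loss calls", {
  gt <- ape::drop.tip(congruent_gene_tree(seed = 3),
                      c("Mtr_fam1_1", "Bra_fam1_1"))
  all_losses <- infer_events(gt, default_st, cog_id = "X")$events
  expect_setequal(all_losses$species[all_losses$event == "loss"],
                  c("Mtr", "Bra"))
  confirmed <- infer_events(gt, default_st, cog_id = "X",
                            confirmed_absent = list(dicot = "Mtr",
                                                    grass = character(0)))
  ev <- confirmed$events
  expect_equal(ev$species[ev$event == "loss"], "Mtr")
})
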