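# Pairwise dN/dS (counting and ML), subgroup comparisons, codon model
# fits, LRTs and positive-site partitioning.

test_that("NG86 handles degenerate pairs exactly", {
  s <- random_cds(20, 1)
  same <- ng86_pairwise(s, s)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$omega))
  # TTT -> TTC is synonymous: pN = 0
  r <- ng86_pairwise("TTT", "TTC")
  expect_equal(r$pN, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$pS, 0)
})

test_that("NG86 equals exhaustive path enumeration to 1e-10", {
  set.seed(8)
  for (k in 1:6) {
    a <- random_cds(20, 50 + k)
    # mutate a handful of positions, keeping codons sense
    b <- cogevol:::mutate_to_identity(a, 0.9)
    got <- ng86_pairwise(a, b)
    orc <- oracle_ng86_pair(a, b)
    expect_equal(got$S, orc$S, tolerance = 1e-10)
    expect_equal(got$pS, orc$pS, tolerance = 1e-10)
    expect_equal(got$pN, orc$pN, tolerance = 1e-10)
    expect_equal(got$dS, orc$dS, tolerance = 1e-10)
    expect_equal(got$dN, orc$dN, tolerance = 1e-10)
  }
})

test_that("ML pairwise omega recovers the simulated truth", {
  tr <- ape::read.tree(text = "(Ath_f_1:0.25,Osa_f_1:0.25);")
  cfg <- sim_config(regime = "one_ratio", omega = 0.2, kappa = 2,
                    n_codons = 20000, seed = 71)
  aln <- simulate_codon_alignment(tr, cfg)
  ml <- ml_pairwise(aln$cds[[1]], aln$cds[[2]])
  expect_lt(abs(ml$omega - 0.2), 0.03)
  expect_lt(abs(ml$t - 0.5), 0.05)
  expect_equal(ml$dN / ml$dS, ml$omega, tolerance = 1e-6)
})

test_that("counting and ML omega agree at low divergence", {
  for (sd in 1:5) {
    tr <- ape::read.tree(text = "(Ath_f_1:0.12,Osa_f_1:0.12);")
    cfg <- sim_config(regime = "one_ratio", omega = 0.3, kappa = 1.5,
                      n_codons = 3000, seed = 500 + sd)
    aln <- simulate_codon_alignment(tr, cfg)
    ml <- ml_pairwise(aln$cds[[1]], aln$cds[[2]])
    ng <- ng86_pairwise(aln$cds[[1]], aln$cds[[2]])
    expect_lt(abs(ml$omega - ng$omega) / ml$omega, 0.2)
  }
})

test_that("identical sequences drive t to the boundary multinomial", {
  s <- random_cds(500, 5)
  ml <- ml_pairwise(s, s)
  expect_true(ml$undefined)
  # at t -> 0 the likelihood is the multinomial over root codons
  pi <- codon_frequencies("F3x4", c(s, s))
  st <- match(cogevol:::split_codons(s), sense_codons())
  expect_lt(abs(ml$lnL - sum(log(pi[st]))), 1)
})

test_that("subgroup omega sets respect the dS cutoff and pair counts", {
  tr <- ape::read.tree(text = paste0(
    "((Osa_f_1:0.05,Osa_f_2:0.05):0.05,(Sbi_f_1:0.05,Zma_f_1:0.05):0.05);"))
  cfg <- sim_config(regime = "one_ratio", omega = 0.25, n_codons = 500,
                    seed = 81)
  aln <- simulate_codon_alignment(tr, cfg)
  sg <- list(list(partition = "grass", members = names(aln$cds),
                  species = unique(species_of_gene(names(aln$cds))),
                  node = 6L, support = NA, low_support = FALSE))
  res <- subgroup_pairwise_omega(aln$cds, sg)
  expect_equal(res$n_pairs, 6L)  # choose(4, 2)
  expect_gt(res$mean_omega, 0)

  # a planted saturated pair is discarded and counted
  deep <- ape::read.tree(text = "(Osa_g_1:4,Osa_g_2:4);")
  cfg2 <- sim_config(regime = "one_ratio", omega = 0.25, n_codons = 300,
                     seed = 82)
  sat <- simulate_codon_alignment(deep, cfg2)
  sg2 <- list(list(partition = "grass", members = names(sat$cds),
                   species = "Osa", node = 3L, support = NA,
                   low_support = FALSE))
  res2 <- subgroup_pairwise_omega(sat$cds, sg2)
  expect_equal(res2$n_excluded, 1L)
  expect_true(is.na(res2$mean_omega))

  # two identical members: pair evaluated, omega undefined, mean missing
  s <- random_cds(200, 9)
  cds3 <- c(Osa_h_1 = s, Osa_h_2 = s)
  sg3 <- list(list(partition = "grass", members = names(cds3),
                   species = "Osa", node = 3L, support = NA,
                   low_support = FALSE))
  res3 <- subgroup_pairwise_omega(cds3, sg3)
  expect_equal(res3$n_pairs, 1L)
  expect_true(is.na(res3$mean_omega))
})

test_that("subgroup mean comparison: exact ties, permutation value, stars", {
  same <- compare_subgroup_means(c(0.2, 0.2), c(0.2, 0.2, 0.2))
  expect_equal(same$p, 1)
  expect_equal(same$stars, "n.s.")
  # complete separation of 3 vs 3: exact two-sided p = 2/choose(6,3) = 0.1
  r <- compare_subgroup_means(c(0.1, 0.1, 0.1) + c(0, 1e-6, 2e-6),
                              c(0.9, 0.9, 0.9) + c(0, 1e-6, 2e-6))
  expect_equal(r$p, 0.1, tolerance = 1e-9)
  expect_true(r$dependence_caveat)
  big <- compare_subgroup_means(stats::runif(20, 0, 0.01),
                                stats::runif(20, 0.5, 0.6))
  expect_equal(big$stars, "**")
})

test_that("the subgroup test has power against a real omega shift", {
  # dicot pairs at omega 0.1 vs grass pairs at omega 0.3, 8 pairs each:
  # rejection rate at alpha = 0.05 clearly above the nominal level
  set.seed(42)
  tr <- ape::read.tree(text = "(a_f_1:0.15,b_f_1:0.15);")
  draw <- function(omega, sd) {
    cfg <- sim_config(regime = "one_ratio", omega = omega, n_codons = 150,
                      seed = sd)
    aln <- simulate_codon_alignment(tr, cfg)
    ng86_pairwise(aln$cds[[1]], aln$cds[[2]])$omega
  }
  n_rep <- 60
  rej <- 0
  sd0 <- 9000
  for (r in seq_len(n_rep)) {
    dic <- vapply(1:8, function(i) draw(0.1, sd0 + r * 100 + i), numeric(1))
    gra <- vapply(1:8, function(i) draw(0.3, sd0 + r * 100 + 50 + i),
                  numeric(1))
    dic <- dic[!is.na(dic)]; gra <- gra[!is.na(gra)]
    if (length(dic) < 3 || length(gra) < 3) next
    if (compare_subgroup_means(dic, gra)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / n_rep, 0.5)
})

test_that("branch-model likelihood is invariant to input order", {
  gt <- congruent_gene_tree(seed = 6, branch_scale = 0.1)
  aln <- quick_alignment(gt, omega = 0.2, n_codons = 120, seed = 61)
  f1 <- fit_branch_model(aln$cds, gt, branch_mode = "scale")
  f2 <- fit_branch_model(rev(aln$cds), gt, branch_mode = "scale")
  expect_lt(abs(f1$lnL - f2$lnL), 1e-6)
})

test_that("rate matrices keep pi stationary with eigenvalue zero", {
  pi <- codon_frequencies("F3x4")
  Q <- gy94_rate_matrix(2, 0.3, pi)
  expect_lt(max(abs(pi %*% Q)), 1e-8)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  gen <- switching_generator(2, c(0.05, 0.5, 2.5), c(0.6, 0.3, 0.1),
                             0.1, pi)
  expect_lt(max(abs(rowSums(gen$G))), 1e-9)
  expect_lt(max(abs(gen$stat %*% gen$G)), 1e-8)
})

test_that("LRT arithmetic and guards behave", {
  mk <- function(lnL, npar) structure(list(lnL = lnL, npar = npar),
                                      class = "codon_model_fit")
  r <- lrt(mk(-100, 3), mk(-95, 4))
  expect_equal(r$statistic, 10)
  expect_equal(r$df, 1)
  expect_equal(r$p, stats::pchisq(10, 1, lower.tail = FALSE))
  same <- lrt(mk(-100, 3), mk(-100, 4))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(lrt(mk(-95, 3), mk(-100, 4)), "converge")
  r2 <- lrt(mk(-100, 3), mk(-95, 5), df = 2)
  expect_equal(r2$df, 2)
})

test_that("M3 posteriors are proper and classes stay ordered", {
  gt <- congruent_gene_tree(seed = 7, branch_scale = 0.15)
  cfg <- sim_config(regime = "M3", omegas = c(0.05, 0.6, 2.5),
                    probs = c(0.5, 0.35, 0.15), n_codons = 250, seed = 91)
  aln <- simulate_codon_alignment(gt, cfg)
  fit <- fit_m3(aln$cds, gt, control = list(factr = 1e9))
  expect_equal(rowSums(fit$posteriors), rep(1, 250), tolerance = 1e-9)
  expect_true(all(diff(fit$omega) >= 0))
  expect_equal(sum(fit$p), 1, tolerance = 1e-9)
})

test_that("M3+S1 at delta -> 0 collapses to the M3 likelihood", {
  gt <- congruent_gene_tree(seed = 8, branch_scale = 0.1)
  cfg <- sim_config(regime = "M3", n_codons = 150, seed = 95)
  aln <- simulate_codon_alignment(gt, cfg)
  pi <- codon_frequencies("F3x4", unname(aln$cds))
  kappa <- 2; omegas <- c(0.05, 0.5, 2.0); probs <- c(0.6, 0.3, 0.1)
  prep61 <- cogevol:::prep_tree_data(aln$cds, gt)
  Qs <- lapply(omegas, function(w) gy94_rate_matrix(kappa, w, pi,
                                                    scale = FALSE))
  rho <- sum(probs * vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1)))
  sll <- vapply(seq_along(Qs), function(k) {
    ed <- cogevol:::rev_eigen(Qs[[k]] / rho, pi)
    Pl <- lapply(prep61$phy$edge.length, function(t)
      cogevol:::prob_matrix(ed, t))
    cogevol:::pruning_site_loglik(prep61$phy, Pl, prep61$tips, pi)$site_ll
  }, numeric(prep61$nsites))
  lnl_m3 <- sum(cogevol:::log_mix(sll, probs))
  prep183 <- cogevol:::prep_tree_data(aln$cds, gt, n_classes = 3)
  gen <- switching_generator(kappa, omegas, probs, 1e-9, pi)
  ed <- cogevol:::rev_eigen(gen$G, gen$stat)
  Pl <- lapply(prep183$phy$edge.length, function(t)
    cogevol:::prob_matrix(ed, t))
  lnl_s1 <- sum(cogevol:::pruning_site_loglik(prep183$phy, Pl, prep183$tips,
                                              gen$stat)$site_ll)
  expect_lt(abs(lnl_m3 - lnl_s1), 1e-5)
})

test_that("positive-site partitioning honors thresholds and omega gating", {
  fake_fit <- function(omega_top, post_d, post_g, tree) {
    edge_side <- cogevol:::edge_partition_classes(tree)
    posts <- lapply(seq_len(nrow(tree$edge)), function(e) {
      m <- matrix(0.01, 3, length(post_d))
      m[3, ] <- if (edge_side[e] == "dicot") post_d else
        if (edge_side[e] == "grass") post_g else 0.01
      m
    })
    structure(list(omega = c(0.05, 0.5, omega_top),
                   branch_class_posterior = posts, tree = tree),
              class = "codon_model_fit")
  }
  gt <- congruent_gene_tree(seed = 9, branch_scale = 0.1)
  post_d <- c(0.9, 0.2, 0.6, 0.1)
  post_g <- c(0.1, 0.9, 0.6, 0.1)
  fit <- fake_fit(2.5, post_d, post_g, gt)
  res <- suppressWarnings(partition_positive_sites(fit, default_st))
  expect_equal(res$dicot, 1L)
  expect_equal(res$grass, 2L)
  expect_equal(res$shared, 3L)
  # omega_top <= 1: everything empty
  res0 <- suppressWarnings(partition_positive_sites(fake_fit(0.9, post_d,
                                                             post_g, gt),
                                                    default_st))
  expect_length(res0$dicot, 0L)
  expect_length(res0$grass, 0L)
  # stricter threshold lists are subsets
  res95 <- suppressWarnings(partition_positive_sites(fit, default_st,
                                                     threshold = 0.85))
  expect_true(all(res95$dicot %in% res$dicot))
  expect_true(all(res95$grass %in% res$grass))
  # kept-column map translates coordinates
  resk <- partition_positive_sites(fit, default_st, kept = c(3, 7, 9, 12))
  expect_equal(resk$dicot, 3L)
  expect_equal(resk$grass, 7L)
})

test_that("codeml-style #k branch labels parse into edge classes", {
  txt <- "((Ath_f_1#1,Gma_f_1):0.1,(Osa_f_1,Zma_f_1)#2:0.1);"
  lt <- read_labeled_tree(text = txt)
  expect_setequal(lt$tree$tip.label,
                  c("Ath_f_1", "Gma_f_1", "Osa_f_1", "Zma_f_1"))
  ntip <- ape::Ntip(lt$tree)
  cls_of_tip <- function(name) {
    e <- which(lt$tree$edge[, 2] == match(name, lt$tree$tip.label))
    lt$branch_classes[e]
  }
  expect_equal(cls_of_tip("Ath_f_1"), "1")
  expect_equal(cls_of_tip("Gma_f_1"), "0")
  grass_node <- ape::getMRCA(lt$tree, c("Osa_f_1", "Zma_f_1"))
  e <- which(lt$tree$edge[, 2] == grass_node)
  expect_equal(lt$branch_classes[e], "2")
})
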