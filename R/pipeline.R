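## End-to-end orchestration: validated configuration, staged execution
## with caching and a run manifest, and report tables mirroring the
## standard duplication/loss and selection summaries.

pipeline_defaults <- function() {
  list(
    mode = "synthetic",            # synthetic | files
    out_dir = "results/pipeline",
    seed = 1L,
    stages = c("simulate", "filter", "cogs", "trees", "events",
               "selection", "report"),
    # synthetic-data settings
    n_families = 3L, lambda = 0.1, mu = 0.05, n0 = 1L, n_codons = 200L,
    regime = "one_ratio", kappa = 2, omega = 0.2, branch_scale = 0.06,
    artifacts = TRUE, n_alleles = 2L, n_fragments = 1L,
    # file-mode inputs
    cds_fasta = NULL, species_tree = NULL, hit_table = NULL,
    # filtering
    min_len_nt = 400L, allele_identity = 0.95,
    # trees
    column_threshold = 12, n_bootstrap = 100L,
    # events
    recent_max_species = 2L,
    # selection
    ds_max = 2, fit_switching = FALSE, branch_mode = "joint",
    force = FALSE)
}

#' Validate a pipeline configuration
#'
#' Checks a YAML file or a list against the known keys and ranges,
#' materializes defaults, and reports precise errors (unknown keys get a
#' nearest-valid-key suggestion).
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated, default-completed configuration list; errors
#'   (class `pipeline_config_error`) carry the full error list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  defaults <- pipeline_defaults()
  errors <- character(0)
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) {
    d <- utils::adist(k, names(defaults))
    sugg <- names(defaults)[which.min(d)]
    errors <- c(errors, sprintf("unknown key '%s' (did you mean '%s'?)",
                                k, sugg))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config),
                                                      names(defaults))])
  chk <- function(ok, msg) if (!ok) errors <<- c(errors, msg)
  chk(cfg$mode %in% c("synthetic", "files"),
      "mode: must be 'synthetic' or 'files'")
  chk(all(cfg$stages %in% defaults$stages),
      paste0("stages: unknown stage(s) ",
             paste(setdiff(cfg$stages, defaults$stages), collapse = ", ")))
  chk(is.numeric(cfg$ds_max) && cfg$ds_max > 0,
      "ds_max: must be > 0 (saturation cutoff on dS)")
  chk(cfg$allele_identity > 0 && cfg$allele_identity <= 1,
      "allele_identity: must be in (0, 1]")
  chk(cfg$min_len_nt >= 0, "min_len_nt: must be >= 0")
  chk(cfg$lambda >= 0 && cfg$mu >= 0, "lambda/mu: must be >= 0")
  chk(cfg$n0 >= 1, "n0: must be >= 1")
  chk(cfg$column_threshold >= 0 && cfg$column_threshold <= 100,
      "column_threshold: must be in [0, 100]")
  chk(cfg$n_bootstrap >= 1, "n_bootstrap: must be >= 1")
  if (cfg$mode == "files")
    chk(!is.null(cfg$cds_fasta), "files mode requires cds_fasta")
  if (length(errors))
    stop(structure(class = c("pipeline_config_error", "error", "condition"),
                   list(message = paste(errors, collapse = "\n"),
                        call = NULL, errors = errors)))
  cfg
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order. Each stage reads and
#' writes only files under the configured output directory; a completed
#' stage whose outputs already exist is skipped unless `force`. The fully
#' resolved configuration is serialized for provenance.
#'
#' @param config Path to YAML, or a named list (see [validate_config()]).
#' @return The run manifest: data.frame with stage, status, seconds, and
#'   output digests.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out <- cfg$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  yaml::write_yaml(cfg, file.path(out, "config_used.yaml"))
  manifest <- list()
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, outputs, fn) {
    paths <- file.path(out, outputs)
    if (!(name %in% cfg$stages)) {
      manifest[[name]] <<- data.frame(stage = name, status = "skipped",
                                      seconds = 0)
      return(invisible())
    }
    if (!cfg$force && length(paths) && all(file.exists(paths)) &&
        is.null(state$dirty)) {
      manifest[[name]] <<- data.frame(stage = name, status = "cached",
                                      seconds = 0)
      return(invisible())
    }
    t0 <- proc.time()[["elapsed"]]
    fn(paths)
    state$dirty <- TRUE
    manifest[[name]] <<- data.frame(stage = name, status = "ok",
                                    seconds = round(proc.time()[["elapsed"]]
                                                    - t0, 2))
  }

  stree <- if (cfg$mode == "files" && !is.null(cfg$species_tree)) {
    phy <- ape::read.tree(cfg$species_tree)
    species_tree(phy, stats::setNames(
      ifelse(phy$tip.label %in% DICOT_LEAVES, "dicot", "grass"),
      phy$tip.label))
  } else build_default_species_tree()

  run_stage("simulate", c("dataset/cds.fasta"), function(paths) {
    if (cfg$mode != "synthetic") stop("simulate stage needs synthetic mode")
    sc <- sim_config(lambda = cfg$lambda, mu = cfg$mu, n0 = cfg$n0,
                     n_codons = cfg$n_codons, regime = cfg$regime,
                     kappa = cfg$kappa, omega = cfg$omega,
                     branch_scale = cfg$branch_scale, seed = cfg$seed)
    ds <- simulate_dataset(stree, sc, n_families = cfg$n_families,
                           artifacts = cfg$artifacts,
                           n_alleles = cfg$n_alleles,
                           n_fragments = cfg$n_fragments)
    write_dataset(ds, file.path(out, "dataset"))
  })

  cds_path <- if (cfg$mode == "synthetic")
    file.path(out, "dataset", "cds.fasta") else cfg$cds_fasta

  run_stage("filter", c("filtered/kept_cds.fasta", "filtered/removed.tsv"),
            function(paths) {
    if (!file.exists(cds_path))
      stop("filter stage: missing upstream input ", cds_path)
    cds <- read_fasta(cds_path)
    fl <- filter_sequences(cds, min_len_nt = cfg$min_len_nt,
                           allele_identity = cfg$allele_identity)
    dir.create(file.path(out, "filtered"), showWarnings = FALSE)
    write_fasta(fl$kept, paths[1L])
    write_tsv(fl$removed, paths[2L])
  })

  run_stage("cogs", c("cogs/cog_membership.tsv", "cogs/cog_report.tsv"),
            function(paths) {
    kept_path <- file.path(out, "filtered", "kept_cds.fasta")
    if (!file.exists(kept_path))
      stop("cogs stage: missing upstream output ", kept_path)
    cds <- read_fasta(kept_path)
    prot <- translate_cds(cds)
    names(prot) <- names(cds)
    hits <- if (!is.null(cfg$hit_table))
      read_hit_table(cfg$hit_table, known_ids = names(cds))
    else score_all_pairs(prot)
    bets <- compute_bets(hits)
    cogs <- build_cogs(bets)
    write_cog_membership(cogs, file.path(out, "cogs"))
    write_tsv(cog_report(cogs, stree), paths[2L])
  })

  run_stage("trees", c("trees/cog_trees.nwk"), function(paths) {
    mem_path <- file.path(out, "cogs", "cog_membership.tsv")
    if (!file.exists(mem_path))
      stop("trees stage: missing upstream output ", mem_path)
    mem <- read_tsv(mem_path)
    cds <- read_fasta(file.path(out, "filtered", "kept_cds.fasta"))
    prot <- translate_cds(cds); names(prot) <- names(cds)
    dir.create(file.path(out, "trees"), showWarnings = FALSE)
    trees <- list(); kept_maps <- list()
    for (cid in unique(mem$cog_id)) {
      ids <- mem$gene_id[mem$cog_id == cid & mem$role == "core"]
      ids <- intersect(ids, names(prot))
      if (length(ids) < 3) next
      if (length(unique(nchar(prot[ids]))) != 1L) next  # needs an alignment
      fc <- filter_columns(prot[ids], threshold = cfg$column_threshold)
      bs <- bootstrap_support(fc$aln, n_reps = cfg$n_bootstrap,
                              seed = cfg$seed + match(cid, unique(mem$cog_id)))
      trees[[cid]] <- bs$tree
      kept_maps[[cid]] <- data.frame(cog_id = cid, kept = fc$kept)
    }
    if (!length(trees)) stop("trees stage: no COG with >= 3 members")
    class(trees) <- "multiPhylo"
    ape::write.tree(trees, paths[1L])
    writeLines(names(trees), file.path(out, "trees", "cog_ids.txt"))
    write_tsv(do.call(rbind, kept_maps), file.path(out, "trees",
                                                   "kept_columns.tsv"))
  })

  run_stage("events", c("events/events.tsv", "events/summary.tsv",
                        "events/copy_numbers.tsv"), function(paths) {
    tr_path <- file.path(out, "trees", "cog_trees.nwk")
    if (!file.exists(tr_path))
      stop("events stage: missing upstream output ", tr_path)
    trees <- ape::read.tree(tr_path)
    if (inherits(trees, "phylo")) trees <- list(trees)
    ids <- readLines(file.path(out, "trees", "cog_ids.txt"))
    dir.create(file.path(out, "events"), showWarnings = FALSE)
    evs <- list(); recs <- list(); annotated <- list()
    for (k in seq_along(trees)) {
      rooted <- root_gene_tree(trees[[k]], stree)
      inf <- infer_events(rooted, stree, cog_id = ids[k],
                          recent_max_species = cfg$recent_max_species)
      evs[[k]] <- inf$events
      recs[[k]] <- inf$reconciliation
      annotated[[k]] <- annotate_events(inf$reconciliation)
    }
    class(annotated) <- "multiPhylo"
    ape::write.tree(annotated,
                    file.path(out, "events", "annotated_trees.nwk"))
    write_tsv(do.call(rbind, evs), paths[1L])
    write_tsv(summarize_family(evs), paths[2L])
    prof <- reconstruct_copy_numbers(recs, stree)
    write_tsv(merge(prof$counts,
                    rbind(data.frame(child = NA, gains = NA, losses = NA),
                          prof$branches),
                    by.x = "node", by.y = "child", all.x = TRUE),
              paths[3L])
  })

  run_stage("selection", c("selection/branch_models.tsv",
                           "selection/pairwise_omega.tsv"), function(paths) {
    tr_path <- file.path(out, "trees", "cog_trees.nwk")
    if (!file.exists(tr_path))
      stop("selection stage: missing upstream output ", tr_path)
    trees <- ape::read.tree(tr_path)
    if (inherits(trees, "phylo")) trees <- list(trees)
    ids <- readLines(file.path(out, "trees", "cog_ids.txt"))
    cds <- read_fasta(file.path(out, "filtered", "kept_cds.fasta"))
    prot <- translate_cds(cds); names(prot) <- names(cds)
    kept_maps <- read_tsv(file.path(out, "trees", "kept_columns.tsv"))
    dir.create(file.path(out, "selection"), showWarnings = FALSE)
    branch_rows <- list(); pw_rows <- list(); m3_rows <- list()
    for (k in seq_along(ids)) {
      cid <- ids[k]
      tr <- trees[[k]]
      kept <- kept_maps$kept[kept_maps$cog_id == cid]
      codon_aln <- back_translate(prot[tr$tip.label], cds[tr$tip.label],
                                  kept = kept)
      rooted <- root_gene_tree(tr, stree)
      sgs <- detect_subgroups(rooted, stree)
      pw <- subgroup_pairwise_omega(codon_aln, sgs, ds_max = cfg$ds_max)
      pw_rows[[cid]] <- cbind(cog_id = cid, pw)
      null_fit <- fit_branch_model(codon_aln, rooted,
                                   branch_mode = cfg$branch_mode)
      alt_fit <- fit_branch_model(codon_aln, rooted,
                                  branch_classes = "partition",
                                  branch_mode = cfg$branch_mode)
      lr <- lrt(null_fit, alt_fit)
      branch_rows[[cid]] <- data.frame(
        cog_id = cid, minus_lnL_null = null_fit$minus_lnL,
        omega_null = unname(null_fit$omega[1L]),
        minus_lnL_alt = alt_fit$minus_lnL,
        omega_alt = paste(sprintf("%s=%.3f", names(alt_fit$omega),
                                  alt_fit$omega), collapse = "; "),
        lrt_p = lr$p)
      if (isTRUE(cfg$fit_switching)) {
        m3 <- fit_m3(codon_aln, rooted)
        s1 <- fit_m3_s1(codon_aln, rooted, init = m3)
        lr2 <- lrt(m3, s1)
        pos <- partition_positive_sites(s1, stree, kept = kept)
        m3_rows[[cid]] <- data.frame(
          cog_id = cid, minus_lnL_m3 = m3$minus_lnL,
          minus_lnL_m3s1 = s1$minus_lnL, delta = s1$delta,
          p1 = s1$p[1], p2 = s1$p[2], p3 = s1$p[3],
          omega1 = s1$omega[1], omega2 = s1$omega[2], omega3 = s1$omega[3],
          lrt_p = lr2$p,
          dicot_sites = paste(pos$dicot, collapse = ","),
          grass_sites = paste(pos$grass, collapse = ","))
      }
    }
    write_tsv(do.call(rbind, branch_rows), paths[1L])
    jsonlite::write_json(branch_rows,
                         file.path(out, "selection", "branch_models.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(do.call(rbind, pw_rows), paths[2L])
    if (length(m3_rows))
      write_tsv(do.call(rbind, m3_rows),
                file.path(out, "selection", "switching_models.tsv"))
  })

  run_stage("report", c("report/duplication_loss.tsv",
                        "report/branch_model.tsv",
                        "report/site_models.tsv",
                        "report/copy_number_profile.tsv"), function(paths) {
    make_report(out)
  })

  mf <- do.call(rbind, manifest)
  mf$digest <- NA_character_
  write_tsv(mf, file.path(out, "run_manifest.tsv"))
  mf
}

#' Assemble the report tables from stage outputs
#'
#' Emits the duplication/loss summary, the branch-model table, the
#' M3-vs-M3+S1 table and the copy-number profile TSV from whatever stage
#' outputs are present; absent pieces yield explicit `missing` cells, not
#' dropped rows.
#'
#' @param results_dir Pipeline output directory.
#' @return Invisibly, the report directory path.
#' @export
make_report <- function(results_dir) {
  rep_dir <- file.path(results_dir, "report")
  if (!dir.exists(rep_dir)) dir.create(rep_dir, recursive = TRUE)
  grab <- function(p) if (file.exists(p)) read_tsv(p) else NULL
  dl <- grab(file.path(results_dir, "events", "summary.tsv"))
  if (is.null(dl))
    dl <- data.frame(cog_id = "missing")
  write_tsv(dl, file.path(rep_dir, "duplication_loss.tsv"))
  bm <- grab(file.path(results_dir, "selection", "branch_models.tsv"))
  if (is.null(bm)) bm <- data.frame(cog_id = "missing")
  write_tsv(bm, file.path(rep_dir, "branch_model.tsv"))
  sm <- grab(file.path(results_dir, "selection", "switching_models.tsv"))
  if (is.null(sm)) {
    sm <- grab(file.path(results_dir, "selection", "branch_models.tsv"))
    if (!is.null(sm)) {
      sm <- data.frame(cog_id = sm$cog_id, minus_lnL_m3 = "missing",
                       minus_lnL_m3s1 = "missing")
    } else sm <- data.frame(cog_id = "missing")
  }
  write_tsv(sm, file.path(rep_dir, "site_models.tsv"))
  cn <- grab(file.path(results_dir, "events", "copy_numbers.tsv"))
  if (is.null(cn)) cn <- data.frame(node = "missing")
  write_tsv(cn, file.path(rep_dir, "copy_number_profile.tsv"))
  invisible(rep_dir)
}
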