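## Planted sequencing artifacts: allele-like near-duplicates and short
## fragments, which the filtering stage must remove.

#' Plant allele-like copies and short fragments into a dataset
#'
#' Adds (a) allele-like copies of chosen genes: same length, no indels,
#' point-mutated to the configured nucleotide identity; and (b) truncated
#' fragments shorter than the configured length. Planted records are listed
#' in a truth table.
#'
#' @param cds Named character vector of CDS sequences.
#' @param cfg A [sim_config()]; `allele_identity` and `fragment_length`
#'   are used.
#' @param n_alleles Number of allele copies to plant.
#' @param n_fragments Number of fragments to plant.
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return List with `cds` (augmented vector) and `truth` (data.frame:
#'   id, source, kind in {"allele","fragment"}).
#' @export
plant_artifacts <- function(cds, cfg, n_alleles = 2, n_fragments = 1,
                            seed = NULL) {
  if (cfg$allele_identity <= 0 || cfg$allele_identity > 1)
    stop("allele identity must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(cds) >= 1)
  truth <- list()
  add <- character(0)

  if (n_alleles > 0) {
    src <- sample(names(cds), n_alleles, replace = n_alleles > length(cds))
    for (i in seq_along(src)) {
      s <- cds[[src[i]]]
      mutated <- mutate_to_identity(s, cfg$allele_identity)
      id <- sprintf("%s_allele%d", src[i], i)
      add[id] <- mutated
      truth[[length(truth) + 1L]] <-
        data.frame(id = id, source = src[i], kind = "allele")
    }
  }
  if (n_fragments > 0) {
    src <- sample(names(cds), n_fragments, replace = n_fragments > length(cds))
    for (i in seq_along(src)) {
      len <- min(cfg$fragment_length, nchar(cds[[src[i]]]))
      len <- len - (len %% 3L)  # keep the fragment in frame
      id <- sprintf("%s_frag%d", src[i], i)
      add[id] <- substr(cds[[src[i]]], 1L, len)
      truth[[length(truth) + 1L]] <-
        data.frame(id = id, source = src[i], kind = "fragment")
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(id = character(0), source = character(0), kind = character(0))
  list(cds = c(cds, add), truth = truth)
}

# Point-mutate a CDS to approximately the target identity without creating
# indels or internal stop codons. Third positions are preferred but any
# position whose mutation leaves the codon sense is eligible.
mutate_to_identity <- function(s, identity) {
  v <- strsplit(s, "")[[1]]
  n <- length(v)
  n_mut <- round((1 - identity) * n)
  if (n_mut == 0) return(s)
  pos_pool <- sample.int(n)
  done <- 0L
  for (p in pos_pool) {
    if (done >= n_mut) break
    ci <- (p - 1L) %/% 3L
    cod_pos <- (ci * 3L + 1L):(ci * 3L + 3L)
    for (alt in sample(setdiff(NUC, v[p]))) {
      cand <- v
      cand[p] <- alt
      cod <- paste(cand[cod_pos], collapse = "")
      aa <- Biostrings::GENETIC_CODE[[cod]]
      if (!is.null(aa) && aa != "*") {
        v <- cand
        done <- done + 1L
        break
      }
    }
  }
  paste(v, collapse = "")
}
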