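## Sequence-set filtering: short-fragment removal and allele collapsing.
## Putative alleles are same-species pairs whose optimal global alignment
## has no gap characters and nucleotide identity above the cutoff; each
## allele-connected component keeps a single representative.

#' Filter sequence records (length and allele filters)
#'
#' Removes CDS shorter than `min_len_nt`, then collapses within-species
#' allele groups: a pair is an allele pair iff the optimal global CDS
#' alignment contains zero gaps AND identity > `allele_identity`. From each
#' allele-connected component the longest CDS (ties: lexicographically
#' smallest id) is kept. Candidate pairs are restricted to same-species
#' pairs with length difference <= 5%, since an indel-free global alignment
#' of very unequal sequences cannot reach the identity cutoff.
#'
#' @param cds Named character vector of CDS sequences; species are parsed
#'   from ids via [species_of_gene()].
#' @param min_len_nt Minimum CDS length in nucleotides (default 400).
#' @param allele_identity Identity threshold for allele pairs (default 0.95).
#' @return List with `kept` (named character vector) and `removed`
#'   (data.frame: id, reason in {"short","allele"}, kept_as).
#' @export
filter_sequences <- function(cds, min_len_nt = 400, allele_identity = 0.95) {
  stopifnot(!is.null(names(cds)), !anyDuplicated(names(cds)))
  removed <- list()
  len <- nchar(cds)
  short <- names(cds)[len < min_len_nt]
  for (id in short)
    removed[[length(removed) + 1L]] <-
      data.frame(id = id, reason = "short", kept_as = NA_character_)
  keep <- setdiff(names(cds), short)

  sp <- species_of_gene(keep)
  drop <- character(0)
  for (s in unique(sp)) {
    ids <- keep[sp == s]
    if (length(ids) < 2) next
    edges <- allele_pairs(cds[ids], allele_identity)
    if (!nrow(edges)) next
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = ids)
    comp <- igraph::components(g)$membership
    for (k in unique(comp)) {
      mem <- names(comp)[comp == k]
      if (length(mem) < 2) next
      rep_id <- mem[order(-nchar(cds[mem]), mem)][1L]
      for (id in setdiff(mem, rep_id)) {
        drop <- c(drop, id)
        removed[[length(removed) + 1L]] <-
          data.frame(id = id, reason = "allele", kept_as = rep_id)
      }
    }
  }
  kept <- cds[setdiff(keep, drop)]
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(0), reason = character(0),
               kept_as = character(0))
  list(kept = kept, removed = removed)
}

# Identify allele pairs among same-species sequences: global (Needleman-
# Wunsch) nucleotide alignment must be gap-free with identity above cutoff.
allele_pairs <- function(seqs, allele_identity) {
  ids <- names(seqs)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      a <- seqs[[ids[i]]]; b <- seqs[[ids[j]]]
      la <- nchar(a); lb <- nchar(b)
      if (abs(la - lb) / max(la, lb) > 0.05) next
      # a gap-free global alignment exists only for equal lengths, but the
      # optimal alignment must itself be gap-free, so align and inspect
      al <- Biostrings::pairwiseAlignment(
        a, b, type = "global",
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 1, mismatch = -1, baseOnly = TRUE),
        gapOpening = 4, gapExtension = 1)
      pa <- as.character(Biostrings::alignedPattern(al))
      ps <- as.character(Biostrings::alignedSubject(al))
      if (grepl("-", pa, fixed = TRUE) || grepl("-", ps, fixed = TRUE)) next
      va <- strsplit(pa, "")[[1]]; vb <- strsplit(ps, "")[[1]]
      ident <- mean(va == vb)
      if (ident > allele_identity)
        out[[length(out) + 1L]] <- data.frame(from = ids[i], to = ids[j])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(from = character(0), to = character(0))
}
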