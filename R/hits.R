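## All-against-all protein similarity: a built-in Smith-Waterman scorer
## (BLOSUM62, affine gaps) replacing the external BLAST step, plus an
## ingest path for precomputed blast outfmt-6 tables.

#' Score all protein pairs (built-in Smith-Waterman)
#'
#' Computes full local-alignment similarity for every cross-species pair of
#' proteins with BLOSUM62 and affine gap penalties (open 11, extend 1), the
#' classic protein-search scoring scheme. Self-hits are dropped.
#'
#' @param protein Named character vector of protein sequences.
#' @param include_same_species Score same-species pairs too (default TRUE;
#'   COG construction only uses cross-species edges, but paralog hits are
#'   reported for completeness).
#' @return A `hit_table` data.frame: query, subject, score, pident, length.
#' @export
score_all_pairs <- function(protein, include_same_species = TRUE) {
  ids <- names(protein)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  sp <- species_of_gene(ids)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  rows <- list()
  aaset <- Biostrings::AAStringSet(protein)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      if (!include_same_species && sp[i] == sp[j]) next
      al <- Biostrings::pairwiseAlignment(
        aaset[[i]], aaset[[j]], type = "local",
        substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1)
      sc <- Biostrings::score(al)
      if (sc <= 0) next
      pid <- Biostrings::pid(al)
      alen <- nchar(as.character(Biostrings::alignedPattern(al)))
      rows[[length(rows) + 1L]] <-
        data.frame(query = c(ids[i], ids[j]), subject = c(ids[j], ids[i]),
                   score = sc, pident = pid, length = alen)
    }
  }
  ht <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), subject = character(0),
               score = numeric(0), pident = numeric(0), length = integer(0))
  class(ht) <- c("hit_table", "data.frame")
  ht
}

#' Read a blast outfmt-6 style hit table
#'
#' Ingests the 12-column tabular dialect (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore),
#' validates ids against the known gene set, and drops self-hits.
#'
#' @param path Path to the TSV file (no header).
#' @param known_ids Optional character vector of valid gene ids.
#' @return A `hit_table` data.frame: query, subject, score, pident, length.
#' @export
read_hit_table <- function(path, known_ids = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12L)
    stop("expected 12 tab-separated columns, found ", ncol(df))
  names(df) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")
  if (!is.null(known_ids)) {
    unknown <- setdiff(unique(c(df$qseqid, df$sseqid)), known_ids)
    if (length(unknown))
      stop("hit table references unknown ids: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  ht <- data.frame(query = df$qseqid, subject = df$sseqid,
                   score = df$bitscore, pident = df$pident,
                   length = df$length)
  ht <- ht[ht$query != ht$subject, , drop = FALSE]
  if (any(!is.finite(ht$score)) || any(ht$score < 0))
    stop("hit scores must be finite and >= 0")
  class(ht) <- c("hit_table", "data.frame")
  ht
}
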