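## Best-hit (BeT) graph: for every gene and every foreign species, the
## top-scoring subject in that species; reciprocal when mutual.

#' Compute the BeT graph from a hit table
#'
#' For each gene g and each foreign species B, `BeT(g, B)` is the
#' highest-scoring subject in B (ties broken by higher percent identity,
#' then lexicographically smallest subject id). An edge g -> h is marked
#' reciprocal iff h's BeT back into g's species is g.
#'
#' @param hits A `hit_table` from [score_all_pairs()] or [read_hit_table()].
#' @param species_of Optional named character vector gene -> species;
#'   defaults to parsing ids with [species_of_gene()].
#' @return A `bet_graph` data.frame of directed edges: from, to, score,
#'   reciprocal (logical).
#' @export
compute_bets <- function(hits, species_of = NULL) {
  if (!nrow(hits)) stop("empty hit table")
  ids <- unique(c(hits$query, hits$subject))
  sp <- if (is.null(species_of)) stats::setNames(species_of_gene(ids), ids)
        else species_of
  h <- hits[sp[hits$query] != sp[hits$subject], , drop = FALSE]
  if (!nrow(h)) {
    edges <- data.frame(from = character(0), to = character(0),
                        score = numeric(0), reciprocal = logical(0))
    class(edges) <- c("bet_graph", "data.frame")
    return(edges)
  }
  key <- paste(h$query, sp[h$subject], sep = "\r")
  # deterministic best hit per (query, foreign species)
  ord <- order(key, -h$score, -h$pident, h$subject, method = "radix")
  h <- h[ord, , drop = FALSE]
  best <- h[!duplicated(key[ord]), , drop = FALSE]
  bet_of <- stats::setNames(best$subject, paste(best$query, sp[best$subject],
                                                sep = "\r"))
  reciprocal <- vapply(seq_len(nrow(best)), function(i) {
    back <- bet_of[paste(best$subject[i], sp[best$query[i]], sep = "\r")]
    !is.na(back) && back == best$query[i]
  }, logical(1))
  edges <- data.frame(from = best$query, to = best$subject,
                      score = best$score, reciprocal = reciprocal)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  class(edges) <- c("bet_graph", "data.frame")
  edges
}
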