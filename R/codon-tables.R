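## Codon state space and genetic-code bookkeeping shared by the simulator,
## the NG86 counter and the likelihood machinery.  The standard code is fixed;
## the 3 stop codons are excluded, leaving 61 sense-codon states.

NUC <- c("T", "C", "A", "G")

#' The 61 sense codons of the standard genetic code
#'
#' Codons are ordered lexicographically in T, C, A, G (the conventional
#' ordering of codon-model software), with the three stop codons removed.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  all64 <- apply(expand.grid(NUC, NUC, NUC)[, 3:1], 1L, paste, collapse = "")
  aa <- Biostrings::GENETIC_CODE[all64]
  all64[aa != "*"]
}

.codon_env <- new.env(parent = emptyenv())

# Precomputed lookup tables: codon strings, amino acids, and for every
# ordered pair of codons differing at one position, whether the change is
# a transition and whether it is synonymous.
codon_tables <- function() {
  if (!is.null(.codon_env$tab)) return(.codon_env$tab)
  codons <- sense_codons()
  n <- length(codons)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  mat <- do.call(rbind, strsplit(codons, ""))
  diffpos <- matrix(0L, n, n)      # 0 = not a single-nt neighbour
  is_ts <- matrix(FALSE, n, n)     # transition?
  is_syn <- matrix(FALSE, n, n)    # synonymous?
  ts_pairs <- c("AG", "GA", "CT", "TC")
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(mat[i, ] != mat[j, ])
      if (length(d) == 1L) {
        diffpos[i, j] <- d
        is_ts[i, j] <- paste0(mat[i, d], mat[j, d]) %in% ts_pairs
        is_syn[i, j] <- aa[i] == aa[j]
      }
    }
  }
  .codon_env$tab <- list(codons = codons, aa = aa, mat = mat,
                         diffpos = diffpos, is_ts = is_ts, is_syn = is_syn)
  .codon_env$tab
}

#' Codon equilibrium frequencies
#'
#' Computes a frequency vector over the 61 sense codons under one of three
#' standard parameterizations: `uniform` (1/61 each), `F3x4`
#' (position-specific nucleotide frequencies multiplied and renormalized
#' over sense codons) or `F61` (empirical codon proportions).
#'
#' @param mode One of `"uniform"`, `"F3x4"`, `"F61"`.
#' @param codon_seqs Optional character vector of in-frame CDS strings used
#'   to estimate the frequencies for `F3x4`/`F61`; when absent, `F3x4`
#'   falls back to uniform nucleotide composition.
#' @return Named numeric vector of length 61 summing to 1.
#' @export
codon_frequencies <- function(mode = c("F3x4", "uniform", "F61"),
                              codon_seqs = NULL) {
  mode <- match.arg(mode)
  tab <- codon_tables()
  codons <- tab$codons
  if (mode == "uniform") {
    pi <- rep(1 / 61, 61)
  } else if (mode == "F3x4") {
    if (is.null(codon_seqs)) {
      f <- matrix(0.25, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
    } else {
      f <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, NUC))
      for (s in codon_seqs) {
        v <- strsplit(toupper(s), "")[[1]]
        if (length(v) %% 3L != 0L) stop("CDS length not a multiple of 3")
        pos <- rep_len(1:3, length(v))
        for (p in 1:3) {
          tb <- table(factor(v[pos == p], levels = NUC))
          f[p, ] <- f[p, ] + tb
        }
      }
      f <- f / rowSums(f)
    }
    pi <- f[1L, tab$mat[, 1L]] * f[2L, tab$mat[, 2L]] * f[3L, tab$mat[, 3L]]
  } else {
    if (is.null(codon_seqs)) stop("F61 requires codon sequences")
    cod <- unlist(lapply(toupper(codon_seqs), function(s) {
      substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    }))
    tb <- table(factor(cod[cod %in% codons], levels = codons))
    pi <- as.numeric(tb) + 0.5  # small pseudocount so no sense codon has mass 0
  }
  pi <- pi / sum(pi)
  names(pi) <- codons
  pi
}

#' Translate in-frame CDS to protein under the standard code
#'
#' @param cds Character vector of nucleotide strings (lengths multiples of 3).
#' @return Character vector of amino-acid strings; internal stops raise an error.
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) {
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L) stop("CDS length not a multiple of 3")
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(Biostrings::GENETIC_CODE[cod])
    if (anyNA(aa)) stop("CDS contains an untranslatable codon")
    if (any(aa == "*")) stop("CDS contains an internal stop codon")
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = TRUE)
}
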