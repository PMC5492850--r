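## Alignment-quality column scoring, column filtering, JTT-distance NJ
## trees with bootstrap, and protein -> codon back-translation.

#' Per-column conservation scores on a 0-100 scale
#'
#' The score of a column is the mean BLOSUM62 score over all residue pairs
#' in the column (pairs involving a gap contribute the matrix minimum),
#' rescaled linearly so the matrix minimum maps to 0 and the matrix maximum
#' (W/W) to 100. A column of identical residues therefore scores at least
#' as high as any mixed column with the same gap pattern.
#'
#' @param aln Named character vector of aligned protein rows (equal
#'   lengths; `-` for gaps).
#' @return Numeric vector of per-column scores.
#' @export
column_scores <- function(aln) {
  if (length(aln) < 2) stop("need at least 2 sequences")
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  if (length(unique(nchar(aln))) != 1L) stop("rows have unequal lengths")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- BLOSUM62[1:20, 1:20]  # the 20 standard residues
  lo <- min(B); hi <- max(B)
  n <- nrow(mat)
  vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    ok <- col %in% rownames(B)
    tot <- 0
    npair <- n * (n - 1) / 2
    if (sum(ok) >= 2) {
      sub <- col[ok]
      for (a in seq_along(sub)) {
        for (b in seq_len(a - 1L)) tot <- tot + B[sub[a], sub[b]]
      }
    }
    n_gap_pairs <- npair - sum(ok) * (sum(ok) - 1) / 2
    tot <- tot + n_gap_pairs * lo
    100 * (tot / npair - lo) / (hi - lo)
  }, numeric(1))
}

#' Filter alignment columns by conservation score
#'
#' Retains columns scoring strictly greater than `threshold` and returns
#' the original-column index of every kept column, needed later for codon
#' back-mapping and for reporting site coordinates.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param threshold Score cutoff on the 0-100 scale (default 12, the
#'   conventional low-quality-column cutoff).
#' @return List with `aln` (filtered rows) and `kept` (integer map).
#' @export
filter_columns <- function(aln, threshold = 12) {
  sc <- column_scores(aln)
  kept <- which(sc > threshold)
  if (!length(kept))
    stop("all columns removed at threshold ", threshold,
         "; review the threshold")
  mat <- do.call(rbind, strsplit(aln, ""))
  filtered <- apply(mat[, kept, drop = FALSE], 1L, paste, collapse = "")
  list(aln = stats::setNames(filtered, names(aln)), kept = kept,
       scores = sc)
}

#' Pairwise maximum-likelihood JTT distances
#'
#' For every sequence pair, the distance maximizing the likelihood of the
#' shared ungapped columns under the JTT replacement model (published
#' exchangeabilities and stationary frequencies, rate matrix normalized to
#' one expected replacement per site). Gapped or non-standard positions
#' are deleted pairwise. The 1-D likelihood is maximized by bracketed
#' derivative-free search on `[1e-6, max_dist]` to tolerance 1e-8.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param max_dist Upper search bound; saturated pairs (optimum at the
#'   bound) are set to this value and flagged.
#' @return List with `D` (a symmetric matrix) and `saturated` (logical
#'   matrix of pairs at the bound).
#' @export
jtt_distances <- function(aln, max_dist = 50) {
  if (length(aln) < 2) stop("need at least 2 sequences")
  ed <- jtt_eigen()
  aa <- ed$aa
  mat <- do.call(rbind, strsplit(toupper(aln), ""))
  idx <- matrix(match(mat, aa), nrow(mat), ncol(mat))
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(D))
  logpi <- log(ed$pi)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
      if (!any(ok))
        stop("pair ", names(aln)[i], "/", names(aln)[j],
             " shares no ungapped sites")
      cnt <- table(factor(idx[i, ok], levels = 1:20),
                   factor(idx[j, ok], levels = 1:20))
      cnt <- unclass(cnt)
      nz <- which(cnt > 0, arr.ind = TRUE)
      w <- cnt[nz]
      f <- function(logt) {
        P <- prob_matrix(ed, exp(logt))
        -sum(w * (logpi[nz[, 1]] + log(pmax(P[nz], 1e-300))))
      }
      if (all(idx[i, ok] == idx[j, ok])) {
        D[i, j] <- D[j, i] <- 0
        next
      }
      opt <- stats::optimize(f, c(log(1e-6), log(max_dist)), tol = 1e-8)
      t_hat <- exp(opt$minimum)
      if (t_hat > max_dist * 0.98) {
        t_hat <- max_dist
        sat[i, j] <- sat[j, i] <- TRUE
      }
      D[i, j] <- D[j, i] <- t_hat
    }
  }
  list(D = D, saturated = sat)
}

# Eigendecomposition of the JTT rate matrix (cached).  Exchangeabilities
# and stationary frequencies are taken from phangorn's published model
# tables; the matrix is normalized to 1 expected replacement/site.
jtt_eigen <- function() {
  if (!is.null(.codon_env$jtt_ed)) return(.codon_env$jtt_ed)
  jtt <- get(".JTT", envir = asNamespace("phangorn"))
  aa <- toupper(c("a", "r", "n", "d", "c", "q", "e", "g", "h", "i", "l",
                  "k", "m", "f", "p", "s", "t", "w", "y", "v"))
  S <- matrix(0, 20, 20, dimnames = list(aa, aa))
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  pi <- stats::setNames(as.numeric(jtt$bf), aa)
  pi <- pi / sum(pi)
  Q <- S * rep(pi, each = 20)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  ed <- rev_eigen(Q, pi)
  ed$pi <- pi
  ed$aa <- aa
  .codon_env$jtt_ed <- ed
  ed
}

#' Neighbor-joining tree with clamped branch lengths
#'
#' Canonical Saitou-Nei neighbor joining on a symmetric distance matrix;
#' negative branch-length estimates are clamped to 0 and flagged.
#'
#' @param D Symmetric distance matrix (zero diagonal, n >= 3).
#' @return List with `tree` (unrooted [ape::phylo]) and `clamped` (number
#'   of negative branch estimates set to 0).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric")
  tr <- ape::nj(as.dist(D))
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  list(tree = tr, clamped = clamped)
}

#' Bootstrap support for the JTT-distance NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the JTT distance
#' matrix and NJ tree per replicate, and reports for each internal edge of
#' the full-data tree the percentage of replicates containing that
#' bipartition. Deterministic given `seed`.
#'
#' @param aln Named character vector of aligned protein rows.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List with `tree` (the full-data NJ tree, `node.label` carrying
#'   supports), `support` (numeric per internal node), `skipped`
#'   (replicates dropped because a pair shared no sites).
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1) {
  set.seed(seed)
  ncol_aln <- unique(nchar(aln))
  stopifnot(length(ncol_aln) == 1L)
  full <- nj_tree(jtt_distances(aln)$D)$tree
  mat <- do.call(rbind, strsplit(aln, ""))
  rownames(mat) <- names(aln)
  reps <- list()
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    sub <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    res <- tryCatch({
      d <- jtt_distances(stats::setNames(sub, names(aln)))$D
      if (any(!is.finite(d))) stop("unusable replicate")
      nj_tree(d)$tree
    }, error = function(e) NULL)
    if (is.null(res)) skipped <- skipped + 1L else
      reps[[length(reps) + 1L]] <- res
  }
  if (skipped > 0.01 * n_reps)
    warning(sprintf("%d of %d bootstrap replicates skipped", skipped, n_reps))
  class(reps) <- "multiPhylo"
  cl <- ape::prop.clades(full, reps, rooted = FALSE)
  cl[is.na(cl)] <- 0
  support <- round(100 * cl / length(reps), 1)
  full$node.label <- as.character(support)
  list(tree = full, support = support, skipped = skipped)
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column expands to its source codon triple; protein gaps
#' become `---`. When a kept-column map from [filter_columns()] is given,
#' only those columns are expanded.
#'
#' @param protein_aln Named character vector of aligned protein rows.
#' @param cds_by_id Named character vector of ungapped CDS for each row.
#' @param kept Optional integer vector of original columns to retain.
#' @return Named character vector of codon-aligned rows (length = 3 x
#'   number of retained columns).
#' @export
back_translate <- function(protein_aln, cds_by_id, kept = NULL) {
  out <- vapply(names(protein_aln), function(id) {
    prow <- strsplit(protein_aln[[id]], "")[[1]]
    cds <- cds_by_id[[id]]
    if (is.null(cds)) stop("no CDS for sequence ", id)
    ncod <- sum(prow != "-")
    if (nchar(cds) < 3 * ncod)
      stop("CDS of ", id, " shorter than its aligned protein")
    codons <- substring(cds, seq(1, 3 * ncod, 3), seq(3, 3 * ncod, 3))
    aa <- unname(Biostrings::GENETIC_CODE[toupper(codons)])
    res <- prow[prow != "-"]
    mism <- which(aa != res)
    if (length(mism))
      stop("translation mismatch for ", id, " at aligned residue ",
           which(prow != "-")[mism[1L]], " (codon ", mism[1L], ")")
    cells <- rep("---", length(prow))
    cells[prow != "-"] <- codons
    if (!is.null(kept)) cells <- cells[kept]
    paste(cells, collapse = "")
  }, character(1))
  stats::setNames(out, names(protein_aln))
}
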