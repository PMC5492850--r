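## Nei-Gojobori (1986) counting estimator of dN/dS, used both as a fast
## estimator and as the independent cross-check for the likelihood method.

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Synonymous site fractions per codon come from single-nucleotide mutation
#' enumeration (changes creating stop codons are excluded from both
#' numerator and denominator); observed synonymous/nonsynonymous
#' differences are averaged over all minimal mutational paths between each
#' codon pair (paths passing through stop codons are discarded); the
#' Jukes-Cantor correction turns proportions into distances.
#'
#' @param a,b Gap-free, equal-length, in-frame codon sequences (strings).
#' @return List of class `pairwise_omega`: `dN`, `dS`, `omega`, `pN`, `pS`,
#'   `N`, `S`, `saturated` (JC correction undefined, distances infinite),
#'   `undefined` (dS == 0), `method = "counting"`.
#' @export
ng86_pairwise <- function(a, b) {
  ca <- split_codons(a); cb <- split_codons(b)
  if (length(ca) != length(cb)) stop("sequences differ in codon length")
  tab <- codon_tables()
  ia <- match(ca, tab$codons); ib <- match(cb, tab$codons)
  if (anyNA(ia) || anyNA(ib)) stop("sequences contain stop or invalid codons")
  sites <- ng86_site_fractions()
  S <- (sum(sites[ia]) + sum(sites[ib])) / 2
  N <- 3 * length(ia) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(ia)) {
    if (ia[k] == ib[k]) next
    d <- ng86_path_differences(ia[k], ib[k])
    Sd <- Sd + d$syn
    Nd <- Nd + d$nonsyn
  }
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) {
    if (p >= 3 / 4) return(Inf)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  saturated <- !is.finite(dS) || !is.finite(dN)
  undefined <- !saturated && dS == 0
  omega <- if (saturated || undefined) NA_real_ else dN / dS
  structure(list(dN = dN, dS = dS, omega = omega, pN = pN, pS = pS,
                 N = N, S = S, saturated = saturated,
                 undefined = undefined, method = "counting"),
            class = "pairwise_omega")
}

split_codons <- function(s) {
  s <- toupper(s)
  if (nchar(s) %% 3L != 0L) stop("length not a multiple of 3")
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

# Synonymous site count per sense codon: per position the fraction of
# non-stop single-nucleotide changes that are synonymous, summed over the
# three positions.
ng86_site_fractions <- function() {
  if (!is.null(.codon_env$ng86_sites)) return(.codon_env$ng86_sites)
  tab <- codon_tables()
  s <- numeric(61)
  for (i in seq_len(61)) {
    for (pos in 1:3) {
      nb <- which(tab$diffpos[i, ] == pos)  # sense-codon neighbours only
      n_valid <- length(nb)                 # stop targets already excluded
      if (n_valid)
        s[i] <- s[i] + sum(tab$is_syn[i, nb]) / n_valid
    }
  }
  .codon_env$ng86_sites <- s
  s
}

# Average synonymous/nonsynonymous step counts over all minimal mutational
# paths between two codons, skipping paths through stop codons.
ng86_path_differences <- function(i, j) {
  tab <- codon_tables()
  diffs <- which(tab$mat[i, ] != tab$mat[j, ])
  perms <- all_permutations(diffs)
  tot_syn <- 0; tot_non <- 0; n_ok <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- tab$mat[i, ]
    syn <- 0L; non <- 0L; ok <- TRUE
    from <- i
    for (pos in perms[p, ]) {
      cur[pos] <- tab$mat[j, pos]
      nxt <- match(paste(cur, collapse = ""), tab$codons)
      if (is.na(nxt)) { ok <- FALSE; break }  # stop codon on the path
      if (tab$is_syn[from, nxt]) syn <- syn + 1L else non <- non + 1L
      from <- nxt
    }
    if (ok) {
      tot_syn <- tot_syn + syn
      tot_non <- tot_non + non
      n_ok <- n_ok + 1L
    }
  }
  if (n_ok == 0L) {
    # every path passes a stop codon (possible only for some 2-3 step
    # pairs); fall back to equal weighting of the raw difference count
    return(list(syn = 0, nonsyn = length(diffs)))
  }
  list(syn = tot_syn / n_ok, nonsyn = tot_non / n_ok)
}

all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (k in seq_len(n)) {
    rest <- all_permutations(x[-k])
    out <- rbind(out, cbind(x[k], rest))
  }
  out
}
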