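# Independent brute-force oracles.  These deliberately re-derive results
# from first principles (dynamic programming, exhaustive enumeration) and
# never call the package code paths they are used to check.

# --- Smith-Waterman with affine gaps, plain DP ---------------------------
oracle_sw_score <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)      # best ending in match
  X <- matrix(NEG, n + 1, m + 1)    # gap in b (deletion)
  Y <- matrix(NEG, n + 1, m + 1)    # gap in a (insertion)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- BLOSUM62[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j], X[i, j], Y[i, j])
    }
  }
  best
}

# --- NG86 path differences by recursive DFS over substitution orders -----
oracle_ng86_pair <- function(a, b) {
  codons <- sense_codons()
  code <- Biostrings::GENETIC_CODE
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  syn_sites <- function(cod) {
    s <- 0
    v <- strsplit(cod, "")[[1]]
    for (p in 1:3) {
      alts <- setdiff(c("T", "C", "A", "G"), v[p])
      ok <- 0; syn <- 0
      for (alt in alts) {
        w <- v; w[p] <- alt
        aa <- code[[paste(w, collapse = "")]]
        if (aa != "*") {
          ok <- ok + 1
          if (aa == code[[cod]]) syn <- syn + 1
        }
      }
      if (ok > 0) s <- s + syn / ok
    }
    s
  }
  paths <- function(x, y) {
    # returns list of c(syn, nonsyn) averaged over valid orderings
    d <- which(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    if (!length(d)) return(c(0, 0))
    acc <- c(0, 0); nvalid <- 0
    recurse <- function(cur, remaining, syn, non) {
      if (!length(remaining)) {
        acc <<- acc + c(syn, non); nvalid <<- nvalid + 1
        return(invisible())
      }
      for (p in remaining) {
        v <- strsplit(cur, "")[[1]]
        v[p] <- strsplit(y, "")[[1]][p]
        nxt <- paste(v, collapse = "")
        if (code[[nxt]] == "*") next
        if (code[[nxt]] == code[[cur]])
          recurse(nxt, setdiff(remaining, p), syn + 1, non)
        else recurse(nxt, setdiff(remaining, p), syn, non + 1)
      }
    }
    recurse(x, d, 0, 0)
    if (nvalid == 0) return(c(0, length(d)))
    acc / nvalid
  }
  S <- (sum(vapply(ca, syn_sites, numeric(1))) +
        sum(vapply(cb, syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  sd_nd <- c(0, 0)
  for (k in seq_along(ca)) sd_nd <- sd_nd + paths(ca[k], cb[k])
  pS <- sd_nd[1] / S; pN <- sd_nd[2] / N
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd_nd[1], Nd = sd_nd[2],
       pS = pS, pN = pN, dS = jc(pS), dN = jc(pN))
}

# --- exhaustive reconciliation over all valid maps -----------------------
# Minimum duplication count (and min dup+loss) of a rooted gene tree
# against a species tree, by enumerating every ancestor-consistent mapping
# of internal gene nodes to species nodes.
oracle_reconcile_min <- function(gtree, stree) {
  sphy <- stree$phylo
  ns <- ape::Ntip(sphy) + sphy$Nnode
  # ancestor-or-equal and LCA tables
  anc <- matrix(FALSE, ns, ns)
  parent <- rep(NA_integer_, ns); parent[sphy$edge[, 2]] <- sphy$edge[, 1]
  for (v in seq_len(ns)) {
    u <- v
    while (!is.na(u)) { anc[u, v] <- TRUE; u <- parent[u] }
  }
  depth <- integer(ns)
  for (v in seq_len(ns)) depth[v] <- sum(anc[, v]) - 1L
  lca_tab <- matrix(0L, ns, ns)
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    common <- which(anc[, i] & anc[, j])
    lca_tab[i, j] <- common[which.max(depth[common])]
  }
  ntip <- ape::Ntip(gtree)
  nint <- gtree$Nnode
  leafmap <- match(species_of_gene(gtree$tip.label), sphy$tip.label)
  kids <- lapply(seq_len(ntip + nint), function(v)
    gtree$edge[gtree$edge[, 1] == v, 2])
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), nint)))
  colmap <- function(v) {
    if (v <= ntip) rep(leafmap[v], nrow(grid)) else grid[, v - ntip]
  }
  ok <- rep(TRUE, nrow(grid))
  dups <- integer(nrow(grid)); losses <- integer(nrow(grid))
  for (v in (ntip + 1L):(ntip + nint)) {
    mv <- colmap(v)
    ch <- kids[[v]]
    m1 <- colmap(ch[1]); m2 <- colmap(ch[2])
    ok <- ok & anc[cbind(mv, m1)] & anc[cbind(mv, m2)]
    isdup <- (mv == m1) | (mv == m2) | (lca_tab[cbind(m1, m2)] != mv)
    dups <- dups + isdup
    losses <- losses + (depth[m1] - depth[mv]) - 1L + isdup +
      (depth[m2] - depth[mv]) - 1L + isdup
  }
  if (!any(ok)) stop("no valid reconciliation map found")
  list(min_dup = min(dups[ok]),
       min_dup_plus_loss = min((dups + losses)[ok]))
}

# --- exhaustive subgroup scan --------------------------------------------
oracle_subgroups <- function(rooted, stree) {
  part <- stree$partition
  ntip <- ape::Ntip(rooted)
  nall <- ntip + rooted$Nnode
  tipset <- function(v) {
    if (v <= ntip) rooted$tip.label[v]
    else ape::extract.clade(rooted, v)$tip.label
  }
  parent <- rep(NA_integer_, nall)
  parent[rooted$edge[, 2]] <- rooted$edge[, 1]
  pure <- function(v) {
    p <- unique(part[species_of_gene(tipset(v))])
    if (length(p) == 1L) p else NA_character_
  }
  res <- list()
  for (v in seq_len(nall)) {
    p <- pure(v)
    if (is.na(p)) next
    pp <- parent[v]
    if (!is.na(pp) && !is.na(pure(pp))) next  # not maximal
    res[[length(res) + 1L]] <- list(node = v, partition = p,
                                    members = sort(tipset(v)))
  }
  res
}
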