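## Felsenstein pruning over codon states with per-node rescaling, plus the
## up/down pass that yields per-node marginal posteriors (used by the
## switching model's clade-specific site partitioning).

# Convert gap-free or gapped codon rows to integer states (NA = gap or
# ambiguous, treated as missing data).
codon_states <- function(cds) {
  tab <- codon_tables()
  ids <- names(cds)
  rows <- lapply(cds, split_codons)
  len <- unique(lengths(rows))
  if (length(len) != 1L) stop("codon rows have unequal lengths")
  st <- matrix(NA_integer_, length(rows), len, dimnames = list(ids, NULL))
  for (i in seq_along(rows)) {
    s <- match(rows[[i]], tab$codons)
    bad <- is.na(s) & !grepl("-", rows[[i]], fixed = TRUE)
    if (any(bad)) stop("invalid codon in ", ids[i], ": ", rows[[i]][bad][1L])
    st[i, ] <- s
  }
  st
}

# Indicator tip partials (nstates x nsites) for one tip; NA -> all ones.
# The state row is kept as an attribute so the pruning pass can replace
# the P %*% indicator product by direct column gathers.
tip_partial <- function(states_row, nstates, n_classes = 1L) {
  nsites <- length(states_row)
  m <- matrix(0, nstates, nsites)
  ok <- !is.na(states_row)
  if (n_classes == 1L) {
    m[cbind(states_row[ok], which(ok))] <- 1
  } else {
    for (k in seq_len(n_classes)) {
      m[cbind((k - 1L) * (nstates / n_classes) + states_row[ok],
              which(ok))] <- 1
    }
  }
  m[, !ok] <- 1
  attr(m, "states") <- states_row
  attr(m, "n_classes") <- n_classes
  m
}

# P %*% tip_indicator via column selection (sums class blocks for the
# expanded switching state space).
edge_term <- function(P, part) {
  st <- attr(part, "states")
  if (is.null(st)) return(P %*% part)
  K <- attr(part, "n_classes")
  n <- nrow(P)
  block <- n / K
  out <- matrix(1, n, length(st))
  ok <- !is.na(st)
  if (any(ok)) {
    acc <- P[, st[ok], drop = FALSE]
    if (K > 1L)
      for (k in seq_len(K - 1L))
        acc <- acc + P[, k * block + st[ok], drop = FALSE]
    out[, ok] <- acc
  }
  out
}

# Per-site log-likelihood by pruning.  `P_by_edge` is a list over edges of
# the postorder-reordered tree.  Returns list(site_ll, partials, logscale)
# so callers can reuse the up-pass for posteriors.
pruning_site_loglik <- function(phy_post, P_by_edge, tip_parts, prior,
                                keep_partials = FALSE) {
  ntip <- ape::Ntip(phy_post)
  nnode_all <- ntip + phy_post$Nnode
  nsites <- ncol(tip_parts[[1L]])
  part <- vector("list", nnode_all)
  for (i in seq_len(ntip)) part[[i]] <- tip_parts[[i]]
  logscale <- numeric(nsites)
  edges <- phy_post$edge
  parents <- unique(edges[, 1])  # postorder: children appear before parents
  for (v in parents) {
    es <- which(edges[, 1] == v)
    prod <- NULL
    for (e in es) {
      term <- edge_term(P_by_edge[[e]], part[[edges[e, 2]]])
      prod <- if (is.null(prod)) term else prod * term
    }
    sc <- colSums(prod)
    sc[sc <= 0] <- 1e-300
    part[[v]] <- prod / rep(sc, each = nrow(prod))
    logscale <- logscale + log(sc)
  }
  root <- ntip + 1L
  site_ll <- log(pmax(colSums(prior * part[[root]]), 1e-300)) + logscale
  if (keep_partials) list(site_ll = site_ll, partials = part)
  else list(site_ll = site_ll)
}

# Marginal per-node posteriors over states for every site via the standard
# outside (down) pass; partials must come from pruning_site_loglik with
# keep_partials = TRUE.  Returns a list over nodes of nstates x nsites
# matrices of posteriors (columns sum to 1).
node_marginals <- function(phy_post, P_by_edge, up, prior) {
  ntip <- ape::Ntip(phy_post)
  nnode_all <- ntip + phy_post$Nnode
  nsites <- ncol(up$partials[[ntip + 1L]])
  edges <- phy_post$edge
  outside <- vector("list", nnode_all)
  root <- ntip + 1L
  outside[[root]] <- matrix(prior, nrow = length(prior), ncol = nsites)
  # preorder traversal: reverse postorder parent list
  for (v in rev(unique(edges[, 1]))) {
    es <- which(edges[, 1] == v)
    terms <- lapply(es, function(e)
      edge_term(P_by_edge[[e]], up$partials[[edges[e, 2]]]))
    for (k in seq_along(es)) {
      e <- es[k]
      oth <- outside[[v]]
      for (l in seq_along(es)) if (l != k) oth <- oth * terms[[l]]
      o <- crossprod(P_by_edge[[e]], oth)  # t(P) %*% oth
      sc <- colSums(o); sc[sc <= 0] <- 1e-300
      outside[[edges[e, 2]]] <- o / rep(sc, each = nrow(o))
    }
  }
  post <- vector("list", nnode_all)
  for (v in seq_len(nnode_all)) {
    m <- outside[[v]] * up$partials[[v]]
    sc <- colSums(m); sc[sc <= 0] <- 1e-300
    post[[v]] <- m / rep(sc, each = nrow(m))
  }
  post
}
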