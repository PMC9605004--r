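# Shared fixtures and independent oracles used across the suite.

rand_protein <- function(len, alphabet = aa_alphabet()) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

blosum62_20 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[aa_alphabet(), aa_alphabet()]
}

# --- Local-alignment oracles -------------------------------------------------
# Top-down exhaustive search over all gapped local alignments (affine gaps,
# opening a length-1 gap costs go + ge). Memoised on (i, j, previous move);
# independent of the package's bottom-up C++ DP.
oracle_sw <- function(a, b, S = blosum62_20(), go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  memo <- array(NA_real_, c(n + 1, m + 1, 3))  # states: M, E(gap in a), F
  rec <- function(i, j, s) {
    v <- memo[i, j, s]
    if (!is.na(v)) return(v)
    best <- 0  # alignment may stop here
    if (i <= n && j <= m)
      best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, 1))
    if (j <= m)
      best <- max(best, -(if (s == 2) ge else go + ge) + rec(i, j + 1, 2))
    if (i <= n)
      best <- max(best, -(if (s == 3) ge else go + ge) + rec(i + 1, j, 3))
    memo[i, j, s] <<- best
    best
  }
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m))
    best <- max(best, S[A[i], B[j]] + rec(i + 1, j + 1, 1))
  best
}

# Pure enumeration for tiny sequences: generate every move string, score it
# with a separate scorer. No shared recurrence at all.
oracle_sw_enum <- function(a, b, S = blosum62_20(), go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  score_path <- function(i0, j0, moves) {
    sc <- 0; i <- i0; j <- j0; prev <- ""
    for (mv in moves) {
      if (mv == "M") { sc <- sc + S[A[i], B[j]]; i <- i + 1; j <- j + 1 }
      else if (mv == "E") { sc <- sc - (if (prev == "E") ge else go + ge); j <- j + 1 }
      else { sc <- sc - (if (prev == "F") ge else go + ge); i <- i + 1 }
      prev <- mv
    }
    sc
  }
  best <- 0
  walk <- function(i, j, moves) {
    if (length(moves))
      best <<- max(best, score_path(moves$i0, moves$j0, moves$mv))
    if (i <= n && j <= m)
      walk(i + 1, j + 1, list(i0 = moves$i0 %||% i, j0 = moves$j0 %||% j,
                              mv = c(moves$mv, "M")))
    if (j <= m && length(moves))
      walk(i, j + 1, list(i0 = moves$i0, j0 = moves$j0,
                          mv = c(moves$mv, "E")))
    if (i <= n && length(moves))
      walk(i + 1, j, list(i0 = moves$i0, j0 = moves$j0,
                          mv = c(moves$mv, "F")))
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (i in seq_len(n)) for (j in seq_len(m)) walk(i, j, list())
  best
}

# --- Tree oracles ------------------------------------------------------------
# Least-squares residual of fitting branch lengths of a fixed topology to a
# distance matrix; used for exhaustive-topology search.
ls_rss <- function(topo, dm) {
  taxa <- rownames(dm)
  nedge <- nrow(topo$edge)
  pairs <- t(combn(seq_along(taxa), 2))
  X <- matrix(0, nrow(pairs), nedge)
  # BFS paths over the unrooted tree graph
  nnode <- max(topo$edge)
  adj <- vector("list", nnode)
  for (e in seq_len(nedge)) {
    u <- topo$edge[e, 1]; v <- topo$edge[e, 2]
    adj[[u]] <- rbind(adj[[u]], c(v, e))
    adj[[v]] <- rbind(adj[[v]], c(u, e))
  }
  tip_idx <- match(taxa, topo$tip.label)
  for (r in seq_len(nrow(pairs))) {
    from <- tip_idx[pairs[r, 1]]; to <- tip_idx[pairs[r, 2]]
    # DFS with path tracking
    stack <- list(list(node = from, edges = integer()))
    seen <- rep(FALSE, nnode); seen[from] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$node == to) { X[r, cur$edges] <- 1; break }
      for (k in seq_len(NROW(adj[[cur$node]]))) {
        nb <- adj[[cur$node]][k, ]
        if (!seen[nb[1]]) {
          seen[nb[1]] <- TRUE
          stack[[length(stack) + 1]] <- list(node = nb[1],
                                             edges = c(cur$edges, nb[2]))
        }
      }
    }
  }
  dvec <- dm[pairs]
  fit <- lm.fit(X, dvec)
  sum(fit$residuals^2)
}

# Monte-Carlo expected p-distance between two tips separated by branch
# lengths b1 and b2, under Poisson point substitution with uniform
# replacement by a different residue. Independent of evolve_family.
mc_pdistance <- function(b1, b2, nsites = 50000) {
  aa <- aa_alphabet()
  jump <- function(x, k) {
    for (i in seq_len(k)) x <- sample(setdiff(aa, x), 1)
    x
  }
  anc <- sample(aa, nsites, replace = TRUE)
  k1 <- rpois(nsites, b1); k2 <- rpois(nsites, b2)
  t1 <- anc; t2 <- anc
  for (i in which(k1 > 0)) t1[i] <- jump(anc[i], k1[i])
  for (i in which(k2 > 0)) t2[i] <- jump(anc[i], k2[i])
  mean(t1 != t2)
}

# Random unrooted tree with strictly positive branch lengths.
rand_unrooted_tree <- function(ntaxa, min_len = 0.05, max_len = 0.5) {
  tr <- ape::rtree(ntaxa, br = function(n) runif(n, min_len, max_len))
  ape::unroot(tr)
}
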