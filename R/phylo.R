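# p-distances on a protein MSA, Saitou-Nei neighbor-joining, bootstrap
# supports, Newick output. Trees are ape `phylo` objects throughout.

#' Pairwise p-distances from an aligned block
#'
#' Proportion of differing sites per pair (amino-acid differences per
#' site). Gaps and `X` are not comparable: under `pairwise` deletion each
#' pair uses its own comparable sites; under `complete` deletion any
#' column with a gap or `X` in any record is dropped first.
#'
#' @param block An [aligned_block()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix with zero diagonal, entries in
#'   `[0, 1]`, taxa as dimnames.
#' @export
p_distance <- function(block, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(block, "aligned_block"))
  m <- as_char_matrix(block)
  ok <- m != "-" & m != "X"
  if (deletion == "complete") {
    keep <- colSums(!ok) == 0
    if (!any(keep)) stop("complete deletion removes every site")
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp))
        stop("no comparable sites between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      d[i, j] <- d[j, i] <- mean(m[i, comp] != m[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken deterministically by the lexicographically smallest pair of
#' cluster labels (each cluster is labelled by its smallest tip name), so
#' the result does not depend on taxon input order. Negative
#' branch-length estimates are clamped to 0; the
#' number of clamped branches is kept in the `"clamped"` attribute.
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return Unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <- paste0("t", 1:n)
  stopifnot(isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)))
  labs <- rownames(dm)       # newick fragment per active node
  keys <- rownames(dm)       # smallest tip name per cluster, for tie-breaks
  clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { clamped <<- clamped + 1L; 0 } else x
  }
  d <- dm
  while (nrow(d) > 3) {
    N <- nrow(d)
    r <- rowSums(d)
    q <- (N - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- c(NA, NA); bq <- Inf; bkey <- c("", "")  # set on first strict win
    for (i in 1:(N - 1)) for (j in (i + 1):N) {
      kp <- sort(c(keys[i], keys[j]))
      tie <- abs(q[i, j] - bq) <= 1e-12
      if (q[i, j] < bq - 1e-12 ||
          (tie && (kp[1] < bkey[1] ||
                   (kp[1] == bkey[1] && kp[2] < bkey[2])))) {
        bq <- q[i, j]; best <- c(i, j); bkey <- kp
      }
    }
    i <- best[1]; j <- best[2]
    vi <- clamp(d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2)))
    vj <- clamp(d[i, j] - (d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))))
    newlab <- sprintf("(%s:%.10g,%s:%.10g)", labs[i], vi, labs[j], vj)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    labs <- c(labs[keep], newlab)
    keys <- c(keys[keep], min(keys[i], keys[j]))
    rownames(d2) <- colnames(d2) <- paste0("n", seq_len(N - 1))
    d <- d2
  }
  # final three-point join
  v1 <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  v2 <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  v3 <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 labs[1], v1, labs[2], v2, labs[3], v3)
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# Canonical bipartitions of an unrooted tree: for each internal split the
# side NOT containing the lexicographically smallest taxon, as a sorted
# name set; trivial splits dropped.
.bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  out <- list()
  for (cl in pp) {
    side <- sort(tree$tip.label[cl])
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2 && length(side) <= length(tips) - 2)
      out[[paste(side, collapse = "|")]] <- side
  }
  out
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the p-distance
#' NJ tree per replicate, and reports for each internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition (as integer node labels). A replicate whose resampled
#' columns leave some pair with no comparable site is redrawn (up to 100
#' retries per replicate).
#'
#' @param block An [aligned_block()].
#' @param n_reps Number of bootstrap replicates (>= 1; 1000 is the
#'   conventional choice).
#' @param seed Integer seed; same seed, same supports.
#' @param deletion Gap-deletion rule passed to [p_distance()].
#' @return The original-tree `phylo` with `node.label` holding support
#'   percentages (empty for trivial splits).
#' @export
bootstrap_support <- function(block, n_reps = 1000, seed = 1,
                              deletion = "pairwise") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  stopifnot(inherits(block, "aligned_block"))
  m <- as_char_matrix(block)
  base_tree <- neighbor_joining(p_distance(block, deletion))
  target <- .bipartitions(base_tree)
  counts <- setNames(numeric(length(target)), names(target))
  block_from <- function(cols) {
    seqs <- apply(m[, cols, drop = FALSE], 1, paste, collapse = "")
    aligned_block(protein_set(rownames(m), seqs, gapped = TRUE))
  }
  withr::with_seed(seed, {
    for (b in seq_len(n_reps)) {
      bp <- NULL
      for (try in 1:100) {
        cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
        bp <- tryCatch(
          .bipartitions(neighbor_joining(p_distance(block_from(cols),
                                                    deletion))),
          error = function(e) NULL)
        if (!is.null(bp)) break
      }
      if (is.null(bp))
        stop("bootstrap replicate kept failing after 100 redraws")
      hit <- names(target) %in% names(bp)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / n_reps)
  # map supports onto internal nodes of the base tree
  tips <- sort(base_tree$tip.label)
  pp <- ape::prop.part(base_tree)
  lab <- character(base_tree$Nnode)
  for (k in seq_along(pp)) {
    side <- sort(base_tree$tip.label[pp[[k]]])
    if (tips[1] %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    if (key %in% names(support)) lab[k] <- as.character(support[key])
  }
  base_tree$node.label <- lab
  base_tree
}

#' Write a tree to Newick
#'
#' Branch lengths and (when present) integer bootstrap supports as
#' internal node labels, readable by standard viewers.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a distance matrix as TSV
#'
#' @param dm Symmetric distance matrix with taxa dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  out <- data.frame(taxon = rownames(dm), as.data.frame(dm),
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
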