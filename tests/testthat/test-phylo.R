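# p-distances, neighbor joining, bootstrap supports, Newick output.

make_block <- function(ids, seqs) {
  aligned_block(protein_set(ids, seqs, gapped = TRUE))
}

test_that("p_distance counts differences per comparable site", {
  blk <- make_block(c("a", "b"), c("GAV", "GAL"))
  expect_equal(p_distance(blk)["a", "b"], 1 / 3)

  same <- make_block(c("a", "b"), c("GAV", "GAV"))
  expect_equal(p_distance(same)["a", "b"], 0)

  gap <- make_block(c("a", "b"), c("GA-", "G-A"))
  expect_equal(p_distance(gap, "pairwise")["a", "b"], 0)  # site 1 only

  # complete deletion drops any column with a gap anywhere
  tri <- make_block(c("a", "b", "c"), c("GAV-", "GAL-", "GCVA"))
  dc <- p_distance(tri, "complete")
  expect_equal(dc["a", "b"], 1 / 3)

  allgap <- make_block(c("a", "b", "c"), c("GA--", "GA--", "--AA"))
  expect_error(p_distance(allgap), "no comparable sites.*'a'.*'c'")
})

test_that("three-taxon NJ reproduces the closed-form branch lengths", {
  dm <- matrix(c(0, 0.3, 0.5,
                 0.3, 0, 0.6,
                 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(dm)
  pl <- ape::cophenetic.phylo(tr)
  expect_equal(pl[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)
  # closed form: v_a = (d_ab + d_ac - d_bc)/2 = 0.1
  va <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(va, 0.1, tolerance = 1e-9)
  expect_error(neighbor_joining(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers topology and lengths from additive 4-taxon input", {
  tr0 <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.15,d:0.3):0.05);")
  dm <- ape::cophenetic.phylo(tr0)
  tr <- neighbor_joining(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr0), tr)), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
               tolerance = 1e-9)
})

test_that("NJ tree matches the exhaustive least-squares topology oracle", {
  skip_if_not_installed("phangorn")
  withr::local_seed(41)
  for (i in 1:5) {
    n <- sample(5:6, 1)
    tr0 <- rand_unrooted_tree(n)
    dm <- ape::cophenetic.phylo(tr0)
    nj <- neighbor_joining(dm)
    all_topo <- phangorn::allTrees(n, rooted = FALSE,
                                   tip.label = rownames(dm))
    rss <- vapply(all_topo, ls_rss, numeric(1), dm = dm)
    best <- all_topo[[which.min(rss)]]
    expect_equal(min(rss), 0, tolerance = 1e-12)
    expect_equal(as.numeric(ape::dist.topo(best, nj)), 0)
  }
})

test_that("path lengths reconstruct any additive matrix to 1e-9", {
  withr::local_seed(43)
  for (i in 1:10) {
    tr0 <- rand_unrooted_tree(sample(4:8, 1))
    dm <- ape::cophenetic.phylo(tr0)
    tr <- neighbor_joining(dm)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ agrees with an independent reference implementation", {
  withr::local_seed(47)
  blkseqs <- vapply(1:5, function(i) rand_protein(80), character(1))
  blk <- make_block(paste0("t", 1:5), blkseqs)
  dm <- p_distance(blk)
  ours <- neighbor_joining(dm)
  ref <- ape::nj(as.dist(dm))
  expect_equal(as.numeric(ape::dist.topo(ours, ape::unroot(ref))), 0)
})

test_that("negative NJ length estimates are clamped and counted", {
  # strongly non-additive matrix known to produce a negative NJ estimate
  dm <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 0.1,
                 1, 1, 0.1, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(dm)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 0)
})

test_that("a clean two-clade alignment gets 100% support", {
  blk <- make_block(c("a1", "a2", "b1", "b2"),
                    c("AAAAAGAAAAGA", "AAGAAAAAGAAA",
                      "WWWYWWWYWWWW", "WWWWWYWWWWYW"))
  tr <- bootstrap_support(blk, n_reps = 50, seed = 1)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(any(sup == 100, na.rm = TRUE))
})

test_that("single-replicate supports are 0 or 100 and seeds reproduce", {
  withr::local_seed(53)
  fam <- evolve_family(rand_unrooted_tree(5), root_length = 60, seed = 5)
  blk <- make_block(fam$records$id, fam$records$sequence)
  t1 <- bootstrap_support(blk, n_reps = 1, seed = 9)
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup %in% c(0, 100) | is.na(sup)))
  t2 <- bootstrap_support(blk, n_reps = 20, seed = 9)
  t3 <- bootstrap_support(blk, n_reps = 20, seed = 9)
  expect_equal(t2$node.label, t3$node.label)
  expect_error(bootstrap_support(blk, n_reps = 0), ">= 1")
})

test_that("bootstrap supports are invariant under taxon reordering", {
  withr::local_seed(59)
  fam <- evolve_family(rand_unrooted_tree(5), root_length = 80, seed = 7)
  blk1 <- make_block(fam$records$id, fam$records$sequence)
  ord <- rev(seq_len(nrow(fam$records)))
  blk2 <- make_block(fam$records$id[ord], fam$records$sequence[ord])
  t1 <- bootstrap_support(blk1, n_reps = 30, seed = 2)
  t2 <- bootstrap_support(blk2, n_reps = 30, seed = 2)
  key <- function(tr) {
    sup <- tr$node.label
    pp <- ape::prop.part(tr)
    tips <- sort(tr$tip.label)
    keys <- vapply(pp, function(cl) {
      side <- sort(tr$tip.label[cl])
      if (tips[1] %in% side) side <- setdiff(tips, side)
      paste(side, collapse = "|")
    }, character(1))
    setNames(sup, keys)[nzchar(sup)]
  }
  k1 <- key(t1); k2 <- key(t2)
  shared <- intersect(names(k1), names(k2))
  expect_true(length(shared) >= 1)
  expect_equal(k1[shared], k2[shared])
})

test_that("Newick output round-trips topology, lengths and supports", {
  withr::local_seed(61)
  fam <- evolve_family(rand_unrooted_tree(6), root_length = 120, seed = 13)
  blk <- make_block(fam$records$id, fam$records$sequence)
  tr <- bootstrap_support(blk, n_reps = 10, seed = 3)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
})
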