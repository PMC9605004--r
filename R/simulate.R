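# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes: labelled composition panels with known residue
# shifts, homolog families diverged by point substitution along a known
# tree, and global-null panels for FDR-control simulation. All generators
# are pure functions of their arguments plus the seed.

#' Default per-group residue shifts for thermal panels
#'
#' Percentage-point offsets applied to the baseline residue frequencies:
#' the cold group gains glycine and loses glutamic acid and tyrosine
#' (Gly +4, Glu -2, Tyr -1.5), the thermophilic group is mirrored, and the
#' mesophilic group sits at the baseline.
#'
#' @return Named list of named numeric shift vectors.
#' @export
default_thermal_shifts <- function() {
  list(cold = c(G = 4, E = -2, Y = -1.5),
       mesophilic = c(),
       thermophilic = c(G = -4, E = 2, Y = 1.5))
}

.shift_simplex <- function(baseline, shift) {
  f <- baseline
  if (length(shift)) {
    if (!all(names(shift) %in% AA20)) stop("shift names must be residues")
    f[names(shift)] <- f[names(shift)] + shift / 100
  }
  if (any(f <= 0))
    stop("shift drives residue frequency(ies) non-positive: ",
         paste(names(f)[f <= 0], collapse = ", "))
  f / sum(f)
}

.random_protein <- function(len, freqs) {
  paste(sample(AA20, len, replace = TRUE, prob = freqs), collapse = "")
}

#' Generate labelled thermal composition panels
#'
#' One panel of residue-wise i.i.d. protein sequences per group, drawn
#' from the baseline frequencies plus the group's shifts. Defaults are the
#' package's study conditions: uniform 5% baseline, the shifts of
#' [default_thermal_shifts()], 20 proteins per group of 200-400 residues.
#'
#' @param n_per_group Proteins per group.
#' @param length_range Inclusive residue-count interval.
#' @param baseline Named 20-simplex of residue frequencies (default
#'   uniform).
#' @param shifts Named list of per-group shifts in percentage points.
#' @param seed Integer seed; same seed, same panels.
#' @return Named list of [protein_set()]s, one per group.
#' @export
#' @examples
#' panels <- generate_thermal_panels(n_per_group = 5, seed = 1)
#' sapply(panels, nrow)
generate_thermal_panels <- function(n_per_group = 20,
                                    length_range = c(200, 400),
                                    baseline = NULL,
                                    shifts = default_thermal_shifts(),
                                    seed = 1) {
  if (is.null(baseline)) baseline <- setNames(rep(1 / 20, 20), AA20)
  stopifnot(abs(sum(baseline) - 1) < 1e-9, all(baseline > 0),
            n_per_group >= 1, length_range[1] >= 1,
            length_range[2] >= length_range[1])
  freqs <- lapply(shifts, .shift_simplex, baseline = baseline)
  withr::with_seed(seed, {
    out <- lapply(names(freqs), function(g) {
      lens <- length_range[1] - 1L +
        sample.int(length_range[2] - length_range[1] + 1L, n_per_group,
                   replace = TRUE)
      protein_set(sprintf("%s_%02d", g, seq_len(n_per_group)),
                  vapply(lens, .random_protein, character(1),
                         freqs = freqs[[g]]),
                  source = "generate_thermal_panels")
    })
  })
  setNames(out, names(freqs))
}

# One Poisson-number-of-events point-substitution pass over a residue
# vector; each event replaces the residue with a uniformly chosen
# different one.
.mutate_chain <- function(chars, branch_length) {
  nev <- rpois(length(chars), branch_length)
  for (i in which(nev > 0)) {
    for (k in seq_len(nev[i]))
      chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  chars
}

#' Evolve a protein family along a known tree
#'
#' A uniform-random root sequence is mutated independently along each
#' branch; branch lengths are expected substitutions per site and each
#' substitution event replaces the residue with a uniformly random
#' different one (multiple hits therefore saturate).
#'
#' @param tree An `ape::phylo` tree with branch lengths (rooted or
#'   unrooted; traversal starts at the root node).
#' @param root_length Root sequence length in residues (>= 10).
#' @param seed Integer seed.
#' @return List: `records` (tip [protein_set()]), `tree` (the generating
#'   tree), `root_sequence`.
#' @export
evolve_family <- function(tree, root_length = 300, seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length),
            root_length >= 10)
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  withr::with_seed(seed, {
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- sample(AA20, root_length, replace = TRUE)
    # preorder over edges: parents always precede children in ape's
    # cladewise edge ordering from the root
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      seqs[[child]] <- .mutate_chain(seqs[[par]], ord$edge.length[e])
    }
    records <- protein_set(tree$tip.label,
                           vapply(seqs[seq_len(ntip)], paste,
                                  character(1), collapse = ""),
                           source = "evolve_family")
  })
  list(records = records, tree = tree,
       root_sequence = paste(seqs[[root]], collapse = ""))
}

#' Generate a global-null composition panel
#'
#' All groups are drawn from one common sequence distribution (uniform
#' residue frequencies), so any rejection by the group-comparison
#' procedure is a false discovery.
#'
#' @param n Proteins per group.
#' @param groups Group labels.
#' @param length Sequence length per protein.
#' @param seed Integer seed.
#' @return Named list of composition matrices (n x 20, percent).
#' @export
generate_null_panel <- function(n = 10,
                                groups = c("cold", "mesophilic",
                                           "thermophilic"),
                                length = 150, seed = 1) {
  stopifnot(n >= 2, length >= 20)
  freqs <- setNames(rep(1 / 20, 20), AA20)
  withr::with_seed(seed, {
    out <- lapply(groups, function(g) {
      ps <- protein_set(sprintf("%s_%02d", g, seq_len(n)),
                        vapply(rep(length, n), .random_protein,
                               character(1), freqs = freqs))
      composition_matrix(ps)
    })
  })
  setNames(out, groups)
}
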