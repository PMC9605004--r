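# Whole-protein amino-acid composition and predicted molecular mass.

# Average (isotope-weighted) residue masses in Da; water added per chain.
RESIDUE_MASS_DA <- c(
  A = 71.0788,  C = 103.1388, D = 115.0886, E = 129.1155, F = 147.1766,
  G = 57.0519,  H = 137.1411, I = 113.1594, K = 128.1741, L = 113.1594,
  M = 131.1926, N = 114.1038, P = 97.1167,  Q = 128.1307, R = 156.1875,
  S = 87.0782,  T = 101.1051, V = 99.1326,  W = 186.2132, Y = 163.1760)
WATER_DA <- 18.0153

.residue_counts <- function(sequence) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  tab <- table(factor(ch, levels = AA20))
  setNames(as.integer(tab), AA20)
}

#' Amino-acid composition of one protein
#'
#' Percentage of each of the 20 standard residues in the sequence. Unknown
#' residues (`X`) are excluded from both numerator and denominator, so the
#' 20 percentages always sum to 100.
#'
#' @param sequence Residue string, or a single-row [protein_set()].
#' @param id Identifier attached to the result (taken from the record when
#'   a `protein_set` row is supplied).
#' @return Named numeric vector of 20 percentages, class
#'   `composition_vector`, with attributes `protein_id` and `length_used`.
#' @export
#' @examples
#' aa_composition("GAGA")  # Gly 50, Ala 50
aa_composition <- function(sequence, id = NA_character_) {
  if (inherits(sequence, "protein_set")) {
    stopifnot(nrow(sequence) == 1)
    id <- sequence$id
    sequence <- sequence$sequence
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  cnt <- .residue_counts(sequence)
  used <- sum(cnt)
  if (used == 0) stop("no usable residues (sequence is all X) in '", id, "'")
  out <- 100 * cnt / used
  structure(out, protein_id = id, length_used = used,
            class = "composition_vector")
}

#' Composition matrix for a protein set
#'
#' @param x A [protein_set()].
#' @return Numeric matrix, one row per protein (rownames = ids), 20 residue
#'   columns in canonical order, entries in percent.
#' @export
composition_matrix <- function(x) {
  stopifnot(inherits(x, "protein_set"))
  m <- t(vapply(seq_len(nrow(x)),
                function(i) as.numeric(aa_composition(x$sequence[i], x$id[i])),
                numeric(20)))
  dimnames(m) <- list(x$id, AA20)
  m
}

#' Predicted molecular mass of a protein
#'
#' Sum of average residue masses plus one water, in kilodaltons — the
#' "predicted mass" scale used to annotate enzyme gels (~kDa). The full
#' provided chain is used; pre-trim signal peptides yourself if you want
#' mature-chain masses.
#'
#' @param sequence Residue string without `X`, or a single-row
#'   [protein_set()].
#' @return Mass in kDa.
#' @export
#' @examples
#' molecular_mass("GG")  # 0.1321 kDa
molecular_mass <- function(sequence) {
  if (inherits(sequence, "protein_set")) {
    stopifnot(nrow(sequence) == 1)
    sequence <- sequence$sequence
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("X", sequence, fixed = TRUE))
    stop("sequence contains X; resolve or remove unknown residues ",
         "before computing a mass")
  cnt <- .residue_counts(sequence)
  if (sum(cnt) != nchar(sequence)) stop("illegal residue character in sequence")
  (sum(cnt * RESIDUE_MASS_DA[AA20]) + WATER_DA) / 1000
}

#' Per-group composition summary
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of each
#' residue percentage across the proteins of one labelled group.
#'
#' @param comps Composition matrix from [composition_matrix()] (rows =
#'   proteins), or a list of `composition_vector`s.
#' @param label Group label, e.g. `"cold"`.
#' @return List of class `group_summary`: `group_label`, `mean_percent`,
#'   `sd_percent` (20-vectors), `n`.
#' @export
summarize_group <- function(comps, label) {
  if (is.list(comps) && !is.data.frame(comps))
    comps <- do.call(rbind, lapply(comps, as.numeric))
  comps <- as.matrix(comps)
  if (nrow(comps) < 2) stop("need at least 2 proteins to summarize a group")
  if (ncol(comps) != 20) stop("composition matrix must have 20 columns")
  colnames(comps) <- AA20
  structure(list(group_label = label,
                 mean_percent = colMeans(comps),
                 sd_percent = apply(comps, 2, sd),
                 n = nrow(comps)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group_summary '", x$group_label, "' (n = ", x$n, ")\n", sep = "")
  print(round(rbind(mean = x$mean_percent, sd = x$sd_percent), 2))
  invisible(x)
}

#' Composition and mass table for export
#'
#' One row per protein: id, the 20 composition percentages, residue count
#' used, and predicted mass in kDa (NA when the sequence contains `X`).
#'
#' @param x A [protein_set()].
#' @param path Optional TSV output path.
#' @return Data frame (invisibly written to `path` when given).
#' @export
composition_table <- function(x, path = NULL) {
  m <- composition_matrix(x)
  mass <- vapply(x$sequence, function(s) {
    if (grepl("X", s, fixed = TRUE)) NA_real_ else molecular_mass(s)
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(id = x$id, m,
                    length_used = vapply(x$sequence, function(s)
                      sum(.residue_counts(s)), integer(1), USE.NAMES = FALSE),
                    mass_kda = mass,
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
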