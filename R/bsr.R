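# Blast-score-ratio (BSR) homologue mapping: each query enzyme is aligned
# against every protein of each reference proteome; the best bit score is
# normalized by the query's self-alignment bit score. 1 = identical match
# present, 0 = no match; calls use a strict "> threshold" rule
# (conventionally 0.4).

#' Self-alignment bit score of a protein
#'
#' Bit score of the query aligned to itself — the BSR denominator. For any
#' standard positive-diagonal matrix this is the sum of diagonal scores.
#'
#' @param query Protein string or single-row [protein_set()].
#' @param params [alignment_params()].
#' @return Bit score (> 0).
#' @export
self_bits <- function(query, params = alignment_params()) {
  if (inherits(query, "protein_set")) query <- query$sequence[1]
  smith_waterman(query, query, params, traceback = FALSE)$bit_score
}

#' Blast score ratio of one query against one proteome
#'
#' Maximum over the proteome of `bits(query, ref) / self_bits(query)`,
#' clamped to `[0, 1]`. Hits below `params$bit_floor` bits count as "no
#' match" and yield 0. A pre-clamp ratio above 1 (a reference out-scoring
#' the query's self-alignment) is recorded as a dominance anomaly via a
#' warning.
#'
#' @param query Protein string or single-row [protein_set()].
#' @param proteome A non-empty [protein_set()] of reference proteins.
#' @param params [alignment_params()].
#' @return List: `ratio` in `[0, 1]`, `best_hit_id` (NA when no match).
#' @export
bsr <- function(query, proteome, params = alignment_params()) {
  stopifnot(inherits(proteome, "protein_set"))
  if (!nrow(proteome)) stop("empty proteome")
  qseq <- if (inherits(query, "protein_set")) query$sequence[1] else query
  denom <- self_bits(qseq, params)
  bits <- vapply(proteome$sequence, function(ref)
    smith_waterman(qseq, ref, params, traceback = FALSE)$bit_score,
    numeric(1), USE.NAMES = FALSE)
  best <- which.max(bits)
  if (bits[best] < params$bit_floor)
    return(list(ratio = 0, best_hit_id = NA_character_))
  ratio <- bits[best] / denom
  if (ratio > 1 + 1e-12)
    warning("matrix-dominance anomaly: reference '", proteome$id[best],
            "' out-scores the query self-alignment (ratio ",
            format(ratio), "); clamped to 1")
  list(ratio = min(ratio, 1), best_hit_id = proteome$id[best])
}

#' Build a BSR matrix of queries against reference proteomes
#'
#' @param queries A [protein_set()] of query enzymes.
#' @param proteomes Named list of [protein_set()]s, one per reference
#'   proteome (names become proteome ids), or a directory of FASTA files
#'   (file stems become proteome ids).
#' @param params [alignment_params()].
#' @param threshold Homologue call cutoff; calls are strict
#'   `value > threshold` (default 0.4).
#' @return Object of class `bsr_matrix`: `values` and `best_hit` matrices
#'   (queries x proteomes), logical `calls`, `threshold`.
#' @export
build_bsr_matrix <- function(queries, proteomes, params = alignment_params(),
                             threshold = 0.4) {
  stopifnot(inherits(queries, "protein_set"), nrow(queries) > 0)
  if (is.character(proteomes) && length(proteomes) == 1 &&
      dir.exists(proteomes)) {
    files <- list.files(proteomes, pattern = "\\.(fa|faa|fasta)$",
                        full.names = TRUE)
    if (!length(files)) stop("no FASTA files in ", proteomes)
    proteomes <- setNames(lapply(files, read_fasta),
                          sub("\\.[^.]*$", "", basename(files)))
  }
  if (is.null(names(proteomes)) || any(!nzchar(names(proteomes))))
    stop("proteomes must be named")
  if (anyDuplicated(names(proteomes)))
    stop("duplicate proteome id(s): ",
         paste(unique(names(proteomes)[duplicated(names(proteomes))]),
               collapse = ", "))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  nq <- nrow(queries); np <- length(proteomes)
  values <- matrix(NA_real_, nq, np,
                   dimnames = list(queries$id, names(proteomes)))
  hits <- matrix(NA_character_, nq, np, dimnames = dimnames(values))
  for (i in seq_len(nq)) {
    for (j in seq_len(np)) {
      r <- bsr(queries$sequence[i], proteomes[[j]], params)
      values[i, j] <- r$ratio
      hits[i, j] <- r$best_hit_id
    }
  }
  structure(list(values = values, best_hit = hits,
                 calls = homologue_calls(values, threshold),
                 threshold = threshold,
                 query_ids = queries$id, proteome_ids = names(proteomes)),
            class = "bsr_matrix")
}

#' Homologue calls from BSR values
#'
#' Strict rule: a homologue is called only when the ratio is strictly
#' greater than the threshold; a value exactly at the threshold is not
#' called.
#'
#' @param values Numeric BSR values (any shape).
#' @param threshold Cutoff in (0, 1), default 0.4.
#' @return Logical calls with the shape of `values`.
#' @export
homologue_calls <- function(values, threshold = 0.4) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  values > threshold
}

#' @export
print.bsr_matrix <- function(x, ...) {
  cat("bsr_matrix:", length(x$query_ids), "queries x",
      length(x$proteome_ids), "proteomes; threshold >", x$threshold, "\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Long-format export of a BSR matrix
#'
#' One row per query-by-proteome cell, ready for heatmap plotting.
#' Row order is fixed (queries varying slowest) so repeated exports are
#' byte-identical.
#'
#' @param x A `bsr_matrix`.
#' @param path Optional TSV output path.
#' @return Data frame: `query`, `proteome`, `ratio`, `best_hit`, `call`.
#' @export
export_heatmap_table <- function(x, path = NULL) {
  stopifnot(inherits(x, "bsr_matrix"))
  out <- data.frame(
    query = rep(x$query_ids, each = length(x$proteome_ids)),
    proteome = rep(x$proteome_ids, times = length(x$query_ids)),
    ratio = as.vector(t(x$values)),
    best_hit = as.vector(t(x$best_hit)),
    call = as.vector(t(x$calls)),
    stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
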