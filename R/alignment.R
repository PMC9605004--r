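# Exact Smith-Waterman local alignment and Karlin-Altschul bit scores —
# the score engine under the Blast-score-ratio statistic. Full dynamic
# programming, no heuristic seeding: proteome sets at desk scale do not
# need BLAST's word heuristics and exactness keeps the enumeration oracle
# meaningful.

.default_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA20, AA20]
    }
    cache
  }
})

#' Alignment scoring parameters
#'
#' Substitution matrix, affine gap penalties and Karlin-Altschul constants.
#' Defaults mirror gapped blastp: BLOSUM62, gap open 11, gap extend 1,
#' lambda = 0.267, K = 0.041. The unknown residue `X` scores 0 against
#' everything. A length-1 gap costs `gap_open + gap_extend`.
#'
#' @param matrix Symmetric integer substitution matrix with residue
#'   dimnames covering the 20 standard codes (default: BLOSUM62 shipped
#'   with Biostrings).
#' @param gap_open,gap_extend Positive integer gap penalties.
#' @param lambda,k_const Karlin-Altschul scale and K for the gapped
#'   scoring system.
#' @param bit_floor Bit-score floor below which a hit counts as "no match"
#'   in BSR computations (default 1 bit).
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                             lambda = 0.267, k_const = 0.041, bit_floor = 1) {
  if (is.null(matrix)) matrix <- .default_blosum62()
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)) || !all(AA20 %in% rownames(matrix)))
    stop("substitution matrix must have the 20 residue codes as dimnames")
  matrix <- matrix[intersect(rownames(matrix), c(AA20, "X")),
                   intersect(colnames(matrix), c(AA20, "X")), drop = FALSE]
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open >= gap_extend && gap_extend >= 1))
    stop("need gap_open >= gap_extend >= 1")
  stopifnot(lambda > 0, k_const > 0, k_const < 1)
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda,
                 k_const = k_const, bit_floor = bit_floor),
            class = "alignment_params")
}

# 21 x 21 integer lookup over AA20 + X, with X scoring 0 vs everything.
.score_lookup <- function(params) {
  full <- matrix(0L, 21, 21, dimnames = list(c(AA20, "X"), c(AA20, "X")))
  full[AA20, AA20] <- as.integer(params$matrix[AA20, AA20])
  full
}

.encode_seq <- function(sequence) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  idx <- match(ch, c(AA20, "X"))
  if (anyNA(idx))
    stop("illegal residue character '", ch[is.na(idx)][1], "' in sequence")
  idx
}

#' Optimal Smith-Waterman local alignment
#'
#' Exact affine-gap local alignment of two protein sequences. The raw
#' score is 0 when no positive-scoring local alignment exists.
#'
#' @param a,b Protein strings over the 20-letter alphabet (plus `X`), or
#'   single-row [protein_set()]s.
#' @param params [alignment_params()].
#' @param traceback Logical; also reconstruct the aligned strings and
#'   1-based spans (slower, keeps full DP matrices).
#' @return List of class `local_alignment`: `raw_score`, `bit_score`, and
#'   with `traceback = TRUE` also `aligned_query`, `aligned_ref`,
#'   `query_span`, `ref_span` (1-based inclusive, NA when raw score is 0).
#' @export
#' @examples
#' smith_waterman("MKWVL", "MKWIL")$raw_score
smith_waterman <- function(a, b, params = alignment_params(),
                           traceback = TRUE) {
  if (inherits(a, "protein_set")) a <- a$sequence[1]
  if (inherits(b, "protein_set")) b <- b$sequence[1]
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  S <- .score_lookup(params)
  ai <- .encode_seq(a); bi <- .encode_seq(b)
  if (!traceback) {
    raw <- sw_score_cpp(ai, bi, S, params$gap_open, params$gap_extend)
    return(structure(list(raw_score = raw,
                          bit_score = to_bits(raw, params)),
                     class = "local_alignment"))
  }
  res <- sw_align_cpp(ai, bi, S, params$gap_open, params$gap_extend)
  alpha <- c(AA20, "X")
  decode <- function(path) paste(ifelse(path == 0, "-", alpha[path]),
                                 collapse = "")
  structure(list(raw_score = res$score,
                 bit_score = to_bits(res$score, params),
                 aligned_query = decode(res$path_a),
                 aligned_ref = decode(res$path_b),
                 query_span = c(res$a_start, res$a_end),
                 ref_span = c(res$b_start, res$b_end)),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat("local_alignment: raw", x$raw_score, "=",
      round(x$bit_score, 2), "bits\n")
  if (!is.null(x$aligned_query)) {
    cat(" query", x$query_span[1], x$aligned_query, x$query_span[2], "\n")
    cat(" ref  ", x$ref_span[1], x$aligned_ref, x$ref_span[2], "\n")
  }
  invisible(x)
}

#' Convert a raw alignment score to bits
#'
#' S' = (lambda * S - ln K) / ln 2 for positive raw scores, floored at 0.
#' A raw score of 0 means no positive-scoring local alignment exists and
#' reports 0 bits.
#'
#' @param raw_score Non-negative integer raw score(s).
#' @param params [alignment_params()] supplying lambda and K.
#' @return Bit score(s), >= 0.
#' @export
#' @examples
#' to_bits(100)  # 43.13 with the gapped BLOSUM62 constants
to_bits <- function(raw_score, params = alignment_params()) {
  bits <- (params$lambda * raw_score - log(params$k_const)) / log(2)
  ifelse(raw_score <= 0, 0, pmax(bits, 0))
}

#' Read an NCBI-format substitution matrix file
#'
#' Plain-text matrices as distributed by NCBI: `#` comment lines, a header
#' row of column letters, then one row per residue.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, character(1), 1)
  vals <- t(vapply(body, function(x) as.integer(x[-1]),
                   integer(length(cols))))
  dimnames(vals) <- list(rows, cols)
  vals
}
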