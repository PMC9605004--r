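# Sequence data model and FASTA / translation plumbing shared by all stages.

#' Construct a set of protein records
#'
#' A `protein_set` is the package's basic container: a data frame with one
#' row per protein and columns `id`, `description`, `sequence`, `source`.
#' Sequences are upper-case strings over the 20 standard one-letter residue
#' codes, optionally containing `X` for unknown residues (and `-` when the
#' set represents aligned, gapped sequences).
#'
#' @param id Character vector of unique identifiers.
#' @param sequence Character vector of residue strings (same length as `id`).
#' @param description Free-text descriptions (recycled).
#' @param source Free-text provenance tags, e.g. a file name (recycled).
#' @param gapped Logical; allow the gap character `-` (used for alignments).
#' @return A data frame of class `protein_set`.
#' @export
#' @examples
#' protein_set(c("p1", "p2"), c("MKLV", "MKIV"))
protein_set <- function(id, sequence, description = "", source = "",
                        gapped = FALSE) {
  stopifnot(length(id) == length(sequence))
  x <- data.frame(id = as.character(id),
                  description = rep_len(as.character(description), length(id)),
                  sequence = toupper(as.character(sequence)),
                  source = rep_len(as.character(source), length(id)),
                  stringsAsFactors = FALSE)
  class(x) <- c("protein_set", "data.frame")
  validate_protein_set(x, gapped = gapped)
  x
}

validate_protein_set <- function(x, gapped = FALSE) {
  if (anyDuplicated(x$id))
    stop("duplicate sequence id(s): ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "))
  if (nrow(x) && any(!nzchar(x$sequence)))
    stop("empty sequence for id(s): ",
         paste(x$id[!nzchar(x$sequence)], collapse = ", "))
  pat <- if (gapped) "^[ACDEFGHIKLMNPQRSTVWYX-]*$" else "^[ACDEFGHIKLMNPQRSTVWYX]*$"
  bad <- !grepl(pat, x$sequence)
  if (any(bad)) {
    ch <- gsub(if (gapped) "[ACDEFGHIKLMNPQRSTVWYX-]" else "[ACDEFGHIKLMNPQRSTVWYX]",
               "", x$sequence[bad][1])
    stop("illegal residue character(s) '", substr(ch, 1, 5), "' in record '",
         x$id[bad][1], "'")
  }
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased, a single terminal stop symbol `*` is stripped,
#' and records are validated against the 20-letter alphabet plus `X`.
#' Errors name the offending record and the line of the file on which it
#' starts. Any line wrapping is accepted.
#'
#' @param path Path to a FASTA file.
#' @param gapped Logical; accept the gap character `-` (see
#'   [read_aligned_fasta()] for validated alignments).
#' @return A [protein_set()] in file order (zero rows for an empty file).
#' @export
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">a enzyme", "MKLV"), f)
#' read_fasta(f)
read_fasta <- function(path, gapped = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e)))
  if (!length(set))
    return(protein_set(character(), character(), source = character()))
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)  # terminal stop from translated CDS
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])[1]
    stop("duplicate id '", dup, "' at line ", .fasta_header_line(path, dup, 2L))
  }
  pat <- if (gapped) "^[ACDEFGHIKLMNPQRSTVWYX-]+$" else "^[ACDEFGHIKLMNPQRSTVWYX]+$"
  bad <- which(!grepl(pat, seqs))
  if (length(bad)) {
    stop("illegal residue character in record '", id[bad[1]],
         "' (starts at line ", .fasta_header_line(path, id[bad[1]], 1L), ")")
  }
  if (any(!nzchar(seqs)))
    stop("empty sequence in record '", id[!nzchar(seqs)][1], "'")
  x <- data.frame(id = id, description = desc, sequence = seqs,
                  source = basename(path), stringsAsFactors = FALSE)
  class(x) <- c("protein_set", "data.frame")
  x
}

# Line number of the n-th header whose first token is `id`.
.fasta_header_line <- function(path, id, n = 1L) {
  lines <- readLines(path, warn = FALSE)
  hits <- which(grepl("^>", lines) &
                  sub("\\s.*$", "", sub("^>", "", lines)) == id)
  if (length(hits) >= n) hits[n] else NA_integer_
}

#' Write a protein set to FASTA
#'
#' Sequences are wrapped at 60 columns. `read_fasta(write_fasta(x, p))`
#' reproduces ids, descriptions and sequences exactly.
#'
#' @param x A [protein_set()].
#' @param path Output path.
#' @param width Wrap width in columns (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(inherits(x, "protein_set"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    hdr <- if (nzchar(x$description[i]))
      paste(x$id[i], x$description[i]) else x$id[i]
    writeLines(paste0(">", hdr), con)
    s <- x$sequence[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a coding sequence to protein
#'
#' Standard genetic code. Codons containing `N` translate to `X`. Stop
#' codons become `*`, or truncate the translation when
#' `to_first_stop = TRUE`.
#'
#' @param dna Nucleotide string over `A,C,G,T,N`; length divisible by 3.
#' @param to_first_stop Logical; stop translating at the first stop codon.
#' @return Protein string.
#' @export
#' @examples
#' translate_cds("ATGGGTGGATAA", to_first_stop = TRUE)  # "MGG"
translate_cds <- function(dna, to_first_stop = FALSE) {
  dna <- toupper(dna)
  if (!nzchar(dna)) stop("empty coding sequence")
  if (!grepl("^[ACGTN]+$", dna)) stop("coding sequence must be over A,C,G,T,N")
  if (nchar(dna) %% 3 != 0)
    stop("coding sequence length (", nchar(dna), ") not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                           if.fuzzy.codon = "X",
                                           no.init.codon = TRUE))
  if (to_first_stop) sub("\\*.*$", "", aa) else aa
}

#' Read a pre-aligned protein FASTA into an aligned block
#'
#' All sequences (gaps included) must share one length; the gap character
#' is `-` only. Each record must contain at least one non-gap residue.
#'
#' @param path Path to an aligned FASTA file.
#' @return An object of class `aligned_block`: list with `records`
#'   (a gapped [protein_set()]) and `length` (number of columns).
#' @export
read_aligned_fasta <- function(path) {
  x <- read_fasta(path, gapped = TRUE)
  aligned_block(x)
}

#' Construct an aligned block from gapped records
#'
#' @param records A [protein_set()] whose sequences may contain `-`.
#' @return An `aligned_block`.
#' @export
aligned_block <- function(records) {
  stopifnot(inherits(records, "protein_set"))
  if (nrow(records) < 2) stop("an alignment needs at least 2 records")
  validate_protein_set(records, gapped = TRUE)
  len <- nchar(records$sequence)
  if (length(unique(len)) != 1) {
    off <- records$id[len != len[1]][1]
    stop("unequal alignment lengths: record '", off, "' has ",
         nchar(records$sequence[records$id == off]), " columns, '",
         records$id[1], "' has ", len[1])
  }
  allgap <- !grepl("[ACDEFGHIKLMNPQRSTVWYX]", records$sequence)
  if (any(allgap))
    stop("record '", records$id[allgap][1], "' is all gaps")
  structure(list(records = records, length = len[1]), class = "aligned_block")
}

#' @export
print.aligned_block <- function(x, ...) {
  cat("aligned_block:", nrow(x$records), "taxa x", x$length, "columns\n")
  invisible(x)
}

# Character matrix view (taxa x sites) used by distance computations.
as_char_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$records$sequence, "", fixed = TRUE))
  rownames(m) <- block$records$id
  m
}
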