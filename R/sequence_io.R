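# Sequence containers are plain named character vectors: names are record
# ids (FASTA header up to first whitespace), values are uppercase residue
# strings over {A,C,G,T,N}.

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

# IUPAC degenerate nucleotide codes mapped to the residue letters each one
# accepts. A residue N is deliberately a member of pattern N only: an
# unknown genome base must never satisfy a literal pattern letter.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

# 15 x 5 logical lookup: .IUPAC_TABLE[pattern_char, residue_char]
.IUPAC_TABLE <- local({
  m <- matrix(FALSE, nrow = length(.IUPAC_SETS), ncol = length(.DNA_ALPHABET),
              dimnames = list(names(.IUPAC_SETS), .DNA_ALPHABET))
  for (p in names(.IUPAC_SETS)) m[p, .IUPAC_SETS[[p]]] <- TRUE
  m
})

#' Read a FASTA file of DNA sequences
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file, truncates each
#' header at the first whitespace to obtain the record id, uppercases
#' soft-masked lowercase residues, and validates that every residue is one
#' of A, C, G, T, N.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are record ids, values uppercase
#'   residue strings.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 some description", "acgtACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read FASTA: file not found: ", path)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA format error: no records in ", path)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop("FASTA format error: empty record id in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("FASTA format error: duplicate record id '",
         ids[duplicated(ids)][1L], "' in ", path)
  }
  residues <- toupper(as.character(set))
  bad <- regexpr("[^ACGTN]", residues)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop("FASTA format error: illegal residue '",
         substr(residues[i], bad[i], bad[i]),
         "' in record '", ids[i], "' at position ", bad[i])
  }
  if (any(!nzchar(residues))) {
    stop("FASTA format error: empty sequence in record '",
         ids[which(!nzchar(residues))[1L]], "'")
  }
  stats::setNames(residues, ids)
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(c(paste0(">", names(seqs)[i]),
                 substring(s, starts, pmin(starts + width - 1L, nchar(s)))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' Standard Watson-Crick complement, reversed; N maps to N. Vectorised over
#' strings. `reverse_complement(reverse_complement(x)) == x`.
#'
#' @param s Character vector of residue strings over A,C,G,T,N.
#' @return Character vector of reverse-complemented strings.
#' @export
reverse_complement <- function(s) {
  if (length(s) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", s))) {
    stop("reverse_complement: illegal character (expected A,C,G,T,N)")
  }
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(x) {
    if (!nzchar(x)) return(x)
    intToUtf8(rev(utf8ToInt(x)))
  }, character(1), USE.NAMES = FALSE)
}

#' Match an IUPAC pattern against a residue string
#'
#' Position-wise membership test: `pattern[i]` is one of the 15 IUPAC
#' nucleotide codes and accepts `s[i]` iff `s[i]` belongs to its base set.
#' A residue N matches pattern N only; it never satisfies any literal or
#' partial-degeneracy code. Both strings must have equal length.
#'
#' @param pattern IUPAC pattern string.
#' @param s Residue string over A,C,G,T,N.
#' @return `TRUE` iff every position matches.
#' @export
#' @examples
#' iupac_matches("NGG", "TGG")   # TRUE
#' iupac_matches("GGG", "TGG")   # FALSE
iupac_matches <- function(pattern, s) {
  if (nchar(pattern) != nchar(s)) {
    stop("iupac_matches: pattern and subject lengths differ (",
         nchar(pattern), " vs ", nchar(s), ")")
  }
  if (nchar(pattern) == 0L) return(TRUE)
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (any(!pc %in% rownames(.IUPAC_TABLE))) {
    stop("iupac_matches: invalid IUPAC code in pattern '", pattern, "'")
  }
  if (any(!sc %in% .DNA_ALPHABET)) {
    stop("iupac_matches: invalid residue in subject '", s, "'")
  }
  all(.IUPAC_TABLE[cbind(pc, sc)])
}

# Translate an IUPAC pattern into a regular-expression character-class
# string preserving the N-matches-only-pattern-N rule (pattern N expands to
# [ACGTN]; every other code to a class without N).
.iupac_to_regex <- function(pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (any(!pc %in% rownames(.IUPAC_TABLE))) {
    stop("invalid IUPAC code in pattern '", pattern, "'")
  }
  paste(vapply(pc, function(p) {
    set <- .IUPAC_SETS[[p]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1)), collapse = "")
}

.is_valid_iupac <- function(x) {
  nzchar(x) & !grepl("[^ACGTRYSWKMBDHVN]", x)
}
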