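# Independent naive oracles and small generators shared by the test files.
# These deliberately re-derive everything by exhaustive per-position loops
# and share no matching machinery with the package internals.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exhaustive both-strand window enumeration (candidate oracle)
naive_enumerate <- function(residues, id, config) {
  pam2 <- if (config$pam == "NGG") "GG" else "AG"
  L <- nchar(residues)
  out <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") residues else reverse_complement(residues)
    for (st in seq_len(max(L - 22L, 0L))) {
      w <- substr(s, st, st + 22L)
      if (grepl("N", w, fixed = TRUE)) next
      if (substr(w, 22L, 23L) != pam2) next
      if (config$start == "G" && substr(w, 1L, 1L) != "G") next
      fs <- if (strand == "+") st else L - st - 21L
      out <- rbind(out, data.frame(
        query_id = id, start = fs, stop = fs + 22L, strand = strand,
        protospacer = substr(w, 1L, 20L), pam = substr(w, 21L, 23L),
        site23 = w, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    return(data.frame(query_id = character(0), start = integer(0),
                      stop = integer(0), strand = character(0),
                      protospacer = character(0), pam = character(0),
                      site23 = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive PAM-site count over both strands (index oracle)
naive_site_count <- function(genome, config) {
  pam2 <- if (config$pam == "NGG") "GG" else "AG"
  cnt <- 0L
  for (cg in genome) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") cg else reverse_complement(cg)
      for (st in seq_len(max(nchar(s) - 22L, 0L))) {
        w <- substr(s, st, st + 22L)
        if (!grepl("N", w, fixed = TRUE) && substr(w, 22L, 23L) == pam2) {
          cnt <- cnt + 1L
        }
      }
    }
  }
  cnt
}

# per-position, per-strand IUPAC scan (restriction oracle); its own local
# degeneracy table, spelled out
NAIVE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

naive_pattern_at <- function(pat_chars, sub_chars, offset) {
  for (j in seq_along(pat_chars)) {
    if (!sub_chars[offset + j - 1L] %in% NAIVE_IUPAC[[pat_chars[j]]]) {
      return(FALSE)
    }
  }
  TRUE
}

naive_find_sites <- function(site23, enzymes) {
  fwd <- strsplit(site23, "", fixed = TRUE)[[1L]]
  rev <- strsplit(reverse_complement(site23), "", fixed = TRUE)[[1L]]
  out <- NULL
  for (i in seq_len(nrow(enzymes))) {
    pat <- strsplit(enzymes$site[i], "", fixed = TRUE)[[1L]]
    m <- length(pat)
    if (m > 23L) next
    for (st in seq_len(23L - m + 1L)) {
      if (naive_pattern_at(pat, fwd, st)) {
        out <- rbind(out, data.frame(
          enzyme_name = enzymes$name[i], start = st, end = st + m - 1L,
          strand = "+", stringsAsFactors = FALSE))
      }
      if (naive_pattern_at(pat, rev, st)) {
        end <- 23L - st + 1L
        out <- rbind(out, data.frame(
          enzyme_name = enzymes$name[i], start = end - m + 1L, end = end,
          strand = "-", stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(enzyme_name = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      overlaps_cleavage = logical(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(out$enzyme_name, out$start, out$end)
  out <- out[!(out$strand == "-" & key %in% key[out$strand == "+"]), ,
             drop = FALSE]
  out$overlaps_cleavage <- (out$start <= 17L & out$end >= 18L) |
    (out$start <= 16L & out$end >= 17L)
  out <- out[order(out$start, out$enzyme_name, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pick a candidate-shaped row from a bare 23-mer
as_candidate <- function(site23, id = "cand") {
  data.frame(query_id = id, start = 1L, stop = 23L, strand = "+",
             protospacer = substr(site23, 1L, 20L),
             pam = substr(site23, 21L, 23L), site23 = site23,
             stringsAsFactors = FALSE)
}

write_temp_fasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  path
}
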