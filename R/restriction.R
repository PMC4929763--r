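# Restriction-site annotation of candidate 23-mers.
#
# Cas9 cuts both strands bluntly ~3-4 bases upstream of the PAM. In 23-mer
# coordinates (protospacer 1-20, PAM 21-23) the two candidate cut
# boundaries are between positions 17|18 (3 bp upstream) and 16|17 (4 bp
# upstream). A recognition site whose match covers both flanking bases of
# either boundary is destroyed by an indel at the cut, so a wild-type
# amplicon digests where a mutant does not — the basis of RFLP mutant
# screening.

#' Cleavage-overlap predicate
#'
#' `TRUE` iff a match interval `[start, end]` (1-based, inclusive, within
#' the 23-mer) covers both flanking bases of the 17|18 or the 16|17 cut
#' boundary.
#'
#' @param start,end Integer vectors of match interval endpoints.
#' @return Logical vector.
#' @export
cleavage_overlaps <- function(start, end) {
  (start <= 17L & end >= 18L) | (start <= 16L & end >= 17L)
}

#' Load a restriction-enzyme table
#'
#' Reads a two-column CSV (`name,site`) of enzyme names and IUPAC
#' recognition sites. Lines starting with `#` and blank lines are skipped.
#' When `path` is `NULL` the built-in default table of common commercial
#' 6-cutters is returned (see [default_enzymes()]).
#'
#' @param path CSV path, or `NULL` for the default table.
#' @return Data frame with columns `name` and `site`.
#' @export
load_enzymes <- function(path = NULL) {
  if (is.null(path)) return(default_enzymes())
  if (!file.exists(path)) stop("enzyme table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0L) stop("no enzymes loaded from ", path)
  name <- character(length(keep)); site <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- trimws(strsplit(lines[ln], ",", fixed = TRUE)[[1L]])
    if (length(fields) != 2L || any(!nzchar(fields))) {
      stop("malformed enzyme row at line ", ln, ": '", lines[ln], "'")
    }
    s <- toupper(fields[2L])
    if (!.is_valid_iupac(s)) {
      stop("illegal IUPAC character in recognition site at line ", ln,
           ": '", fields[2L], "'")
    }
    if (nchar(s) < 4L || nchar(s) > 15L) {
      stop("recognition site length out of range (4-15) at line ", ln,
           ": '", fields[2L], "'")
    }
    name[i] <- fields[1L]; site[i] <- s
  }
  if (anyDuplicated(name)) {
    stop("duplicate enzyme name '", name[duplicated(name)][1L], "' in ", path)
  }
  data.frame(name = name, site = site, stringsAsFactors = FALSE)
}

#' Built-in default enzyme table
#'
#' Twelve common commercial 6-cutters. This list is a user-replaceable
#' default (swap it with `load_enzymes(path)`), not an authoritative
#' catalog; it is shipped as plain CSV under
#' `system.file("extdata", "restriction_enzymes.csv", package = "crispex")`.
#'
#' @return Data frame with columns `name` and `site`.
#' @export
default_enzymes <- function() {
  path <- system.file("extdata", "restriction_enzymes.csv",
                      package = "crispex")
  if (nzchar(path)) return(load_enzymes(path))
  # fallback while the package is loaded without installed extdata
  data.frame(
    name = c("EcoRI", "BamHI", "HindIII", "XhoI", "NdeI", "SpeI",
             "PstI", "SalI", "NcoI", "KpnI", "SacI", "XbaI"),
    site = c("GAATTC", "GGATCC", "AAGCTT", "CTCGAG", "CATATG", "ACTAGT",
             "CTGCAG", "GTCGAC", "CCATGG", "GGTACC", "GAGCTC", "TCTAGA"),
    stringsAsFactors = FALSE)
}

.empty_matches <- function() {
  data.frame(enzyme_name = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             overlaps_cleavage = logical(0), stringsAsFactors = FALSE)
}

#' Find restriction sites on a candidate 23-mer
#'
#' Scans both strands of the 23-mer for each enzyme's IUPAC recognition
#' pattern (recognition sites need not be palindromic, so the reverse
#' strand is scanned too). Minus-strand matches are reported in forward
#' 23-mer coordinates; a palindromic site matching both strands over the
#' same interval is collapsed to a single `+` record. Matching is confined
#' to the 23-mer; flanking query context is not scanned.
#'
#' @param site23 A 23-nt residue string.
#' @param enzymes Enzyme table from [load_enzymes()].
#' @return Data frame with columns `enzyme_name`, `start`, `end` (1-based
#'   inclusive within the 23-mer), `strand` and `overlaps_cleavage`,
#'   sorted by (start, enzyme_name).
#' @export
#' @examples
#' find_sites("ACGTACGTACGTAGAATTCATGG", default_enzymes())
find_sites <- function(site23, enzymes) {
  stopifnot(is.character(site23), length(site23) == 1L, nchar(site23) == 23L)
  rc <- reverse_complement(site23)
  out <- list(); k <- 0L
  for (i in seq_len(nrow(enzymes))) {
    m <- nchar(enzymes$site[i])
    if (m > 23L) next
    # overlapping regex matches via zero-width lookahead
    rx <- paste0("(?=", .iupac_to_regex(enzymes$site[i]), ")")
    for (strand in c("+", "-")) {
      subject <- if (strand == "+") site23 else rc
      pos <- gregexpr(rx, subject, perl = TRUE)[[1L]]
      pos <- pos[pos > 0L]
      if (length(pos) == 0L) next
      if (strand == "+") {
        start <- as.integer(pos); end <- start + m - 1L
      } else {
        end <- 23L - as.integer(pos) + 1L; start <- end - m + 1L
      }
      k <- k + 1L
      out[[k]] <- data.frame(enzyme_name = enzymes$name[i], start = start,
                             end = end, strand = strand,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(.empty_matches())
  hits <- do.call(rbind, out)
  # collapse palindromic duplicates (same enzyme + interval on both strands)
  key <- paste(hits$enzyme_name, hits$start, hits$end)
  dup_minus <- hits$strand == "-" & key %in% key[hits$strand == "+"]
  hits <- hits[!dup_minus, , drop = FALSE]
  hits$overlaps_cleavage <- cleavage_overlaps(hits$start, hits$end)
  hits <- hits[order(hits$start, hits$enzyme_name, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Annotate a candidate with restriction-site information
#'
#' @param candidate Candidate row from [enumerate_candidates()] or a bare
#'   23-mer string.
#' @param enzymes Enzyme table from [load_enzymes()].
#' @return List with `matches` (all sites), `cleavage_matches` (the subset
#'   overlapping the cut position), and summary flags `any_site` and
#'   `any_cleavage_site`.
#' @export
annotate_restriction <- function(candidate, enzymes) {
  site23 <- if (is.character(candidate)) candidate else candidate$site23
  matches <- find_sites(site23, enzymes)
  cl <- matches[matches$overlaps_cleavage, , drop = FALSE]
  rownames(cl) <- NULL
  list(matches = matches, cleavage_matches = cl,
       any_site = nrow(matches) > 0L, any_cleavage_site = nrow(cl) > 0L)
}
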