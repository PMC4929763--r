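# PAM-anchored genome index.
#
# The catalog lists every N-free 23-nt window on either strand of every
# contig whose positions 22-23 carry the literal PAM bases of the run rule
# (start-base rule does not apply on the genome side: an off-target does
# not need a G start). Four hash keys are attached to each site:
#
#   seed  : protospacer positions 9-20 ++ PAM positions 2-3 (the 15-base
#           seed with PAM position 1, a wildcard, dropped)
#   part1 : protospacer positions 1-7
#   part2 : protospacer positions 8-14
#   part3 : protospacer positions 15-20
#
# The three parts tile the 20-mer, so by pigeonhole any genomic site within
# 2 protospacer mismatches of a candidate agrees exactly with it on at
# least one part and is reachable through that key; the seed key reaches
# every seed-exact site regardless of total mismatch count. This is the
# completeness contract find_hits() is tested against (brute_force_hits is
# the independent oracle).

.site_keys <- function(site23) {
  list(
    seed = paste0(substr(site23, 9L, 20L), substr(site23, 22L, 23L)),
    part1 = substr(site23, 1L, 7L),
    part2 = substr(site23, 8L, 14L),
    part3 = substr(site23, 15L, 20L)
  )
}

.key_env <- function(keys) {
  if (length(keys) == 0L) return(new.env(parent = emptyenv()))
  list2env(split(seq_along(keys), keys), envir = new.env(parent = emptyenv()))
}

#' Build a PAM-anchored index over a background genome
#'
#' Catalogs every valid PAM site (N-free 23-mer ending in the run's PAM) on
#' both strands of every contig, and hashes each site under seed and
#' protospacer-partition keys so that all sites within 2 protospacer
#' mismatches of any candidate, and all seed-exact sites, can be retrieved
#' without a full scan. Contigs are scanned independently: sites spanning
#' contig/scaffold boundaries do not exist, which is the correct behaviour
#' for unassembled input.
#'
#' @param genome Named character vector of contig sequences (as returned by
#'   [read_fasta()]).
#' @param config A [crispex_config()].
#' @return An object of class `crispex_index`.
#' @export
build_index <- function(genome, config) {
  stopifnot(is.character(genome))
  if (length(genome) == 0L) stop("cannot index an empty genome")
  if (is.null(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome contigs must be named")
  }

  pieces <- vector("list", 2L * length(genome))
  k <- 0L
  for (i in seq_along(genome)) {
    res <- genome[[i]]
    L <- nchar(res)
    fwd <- .scan_windows(res, config, apply_start_rule = FALSE)
    if (length(fwd)) {
      k <- k + 1L
      pieces[[k]] <- data.frame(
        contig = names(genome)[i], start = fwd, strand = "+",
        site23 = substring(res, fwd, fwd + 22L), stringsAsFactors = FALSE)
    }
    rc <- reverse_complement(res)
    rev <- .scan_windows(rc, config, apply_start_rule = FALSE)
    if (length(rev)) {
      k <- k + 1L
      pieces[[k]] <- data.frame(
        contig = names(genome)[i], start = L - rev - 21L, strand = "-",
        site23 = substring(rc, rev, rev + 22L), stringsAsFactors = FALSE)
    }
  }
  sites <- if (k == 0L) {
    data.frame(contig = character(0), start = integer(0),
               strand = character(0), site23 = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, pieces[seq_len(k)])
  }
  keys <- .site_keys(sites$site23)
  structure(
    list(contig_ids = names(genome), config = config, sites = sites,
         maps = lapply(keys, .key_env)),
    class = "crispex_index"
  )
}

#' @export
print.crispex_index <- function(x, ...) {
  cat("crispex genome index: ", length(x$contig_ids), " contig(s), ",
      nrow(x$sites), " PAM site(s), PAM rule ", x$config$pam, "\n", sep = "")
  invisible(x)
}

#' Number of cataloged PAM sites
#'
#' @param index A `crispex_index`.
#' @param by_contig If `TRUE`, return a per-contig named vector.
#' @return Integer site count(s).
#' @export
n_sites <- function(index, by_contig = FALSE) {
  stopifnot(inherits(index, "crispex_index"))
  if (!by_contig) return(nrow(index$sites))
  tab <- table(factor(index$sites$contig, levels = index$contig_ids))
  stats::setNames(as.integer(tab), index$contig_ids)
}

.empty_hits <- function() {
  data.frame(contig = character(0), start = integer(0), strand = character(0),
             mismatches = integer(0), seed_exact = logical(0),
             stringsAsFactors = FALSE)
}

# Vectorised protospacer Hamming distance of each site 23-mer against one
# candidate 23-mer (positions 1-20 only; PAM validity is a gating
# condition, never counted).
.protospacer_mismatches <- function(site23s, cand23) {
  mm <- integer(length(site23s))
  for (j in 1:20) {
    mm <- mm + (substr(site23s, j, j) != substr(cand23, j, j))
  }
  mm
}

.order_hits <- function(hits, contig_ids) {
  hits <- hits[order(match(hits$contig, contig_ids), hits$start,
                     hits$strand == "-"), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find genomic occurrences of a candidate via the index
#'
#' Returns every cataloged genomic site whose protospacer Hamming distance
#' to the candidate is at most `max_mismatch`, plus every seed-exact site
#' (last 15 bases identical, PAM position 1 wildcarded) even when its total
#' mismatch count exceeds the ceiling — the second specificity filter needs
#' those. Each hit carries the exact mismatch count and a seed-exact flag.
#'
#' @param index A `crispex_index` built with the same PAM rule.
#' @param candidate One candidate row from [enumerate_candidates()], or any
#'   list/row with a `site23` element.
#' @param config A [crispex_config()]; defaults to the index's own.
#' @return Data frame with columns `contig`, `start` (1-based
#'   forward-strand start of the 23-mer), `strand`, `mismatches`,
#'   `seed_exact`, sorted by (contig, start, strand).
#' @export
find_hits <- function(index, candidate, config = index$config) {
  stopifnot(inherits(index, "crispex_index"))
  if (config$pam != index$config$pam) {
    stop("index was built with PAM rule ", index$config$pam,
         " but the run requests ", config$pam)
  }
  cand23 <- if (is.character(candidate)) candidate else candidate$site23
  stopifnot(length(cand23) == 1L, nchar(cand23) == 23L)

  ck <- .site_keys(cand23)
  idx <- unique(unlist(lapply(names(ck), function(nm) {
    get0(ck[[nm]], envir = index$maps[[nm]], inherits = FALSE)
  }), use.names = FALSE))
  if (length(idx) == 0L) return(.empty_hits())

  sites <- index$sites[idx, , drop = FALSE]
  mm <- .protospacer_mismatches(sites$site23, cand23)
  seed <- substr(sites$site23, 9L, 20L) == substr(cand23, 9L, 20L) &
    substr(sites$site23, 22L, 23L) == substr(cand23, 22L, 23L)
  keep <- mm <= config$max_mismatch | seed
  hits <- data.frame(contig = sites$contig[keep], start = sites$start[keep],
                     strand = sites$strand[keep], mismatches = mm[keep],
                     seed_exact = seed[keep], stringsAsFactors = FALSE)
  .order_hits(hits, index$contig_ids)
}

#' Brute-force off-target search (reference oracle)
#'
#' Slides a 23-nt window over both strands of every contig, keeps PAM-valid
#' N-free windows, and computes the protospacer Hamming distance of each
#' against the candidate. Same output contract as [find_hits()] but
#' implemented with no shared matching machinery (no seed keys, no index):
#' it exists so the index path can be property-tested against it, and so
#' the whole pipeline can be re-run through an independent search path.
#'
#' @param genome Named character vector of contigs.
#' @param candidate Candidate row or bare 23-mer string.
#' @param config A [crispex_config()].
#' @return Data frame as in [find_hits()].
#' @export
brute_force_hits <- function(genome, candidate, config) {
  stopifnot(is.character(genome), length(genome) >= 1L)
  cand23 <- if (is.character(candidate)) candidate else candidate$site23
  stopifnot(length(cand23) == 1L, nchar(cand23) == 23L)
  cand_chars <- strsplit(cand23, "", fixed = TRUE)[[1L]]
  lits <- .pam_literals(config)

  out <- list(); k <- 0L
  for (i in seq_along(genome)) {
    L <- nchar(genome[[i]])
    if (L < 23L) next
    for (strand in c("+", "-")) {
      s <- if (strand == "+") genome[[i]] else reverse_complement(genome[[i]])
      starts <- seq_len(L - 22L)
      wins <- substring(s, starts, starts + 22L)
      ok <- substr(wins, 22L, 22L) == lits[1L] &
        substr(wins, 23L, 23L) == lits[2L] &
        !grepl("N", wins, fixed = TRUE)
      starts <- starts[ok]; wins <- wins[ok]
      if (length(wins) == 0L) next
      # per-window character matrix; colSums gives Hamming distances
      wmat <- matrix(unlist(strsplit(wins, "", fixed = TRUE)), nrow = 23L)
      mm <- as.integer(colSums(wmat[1:20, , drop = FALSE] !=
                                 cand_chars[1:20]))
      seed <- colSums(wmat[c(9:20, 22:23), , drop = FALSE] !=
                        cand_chars[c(9:20, 22:23)]) == 0L
      keep <- mm <= config$max_mismatch | seed
      if (!any(keep)) next
      fstart <- if (strand == "+") starts[keep] else L - starts[keep] - 21L
      k <- k + 1L
      out[[k]] <- data.frame(contig = names(genome)[i], start = fstart,
                             strand = strand, mismatches = mm[keep],
                             seed_exact = unname(seed[keep]),
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L) return(.empty_hits())
  .order_hits(do.call(rbind, out), names(genome))
}
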