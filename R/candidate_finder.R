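#' Run configuration for target design
#'
#' Bundles the tunable rules of a design run: which PAM the nuclease
#' requires (NGG for SpCas9, or the weaker NAG), whether the guide must
#' start with G (convenient for U6/T7 transcription) or may start with any
#' base, and the off-target mismatch ceiling used by the first specificity
#' filter. The seed region is fixed at the last 15 bases of the 23-mer
#' (12 PAM-proximal protospacer bases plus the 3-base PAM).
#'
#' @param pam PAM rule, `"NGG"` or `"NAG"`. One rule per run.
#' @param start Start-base rule, `"G"` (protospacer must begin with G) or
#'   `"N"` (any base).
#' @param max_mismatch Non-negative integer mismatch ceiling for the
#'   off-target search over the 20-nt protospacer (default 2).
#' @return An object of class `crispex_config`.
#' @export
#' @examples
#' crispex_config(pam = "NGG", start = "N")
crispex_config <- function(pam = c("NGG", "NAG"), start = c("N", "G"),
                           max_mismatch = 2L) {
  pam <- match.arg(pam)
  start <- match.arg(start)
  max_mismatch <- as.integer(max_mismatch)
  if (is.na(max_mismatch) || max_mismatch < 0L) {
    stop("max_mismatch must be a non-negative integer")
  }
  structure(
    list(pam = pam, start = start, max_mismatch = max_mismatch,
         seed_length = 15L),
    class = "crispex_config"
  )
}

#' @export
print.crispex_config <- function(x, ...) {
  cat("crispex run configuration\n",
      "  PAM rule:        ", x$pam, "\n",
      "  start base:      ", x$start, "\n",
      "  mismatch ceiling:", x$max_mismatch, "\n",
      "  seed length:     ", x$seed_length, " (12 protospacer nt + PAM)\n",
      sep = "")
  invisible(x)
}

# PAM positions 2-3 as literal bases for the chosen rule; position 1 is a
# wildcard (the N of NGG/NAG).
.pam_literals <- function(config) {
  if (config$pam == "NGG") c("G", "G") else c("A", "G")
}

# Scan one strand of a residue string for valid 23-nt windows. Returns
# 1-based start positions ON THAT STRAND. A valid window has the literal
# PAM bases at positions 22-23, contains no N anywhere, and (optionally)
# starts with G. Vectorised over all offsets.
.scan_windows <- function(residues, config, apply_start_rule) {
  L <- nchar(residues)
  if (L < 23L) return(integer(0))
  v <- strsplit(residues, "", fixed = TRUE)[[1L]]
  starts <- seq_len(L - 22L)
  lits <- .pam_literals(config)
  ok <- v[starts + 21L] == lits[1L] & v[starts + 22L] == lits[2L]
  if (apply_start_rule && config$start == "G") {
    ok <- ok & v[starts] == "G"
  }
  # exclude windows containing N (cumulative-count trick)
  ncum <- c(0L, cumsum(v == "N"))
  ok <- ok & (ncum[starts + 23L] - ncum[starts]) == 0L
  starts[ok]
}

.empty_candidates <- function() {
  data.frame(query_id = character(0), start = integer(0), stop = integer(0),
             strand = character(0), protospacer = character(0),
             pam = character(0), site23 = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate Cas9 targets in a query sequence
#'
#' Slides a 23-nt window over both strands of the query and keeps every
#' window whose last 3 bases satisfy the PAM rule and (under the G start
#' rule) whose first base is G. Windows containing N anywhere are excluded:
#' an ambiguous protospacer cannot be synthesised. Coordinates are 1-based
#' inclusive on the query's forward strand for both strands; for a minus
#' strand candidate, `site23` is the reverse complement of the forward
#' slice `[start, stop]`.
#'
#' @param query Length-1 named character vector (name = query id) or an
#'   unnamed string together with `id`.
#' @param config A [crispex_config()].
#' @param id Query id, defaulting to `names(query)`.
#' @return A data frame with one row per candidate and columns `query_id`,
#'   `start`, `stop`, `strand`, `protospacer` (20 nt, candidate
#'   orientation), `pam` (3 nt) and `site23` (protospacer ++ pam), sorted
#'   by (start, '+' before '-').
#' @export
#' @examples
#' cfg <- crispex_config(pam = "NGG", start = "G")
#' enumerate_candidates(c(g1 = "GTTTTTTTTTTTTTTTTTTTTGG"), cfg)
enumerate_candidates <- function(query, config, id = names(query)) {
  stopifnot(is.character(query), length(query) == 1L)
  if (is.null(id) || !nzchar(id)) stop("query id is required")
  residues <- unname(query)
  L <- nchar(residues)

  fwd <- .scan_windows(residues, config, apply_start_rule = TRUE)
  rc <- reverse_complement(residues)
  rev <- .scan_windows(rc, config, apply_start_rule = TRUE)

  n_f <- length(fwd); n_r <- length(rev)
  if (n_f + n_r == 0L) return(.empty_candidates())

  start <- c(fwd, L - rev - 21L)          # forward-strand start of 23-mer
  stop_ <- start + 22L
  strand <- c(rep("+", n_f), rep("-", n_r))
  site_f <- if (n_f) substring(residues, fwd, fwd + 22L) else character(0)
  site_r <- if (n_r) substring(rc, rev, rev + 22L) else character(0)
  site23 <- c(site_f, site_r)

  out <- data.frame(query_id = id, start = start, stop = stop_,
                    strand = strand,
                    protospacer = substr(site23, 1L, 20L),
                    pam = substr(site23, 21L, 23L),
                    site23 = site23, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$strand == "-"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
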