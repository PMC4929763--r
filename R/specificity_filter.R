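# Two-level specificity filter.
#
# A candidate is a "potential Cas9 target" when it is genome-unique in two
# senses: (level 1) no second genomic site lies within the protospacer
# mismatch ceiling, and (level 2) no second genomic site reproduces the
# 15-base seed (12 PAM-proximal protospacer bases + PAM) exactly. The
# candidate's own locus — present whenever the query derives from the
# genome — is the one permitted hit, hence the "<= 1" thresholds; queries
# absent from the genome (e.g. a plasmid insert) simply have zero hits and
# pass on the same rule.

#' First-level specificity check: mismatch-ceiling uniqueness
#'
#' Passes iff at most one genomic site (the candidate's own locus) lies
#' within `max_mismatch` protospacer mismatches — i.e. no off-target with
#' two or fewer mismatches exists anywhere in the genome under the default
#' ceiling.
#'
#' @param hits Hit table from [find_hits()] for one candidate.
#' @param config A [crispex_config()].
#' @return `TRUE`/`FALSE`.
#' @export
check_level1 <- function(hits, config) {
  sum(hits$mismatches <= config$max_mismatch) <= 1L
}

#' Second-level specificity check: seed uniqueness
#'
#' Passes iff at most one genomic site reproduces the candidate's seed
#' region (last 15 bases of the 23-mer: 12 PAM-proximal protospacer bases
#' plus the PAM, with PAM position 1 wildcarded) with zero mismatches.
#'
#' @param hits Hit table from [find_hits()] (which is guaranteed to contain
#'   every seed-exact site).
#' @return `TRUE`/`FALSE`.
#' @export
check_level2 <- function(hits) {
  sum(hits$seed_exact) <= 1L
}

#' Classify one candidate against the genome
#'
#' Runs the off-target search and applies both filter levels. Candidates
#' failing either or both filters are still classified; the reporting layer
#' decides whether to print them. Multi-copy genes legitimately fail both
#' filters — that is a finding, not an error.
#'
#' @param candidate One candidate row from [enumerate_candidates()].
#' @param index A `crispex_index`.
#' @param config A [crispex_config()]; defaults to the index's own.
#' @param hits Optional precomputed hit table (e.g. from
#'   [brute_force_hits()]) to classify through the oracle path.
#' @return One-row data frame: `n_hits_within_ceiling`, `n_seed_exact`,
#'   `level1_pass`, `level2_pass`, `potential`.
#' @export
classify <- function(candidate, index, config = index$config, hits = NULL) {
  if (is.null(hits)) hits <- find_hits(index, candidate, config)
  l1 <- check_level1(hits, config)
  l2 <- check_level2(hits)
  data.frame(
    n_hits_within_ceiling = sum(hits$mismatches <= config$max_mismatch),
    n_seed_exact = sum(hits$seed_exact),
    level1_pass = l1, level2_pass = l2, potential = l1 && l2)
}
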