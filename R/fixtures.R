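# Deterministic synthetic genomes with planted target structures.
#
# The generator plants 23-mers with known off-target structure into random
# background, then VERIFIES every plant's expected classification against
# brute_force_hits() and regenerates (bounded retries) if the random
# background accidentally creates extra hits — random 5-kb backgrounds can
# collide with 15-mer seeds, so expectations are guaranteed by rejection
# sampling, not probability.

#' Plant specifications
#'
#' Constructors for the structures [make_genome()] can plant:
#' * `plant_unique(gene_id)` — one genome-unique target; expected to pass
#'   both filters.
#' * `plant_duplicated(gene_id)` — the identical 23-mer at two loci;
#'   expected to fail both filters.
#' * `plant_near_miss(gene_id, positions)` — the target plus a second copy
#'   carrying one substitution at each listed protospacer position
#'   (1 = PAM-distal end, 20 = PAM-proximal). With <= `max_mismatch`
#'   substitutions the neighbour sits inside the ceiling and filter level 1
#'   fails; with 3+ substitutions all in positions 1-8 the neighbour's
#'   seed is intact and only level 2 fails.
#' * `plant_seed_decoy(gene_id, positions)` — convenience for the
#'   seed-exact decoy case: 3 substitutions at PAM-distal positions
#'   (default 2, 4, 6), so level 1 passes and level 2 fails.
#' * `plant_restriction(gene_id, enzyme_name, site)` — a unique target
#'   whose 23-mer carries the enzyme's recognition site over the predicted
#'   cleavage position (match end fixed at position 19).
#'
#' @param gene_id Query/gene identifier.
#' @param positions Protospacer positions (1-20) to substitute.
#' @param enzyme_name,site Enzyme name and IUPAC recognition site (length
#'   4-15; placed so the match overlaps the cut boundaries).
#' @return A `plant_spec` list consumed by [make_genome()].
#' @name plant_specs
NULL

.plant_spec <- function(kind, gene_id, ...) {
  structure(list(kind = kind, gene_id = gene_id, ...),
            class = "plant_spec")
}

#' @rdname plant_specs
#' @export
plant_unique <- function(gene_id) .plant_spec("unique_target", gene_id)

#' @rdname plant_specs
#' @export
plant_duplicated <- function(gene_id) .plant_spec("duplicated_target", gene_id)

#' @rdname plant_specs
#' @export
plant_near_miss <- function(gene_id, positions) {
  positions <- as.integer(positions)
  if (length(positions) == 0L || any(positions < 1L | positions > 20L) ||
      anyDuplicated(positions)) {
    stop("near-miss positions must be distinct protospacer positions 1-20")
  }
  .plant_spec("near_miss", gene_id, positions = sort(positions))
}

#' @rdname plant_specs
#' @export
plant_seed_decoy <- function(gene_id, positions = c(2L, 4L, 6L)) {
  positions <- as.integer(positions)
  if (any(positions > 8L) || length(positions) < 3L) {
    stop("seed-decoy substitutions must be 3+ positions within 1-8")
  }
  .plant_spec("seed_exact_decoy", gene_id, positions = sort(positions))
}

#' @rdname plant_specs
#' @export
plant_restriction <- function(gene_id, enzyme_name = "EcoRI",
                              site = "GAATTC") {
  if (!.is_valid_iupac(site) || nchar(site) < 4L || nchar(site) > 15L) {
    stop("recognition site must be IUPAC, length 4-15")
  }
  .plant_spec("restriction_overlap", gene_id, enzyme_name = enzyme_name,
              site = toupper(site))
}

# one concrete instantiation of an IUPAC pattern (never N in output)
.instantiate_iupac <- function(pattern) {
  pc <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(pc, function(p) {
    set <- setdiff(.IUPAC_SETS[[p]], "N")
    set[sample.int(length(set), 1L)]
  }, character(1)), collapse = "")
}

.random_residues <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random 23-mer target: G start (valid under both start rules), literal PAM
.random_site23 <- function(config) {
  lits <- .pam_literals(config)
  paste0("G", .random_residues(19L),
         sample(c("A", "C", "G", "T"), 1L), lits[1L], lits[2L])
}

.mutate_positions <- function(site23, positions) {
  chars <- strsplit(site23, "", fixed = TRUE)[[1L]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# closed-form expected classification for the planted candidate
.expected_for_plant <- function(plant, config) {
  extra_within <- 0L; extra_seed <- 0L
  if (plant$kind == "duplicated_target") {
    extra_within <- 1L; extra_seed <- 1L
  } else if (plant$kind %in% c("near_miss", "seed_exact_decoy")) {
    k <- length(plant$positions)
    extra_within <- as.integer(k <= config$max_mismatch)
    extra_seed <- as.integer(all(plant$positions <= 8L))
  }
  n_hits <- 1L + extra_within
  n_seed <- 1L + extra_seed
  data.frame(
    gene_id = plant$gene_id, kind = plant$kind,
    n_hits_within_ceiling = n_hits, n_seed_exact = n_seed,
    level1_pass = n_hits <= 1L, level2_pass = n_seed <= 1L,
    potential = n_hits <= 1L && n_seed <= 1L,
    any_cleavage_site = plant$kind == "restriction_overlap",
    stringsAsFactors = FALSE)
}

#' Generate a synthetic genome with planted target structures
#'
#' Draws uniform-random A/C/G/T contigs from the seeded generator, embeds
#' each plant's 23-mer(s) at non-overlapping random loci, extracts a short
#' query (the planted 23-mer plus `flank` bases of genomic context) per
#' gene, and verifies every plant's expected specificity result with
#' [brute_force_hits()], regenerating everything from fresh random draws
#' when background collisions break an expectation. Identical arguments
#' and seed give identical output bytes.
#'
#' @param plants List of [plant_specs] objects.
#' @param n_contigs,contig_length Genome shape (default 3 x 5 kb).
#' @param rng_seed Integer seed; fixed suite seeds 7, 11, 13, 42 and 99
#'   name the standard test fixtures.
#' @param config A [crispex_config()] (default NGG / any start / 2
#'   mismatches).
#' @param flank Bases of genomic context kept on each side of the planted
#'   23-mer in the query (default 10).
#' @param max_retries Bound on regeneration attempts (default 25).
#' @return List with `genome` (named contigs), `queries` (one per gene),
#'   `expected` (data frame of verified per-plant classifications and
#'   cleavage flags), `plants` (with `site23` and `locations` filled in)
#'   and `config`.
#' @export
make_genome <- function(plants, n_contigs = 3L, contig_length = 5000L,
                        rng_seed = 7L, config = crispex_config(),
                        flank = 10L, max_retries = 25L) {
  stopifnot(length(plants) >= 1L,
            all(vapply(plants, inherits, logical(1), "plant_spec")))
  ids <- vapply(plants, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_id among plants")

  set.seed(as.integer(rng_seed))
  for (attempt in seq_len(max_retries)) {
    built <- .build_attempt(plants, n_contigs, contig_length, config, flank)
    if (is.null(built)) next   # placement failed; redraw
    if (.verify_attempt(built, config)) {
      built$attempts <- attempt
      return(built)
    }
  }
  stop("fixture verification failed after ", max_retries,
       " attempts; loosen the genome shape or reduce plants")
}

.build_attempt <- function(plants, n_contigs, contig_length, config, flank) {
  # per-plant sequences to embed: primary 23-mer, plus optional second copy
  embeds <- list()
  for (i in seq_along(plants)) {
    p <- plants[[i]]
    site23 <- .random_site23(config)
    if (p$kind == "restriction_overlap") {
      inst <- .instantiate_iupac(p$site)
      m <- nchar(inst)
      start <- 19L - m + 1L          # end fixed at 19: covers 16|17 & 17|18
      substr(site23, start, 19L) <- inst
    }
    second <- switch(p$kind,
      duplicated_target = site23,
      near_miss = .mutate_positions(site23, p$positions),
      seed_exact_decoy = .mutate_positions(site23, p$positions),
      NULL)
    plants[[i]]$site23 <- site23
    embeds[[length(embeds) + 1L]] <- list(plant = i, primary = TRUE,
                                          seq = site23)
    if (!is.null(second)) {
      embeds[[length(embeds) + 1L]] <- list(plant = i, primary = FALSE,
                                            seq = second)
    }
  }

  # non-overlapping random placement with clearance for query flanks
  clearance <- 23L + 2L * flank + 4L
  if (length(embeds) * clearance > n_contigs * (contig_length - 2L * flank)) {
    stop("plants cannot fit in the requested genome shape")
  }
  genome <- stats::setNames(
    vapply(seq_len(n_contigs), function(i) .random_residues(contig_length),
           character(1)),
    paste0("contig", seq_len(n_contigs)))
  taken <- lapply(seq_len(n_contigs), function(i) integer(0))
  for (e in seq_along(embeds)) {
    placed <- FALSE
    for (try in 1:50) {
      ci <- sample.int(n_contigs, 1L)
      pos <- sample.int(contig_length - clearance, 1L) + flank
      if (!any(abs(taken[[ci]] - pos) < clearance)) {
        taken[[ci]] <- c(taken[[ci]], pos)
        embeds[[e]]$contig <- ci; embeds[[e]]$pos <- pos
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  for (e in embeds) {
    substr(genome[[e$contig]], e$pos, e$pos + 22L) <- e$seq
  }

  # queries: planted 23-mer with genomic flanks; record locations
  queries <- character(0)
  for (i in seq_along(plants)) {
    locs <- Filter(function(e) e$plant == i, embeds)
    plants[[i]]$locations <- lapply(locs, function(e) {
      list(contig = names(genome)[e$contig], pos = e$pos,
           primary = e$primary)
    })
    prim <- Filter(function(e) e$primary, locs)[[1L]]
    qstart <- prim$pos - flank
    queries[plants[[i]]$gene_id] <-
      substr(genome[[prim$contig]], qstart, prim$pos + 22L + flank)
  }

  expected <- do.call(rbind, lapply(plants, .expected_for_plant, config))
  rownames(expected) <- NULL
  list(genome = genome, queries = queries, expected = expected,
       plants = plants, config = config)
}

# oracle verification of every plant's expectation; FALSE forces a redraw
.verify_attempt <- function(built, config) {
  for (i in seq_along(built$plants)) {
    p <- built$plants[[i]]
    exp_row <- built$expected[i, ]
    hits <- brute_force_hits(built$genome, p$site23, config)
    if (sum(hits$mismatches <= config$max_mismatch) !=
        exp_row$n_hits_within_ceiling) return(FALSE)
    if (sum(hits$seed_exact) != exp_row$n_seed_exact) return(FALSE)
    # the planted candidate must be recoverable from its query
    cands <- enumerate_candidates(built$queries[p$gene_id], config,
                                  id = p$gene_id)
    if (!p$site23 %in% cands$site23) return(FALSE)
    if (p$kind == "restriction_overlap") {
      ann <- annotate_restriction(p$site23, default_enzymes())
      if (!ann$any_cleavage_site) return(FALSE)
    }
  }
  TRUE
}

#' Standard plant set for the fixture suites
#'
#' The canonical mix exercised across the fixed suite seeds: one unique
#' target, one duplicated target, a 1-mismatch and a 2-mismatch neighbour
#' (level 1 fails), a 3-mismatch seed-exact decoy (level 2 fails), and a
#' unique target carrying an EcoRI site over the cleavage position.
#'
#' @return List of [plant_specs] objects.
#' @export
standard_plants <- function() {
  list(
    plant_unique("g_unique"),
    plant_duplicated("g_dup"),
    plant_near_miss("g_near1", positions = 12L),
    plant_near_miss("g_near2", positions = c(5L, 17L)),
    plant_seed_decoy("g_decoy", positions = c(2L, 4L, 6L)),
    plant_restriction("g_rflp", enzyme_name = "EcoRI", site = "GAATTC"))
}
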