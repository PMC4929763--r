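cfg <- crispex_config(pam = "NGG", start = "N")

test_that("build_index catalogs forced and empty cases", {
  idx <- build_index(c(c1 = "GTTTTTTTTTTTTTTTTTTTTGG"), cfg)
  expect_identical(n_sites(idx), 1L)
  expect_identical(idx$sites$strand, "+")
  expect_identical(idx$sites$start, 1L)

  idx0 <- build_index(c(c1 = paste(rep("A", 100), collapse = "")), cfg)
  expect_identical(n_sites(idx0), 0L)
  expect_error(build_index(character(0), cfg), "empty genome")
})

test_that("seed-7 fixture genome site count equals the naive oracle count", {
  fx <- make_genome(standard_plants(), rng_seed = 7)
  idx <- build_index(fx$genome, cfg)
  expect_identical(n_sites(idx), naive_site_count(fx$genome, cfg))
  # frozen once from the oracle
  expect_identical(n_sites(idx), 1867L)
  expect_identical(sum(n_sites(idx, by_contig = TRUE)), 1867L)
})

test_that("verbatim planted candidate produces exactly one 0-mismatch hit", {
  set.seed(301)
  site <- paste0(random_dna(20), "TGG")
  genome <- c(chr1 = paste0(random_dna(300), site, random_dna(300)))
  idx <- build_index(genome, cfg)
  hits <- find_hits(idx, as_candidate(site), cfg)
  self <- hits[hits$mismatches == 0L, ]
  expect_identical(nrow(self), 1L)
  expect_identical(self$start, 301L)
  expect_true(self$seed_exact)
})

test_that("seed-exact copy beyond the ceiling is still returned", {
  set.seed(302)
  site <- paste0(random_dna(20), "TGG")
  # 3 substitutions at PAM-distal protospacer positions 2, 4, 6
  chars <- strsplit(site, "")[[1]]
  for (p in c(2, 4, 6)) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  decoy <- paste(chars, collapse = "")
  genome <- c(chr1 = paste0(random_dna(200), site, random_dna(100),
                            decoy, random_dna(200)))
  idx <- build_index(genome, cfg)
  hits <- find_hits(idx, as_candidate(site), cfg)
  expect_identical(hits$mismatches[order(hits$mismatches)], c(0L, 3L))
  expect_true(all(hits$seed_exact))
  # the 3-mismatch row exceeds max_mismatch = 2: it is there via the seed path
  expect_identical(sum(hits$mismatches <= cfg$max_mismatch), 1L)
})

test_that("candidate absent from the genome yields no hits", {
  set.seed(303)
  genome <- c(chr1 = random_dna(2000))
  cand <- as_candidate(paste0("G", paste(rep("AC", 9), collapse = ""), "T",
                              "TGG"))
  hits <- brute_force_hits(genome, cand, cfg)
  idx_hits <- find_hits(build_index(genome, cfg), cand, cfg)
  expect_equal(idx_hits, hits)
})

test_that("genome equal to the candidate site yields exactly one hit", {
  site <- "GACGTACGTACGTACGTACGTGG"
  hits <- brute_force_hits(c(c1 = site), as_candidate(site), cfg)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$mismatches, 0L)
  expect_true(hits$seed_exact)
})

test_that("index path equals brute force on random (genome, candidate) pairs", {
  set.seed(304)
  for (rep in 1:6) {
    genome <- c(c1 = random_dna(1500), c2 = random_dna(800))
    idx <- build_index(genome, cfg)
    # candidates drawn from the genome's own sites plus mutated variants
    picks <- idx$sites[sample.int(nrow(idx$sites), 4), "site23"]
    muts <- vapply(picks, function(s) {
      p <- sample(1:20, sample(1:3, 1))
      chars <- strsplit(s, "")[[1]]
      for (j in p) chars[j] <- sample(setdiff(c("A", "C", "G", "T"),
                                              chars[j]), 1)
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    for (s in c(picks, muts)) {
      expect_equal(find_hits(idx, as_candidate(s), cfg),
                   brute_force_hits(genome, as_candidate(s), cfg))
    }
  }
})

test_that("hit count is non-decreasing in max_mismatch", {
  set.seed(305)
  genome <- c(c1 = random_dna(3000))
  idx0 <- build_index(genome, crispex_config("NGG", "N", max_mismatch = 0))
  cand <- as_candidate(idx0$sites$site23[1])
  counts <- vapply(0:3, function(k) {
    cfgk <- crispex_config("NGG", "N", max_mismatch = k)
    hits <- brute_force_hits(genome, cand, cfgk)
    sum(hits$mismatches <= k)
  }, integer(1))
  expect_true(all(diff(counts) >= 0L))
  expect_gte(counts[1], 1L)  # self-hit always present
})

test_that("find_hits refuses an index built under a different PAM rule", {
  idx <- build_index(c(c1 = "GACGTACGTACGTACGTACGTGG"), cfg)
  expect_error(
    find_hits(idx, as_candidate("GACGTACGTACGTACGTACGTAG"),
              crispex_config("NAG", "N")),
    "PAM rule")
})
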