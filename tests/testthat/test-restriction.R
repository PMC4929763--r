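test_that("load_enzymes parses, validates and reports line numbers", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# comment", "EcoRI,GAATTC", "", "SgrDI, cgtcgacg"), path)
  enz <- load_enzymes(path)
  expect_identical(enz$name, c("EcoRI", "SgrDI"))
  expect_identical(enz$site, c("GAATTC", "CGTCGACG"))

  writeLines(c("EcoRI,GAATTC", "BadZyme,GAXTTC"), path)
  expect_error(load_enzymes(path), "IUPAC.*line 2")
  writeLines(c("EcoRI,GAATTC", "EcoRI,GAATTC"), path)
  expect_error(load_enzymes(path), "duplicate enzyme name 'EcoRI'")
  writeLines(c("OnlyName"), path)
  expect_error(load_enzymes(path), "malformed.*line 1")
  writeLines(c("# nothing"), path)
  expect_error(load_enzymes(path), "no enzymes loaded")
  writeLines(c("TooShort,ACG"), path)
  expect_error(load_enzymes(path), "length out of range")
})

test_that("default table ships 12 unique valid enzymes", {
  enz <- default_enzymes()
  expect_identical(nrow(enz), 12L)
  expect_identical(anyDuplicated(enz$name), 0L)
  expect_true(all(grepl("^[ACGT]{6}$", enz$site)))
  expect_true("EcoRI" %in% enz$name)
})

test_that("EcoRI placements match the constructed examples", {
  m <- find_sites("ACGTACGTACGTAGAATTCATGG", default_enzymes())
  expect_identical(nrow(m), 1L)
  expect_identical(m$enzyme_name, "EcoRI")
  expect_identical(c(m$start, m$end), c(14L, 19L))
  expect_identical(m$strand, "+")   # palindromic: collapsed to one record
  expect_true(m$overlaps_cleavage)

  m2 <- find_sites("GAATTCACGTACGTACGTACTGG", default_enzymes())
  expect_identical(nrow(m2), 1L)
  expect_identical(c(m2$start, m2$end), c(1L, 6L))
  expect_false(m2$overlaps_cleavage)
})

test_that("non-palindromic sites are found on the reverse strand", {
  enz <- data.frame(name = "AsymI", site = "ACCTGC", stringsAsFactors = FALSE)
  # reverse complement GCAGGT planted at forward positions 10-15
  s <- paste0("AAATTTAAA", "GCAGGT", "TTAAATTA")
  expect_identical(nchar(s), 23L)
  m <- find_sites(s, enz)
  expect_identical(nrow(m), 1L)
  expect_identical(m$strand, "-")
  expect_identical(c(m$start, m$end), c(10L, 15L))
})

test_that("cleavage-overlap predicate verified over all placements", {
  for (len in 1:23) {
    for (start in 1:(23 - len + 1)) {
      end <- start + len - 1L
      # independent reading: the match must cover both flanking bases of
      # the 17|18 or the 16|17 cut boundary
      covers_17_18 <- start <= 17L && end >= 18L
      covers_16_17 <- start <= 16L && end >= 17L
      expect_identical(cleavage_overlaps(start, end),
                       covers_17_18 || covers_16_17,
                       label = paste("interval", start, end))
    }
  }
  # a site of length >= 4 confined to the PAM cannot overlap the cut
  expect_false(cleavage_overlaps(20L, 23L))
})

test_that("find_sites equals the naive IUPAC scan on random 23-mers", {
  set.seed(501)
  enz <- rbind(default_enzymes(),
               data.frame(name = "DegI", site = "RGATCY"),
               data.frame(name = "AsymI", site = "ACCTGC"))
  for (i in 1:150) {
    s <- random_dna(23)
    expect_equal(find_sites(s, enz), naive_find_sites(s, enz))
  }
})

test_that("matches mirror under reverse complement of the 23-mer", {
  set.seed(502)
  enz <- rbind(default_enzymes(),
               data.frame(name = "AsymI", site = "ACCTGC"))
  for (i in 1:40) {
    s <- random_dna(23)
    a <- find_sites(s, enz)
    b <- find_sites(reverse_complement(s), enz)
    # mirrored interval + flipped strand (palindromes stay '+' on both)
    key_a <- sort(paste(a$enzyme_name, 24L - a$end, 24L - a$start))
    key_b <- sort(paste(b$enzyme_name, b$start, b$end))
    expect_identical(key_a, key_b)
  }
})

test_that("annotate_restriction summarises matches and cleavage overlap", {
  ann <- annotate_restriction("ACGTACGTACGTAGAATTCATGG", default_enzymes())
  expect_true(ann$any_site)
  expect_true(ann$any_cleavage_site)
  expect_identical(ann$cleavage_matches$enzyme_name, "EcoRI")

  none <- annotate_restriction(paste(rep("A", 23), collapse = ""),
                               default_enzymes())
  expect_false(none$any_site)
  expect_false(none$any_cleavage_site)
  expect_identical(nrow(none$matches), 0L)
})
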