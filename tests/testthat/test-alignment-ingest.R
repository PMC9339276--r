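test_that("triplet construction validates roles and lengths", {
  expect_error(triplet_alignment("r", "ACGT", "ACG", "ACGT"), "unequal lengths")
  ta <- triplet_alignment("r", "acgt", "ACGT", "ACGT")
  expect_identical(unname(ta$m[1, ]), c("A", "C", "G", "T"))  # case-normalized
})

test_that("the FASTA reader groups roles, errors on missing ones, and logs short regions", {
  dir <- withr::local_tempdir()
  seq60 <- strrep("ACGT", 15)   # 60 columns: too short
  seq100 <- strrep("ACGT", 25)  # 100 columns: kept
  writeLines(c(
    ">regA|ingroup1", seq100, ">regA|ingroup2", seq100, ">regA|outgroup", seq100,
    ">regB|ingroup1", seq60, ">regB|ingroup2", seq60, ">regB|outgroup", seq60
  ), file.path(dir, "two.fasta"))
  out <- read_triplet_alignments(dir)
  expect_length(out, 1L)
  expect_identical(names(out), "regA")
  log <- attr(out, "log")
  expect_identical(unname(log["regions_read"]), 2L)
  expect_identical(unname(log["regions_too_short"]), 1L)

  writeLines(c(">regC|ingroup1", seq100, ">regC|outgroup", seq100),
             file.path(dir, "bad.fasta"))
  expect_error(read_triplet_alignments(file.path(dir, "bad.fasta")),
               "missing role.*ingroup2")
})

test_that("interior columns of identical gap-free triplets are eligible", {
  ta <- identical_triplet(strrep("ACGT", 10))  # 40 columns
  el <- vapply(0:39, function(cc) site_eligible(ta, cc, radius = 3), logical(1))
  expect_identical(which(el) - 1L, 5:34)  # max(5, r) columns trimmed per end
  # radius drives the trim once it exceeds the 5-column window requirement
  el1 <- vapply(0:39, function(cc) site_eligible(ta, cc, radius = 1), logical(1))
  expect_identical(which(el1) - 1L, 5:34)
  expect_error(site_eligible(ta, 40, 3), "column")
})

test_that("the 8-of-10 gap filter and 70% similarity filter reject sites", {
  base <- strrep("ACGTTGCAAC", 4)  # 40 columns
  # three gaps among the 10 columns surrounding column 20 (0-based)
  gapped <- poke(base, c(17, 19, 23))
  ta <- triplet_alignment("r", base, gapped, base)
  expect_false(site_eligible(ta, 20, radius = 1))
  # two gaps pass the 8-of-10 filter but each gap also breaks similarity;
  # place them away from the context columns
  gapped2 <- poke(base, c(17, 24))
  ta2 <- triplet_alignment("r", base, gapped2, base)
  expect_true(site_eligible(ta2, 20, radius = 1))
  # three mismatches keep similarity at exactly 7 of 10; a fourth breaks it
  mm3 <- poke(poke(poke(base, 17, "A"), 19, "C"), 23, "T")
  ta3 <- triplet_alignment("r", base, mm3, base)
  expect_true(site_eligible(ta3, 20, radius = 1))
  mm4 <- poke(mm3, 16, "A")
  ta4 <- triplet_alignment("r", base, mm4, base)
  expect_false(site_eligible(ta4, 20, radius = 1))
})

test_that("a non-conserved flanking base disqualifies the context", {
  base <- strrep("ACGTTGCAAC", 4)
  # outgroup differs from the ingroups at alignment column 21 (0-based)
  outg <- poke(base, 22, "G")
  ta <- triplet_alignment("r", base, base, outg)
  expect_false(site_eligible(ta, 20, radius = 1))   # column 21 is its neighbor
  expect_false(site_eligible(ta, 22, radius = 1))
  expect_true(site_eligible(ta, 18, radius = 1))    # outside the radius
  expect_false(site_eligible(ta, 18, radius = 3))   # inside at radius 3
  # ambiguity codes make a column ineligible as focal or context
  amb <- poke(base, 20, "N")
  ta2 <- triplet_alignment("r", amb, amb, amb)
  expect_false(site_eligible(ta2, 19, radius = 1))
  expect_false(site_eligible(ta2, 20, radius = 1))
})

test_that("record extraction emits two records per eligible column", {
  ta <- identical_triplet(strrep("ACGT", 10))
  recs <- extract_site_records(ta, radius = 3)
  el <- eligible_count <- sum(vapply(0:39, function(cc) site_eligible(ta, cc, 3),
                                     logical(1)))
  expect_identical(nrow(recs), 2L * eligible_count)
  expect_true(all(recs$ancestral == recs$derived))  # fully conserved triplet
  expect_identical(sort(unique(recs$ingroup)), c(1L, 2L))
  # contexts are the physical neighbors
  r10 <- recs[recs$column == 10 & recs$ingroup == 1, ]
  expect_identical(r10$left, "TAC")   # columns 7..9 of ACGTACGT...
  expect_identical(r10$right, "TAC")
  expect_identical(r10$ancestral, "G")
})

test_that("substituted and double-substituted columns follow the increment rule", {
  base <- strrep("ACGTTGCAAC", 4)
  in1 <- poke(base, 21, "G")  # column 20 (0-based): outgroup A -> ingroup1 G
  ta <- triplet_alignment("r", in1, base, base)
  recs <- extract_site_records(ta, radius = 2)
  r20 <- recs[recs$column == 20, ]
  expect_identical(nrow(r20), 2L)
  expect_identical(r20$ancestral, c("A", "A"))
  expect_identical(r20$derived[r20$ingroup == 1], "G")
  expect_identical(r20$derived[r20$ingroup == 2], "A")
  # both ingroups differing from the outgroup yields two substitutions
  in2 <- poke(base, 21, "C")
  ta2 <- triplet_alignment("r", in1, in2, base)
  r20b <- extract_site_records(ta2, radius = 2)
  r20b <- r20b[r20b$column == 20, ]
  expect_setequal(r20b$derived, c("G", "C"))
  expect_identical(r20b$ancestral, c("A", "A"))
})

test_that("adding a gap never makes an ineligible site eligible (monotonicity)", {
  withr::local_seed(11)
  base <- generate_ancestor(60, 0.5)
  for (i in 1:20) {
    s2 <- poke(base, sample(60, 3))
    ta <- triplet_alignment("r", base, s2, base)
    before <- eligible_cols <- which(vapply(0:59, function(cc)
      site_eligible(ta, cc, 2), logical(1)))
    s3 <- poke(s2, sample(60, 1))
    ta2 <- triplet_alignment("r", base, s3, base)
    after <- which(vapply(0:59, function(cc) site_eligible(ta2, cc, 2),
                          logical(1)))
    expect_true(all(after %in% before))
  }
})

test_that("filter tallies account for every scanned column", {
  m <- builtin_model("uniform", radius = 1)
  p <- simulation_params(n_regions = 4, region_length = 300,
                         ingroup_branch = 0.05, outgroup_branch = 0.05,
                         indel_rate = 0.005, seed = 6)
  recs <- extract_records(dataset_triplets(generate_triplet_dataset(p, m)),
                          radius = 3)
  log <- attr(recs, "log")
  expect_identical(
    unname(log["columns_scanned"]),
    unname(sum(log[setdiff(names(log), "columns_scanned")]))
  )
  expect_identical(nrow(recs), 2L * unname(log["eligible"]))
})
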