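test_that("generated ancestors honor the composition parameters", {
  expect_match(generate_ancestor(10, gc_content = 0, seed = 1), "^[AT]+$")
  expect_match(generate_ancestor(10, gc_content = 1, seed = 1), "^[CG]+$")
  # binomial oracle: observed G+C within 3 standard errors of 0.5
  s <- generate_ancestor(10000, gc_content = 0.5, seed = 7)
  gc <- mean(strsplit(s, NULL)[[1]] %in% c("C", "G"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(generate_ancestor(0), "positive")
  expect_error(generate_ancestor(-3), "positive")
})

test_that("model presets validate names and reduce to uniform at k = 1", {
  expect_error(builtin_model("nope"), "unknown model preset")
  u <- builtin_model("uniform", radius = 1)
  c1 <- builtin_model("cpg", radius = 1, k = 1)
  ctx <- enumerate_contexts(1)
  for (from in c("A", "C", "G", "T")) {
    for (to in setdiff(c("A", "C", "G", "T"), from)) {
      expect_equal(
        c1$rate_fn(ctx$left, ctx$right, rep(from, 16), rep(to, 16)),
        as.numeric(u$rate_fn(ctx$left, ctx$right, rep(from, 16), rep(to, 16)))
      )
    }
  }
})

test_that("cpg preset boosts only CpG-facing transitions", {
  m <- builtin_model("cpg", radius = 2, k = 2.5, mu = 1 / 3)
  # focal C followed by G: transition C->T boosted
  expect_equal(m$rate_fn("AA", "GA", "C", "T"), 2.5 / 3, ignore_attr = TRUE)
  # transversions never boosted
  expect_equal(m$rate_fn("AA", "GA", "C", "A"), 1 / 3, ignore_attr = TRUE)
  # focal G preceded by C: transition G->A boosted
  expect_equal(m$rate_fn("AC", "AA", "G", "A"), 2.5 / 3, ignore_attr = TRUE)
  # no CpG: baseline
  expect_equal(m$rate_fn("AA", "AA", "C", "T"), 1 / 3, ignore_attr = TRUE)
})

test_that("ati_tv preset scales transversions by the configured ATI fold", {
  m <- builtin_model("ati_tv", tv_ratio = 4, mu = 1 / 3)
  tv_hi <- m$rate_fn("AAA", "AAA", "T", "G")  # ATI = 28
  tv_lo <- m$rate_fn("GGG", "CCC", "T", "G")  # ATI = 0
  expect_equal(tv_hi / tv_lo, 4)
  ts_hi <- m$rate_fn("AAA", "AAA", "T", "C")
  expect_equal(ts_hi, 1 / 3, ignore_attr = TRUE)
  expect_error(builtin_model("ati_tv", radius = 2), "radius 3")
})

test_that("evolution at branch 0 is the identity and negative branches error", {
  m <- builtin_model("uniform", radius = 3)
  s <- generate_ancestor(100, seed = 4)
  out <- evolve_sequence(s, m, 0, seed = 1)
  expect_identical(as.character(out), s)
  expect_identical(attr(out, "n_events"), 0L)
  expect_error(evolve_sequence(s, m, -0.1), "nonnegative")
  expect_error(evolve_sequence("ACGTA", m, 0.1), "exceed")
})

test_that("uniform-model event counts match the Poisson oracle", {
  # with mu = 1/3 the per-site total rate is exactly 1, so the event count
  # is Poisson(n_active * branch)
  m <- builtin_model("uniform", radius = 3)
  s <- generate_ancestor(5000, gc_content = 0.5, seed = 1)
  lambda <- (5000 - 6) * 0.05
  ev <- evolve_sequence(s, m, 0.05, seed = 2)
  expect_lt(abs(attr(ev, "n_events") - lambda), 3 * sqrt(lambda))
})

test_that("cpg-model evolution elevates C->T in CG dinucleotides", {
  m <- builtin_model("cpg", radius = 1, k = 4)
  s <- generate_ancestor(30000, gc_content = 0.5, seed = 3)
  out <- as.character(evolve_sequence(s, m, 0.04, seed = 5))
  a <- strsplit(s, NULL)[[1]]
  d <- strsplit(out, NULL)[[1]]
  nxt <- c(a[-1], "X")  # ancestral 3' neighbor
  cg <- a == "C" & nxt == "G"
  ch <- a == "C" & nxt != "G" & nxt != "X"
  rate_cg <- mean(d[cg] == "T")
  rate_ch <- mean(d[ch] == "T")
  expect_gt(rate_cg, rate_ch)
  expect_gt(rate_cg / rate_ch, 2)  # well separated at k = 4
})

test_that("simulation is deterministic given the master seed", {
  m <- builtin_model("cpg", radius = 1, k = 1.5)
  p <- simulation_params(n_regions = 3, region_length = 200,
                         ingroup_branch = 0.05, outgroup_branch = 0.05,
                         indel_rate = 0.005, seed = 42)
  d1 <- generate_triplet_dataset(p, m)
  d2 <- generate_triplet_dataset(p, m)
  expect_identical(d1$regions, d2$regions)
  d3 <- generate_triplet_dataset(
    simulation_params(n_regions = 3, region_length = 200,
                      ingroup_branch = 0.05, outgroup_branch = 0.05,
                      indel_rate = 0.005, seed = 43), m)
  expect_false(identical(d1$regions, d3$regions))
})

test_that("zero branches and zero indels give three identical ungapped sequences", {
  m <- builtin_model("uniform", radius = 1)
  p <- simulation_params(n_regions = 2, region_length = 150, ingroup_branch = 0,
                         outgroup_branch = 0, indel_rate = 0, seed = 1)
  ds <- generate_triplet_dataset(p, m)
  for (reg in ds$regions) {
    aln <- reg$alignment
    expect_identical(aln[["ingroup1"]], aln[["ingroup2"]])
    expect_identical(aln[["ingroup1"]], aln[["outgroup"]])
    expect_false(grepl("-", aln[["outgroup"]], fixed = TRUE))
  }
})

test_that("indels introduce gap columns and preserve true homology", {
  m <- builtin_model("uniform", radius = 1)
  p <- simulation_params(n_regions = 6, region_length = 400,
                         ingroup_branch = 0.02, outgroup_branch = 0,
                         indel_rate = 0.01, seed = 8)
  ds <- generate_triplet_dataset(p, m)
  alns <- lapply(ds$regions, `[[`, "alignment")
  any_gap <- any(vapply(alns, function(a) any(grepl("-", a, fixed = TRUE)),
                        logical(1)))
  expect_true(any_gap)
  for (reg in ds$regions) {
    aln <- reg$alignment
    expect_identical(length(unique(nchar(aln))), 1L)
    # stripping gaps from the outgroup row recovers the ungapped ancestor
    # lineage (outgroup branch is 0 here)
    expect_identical(gsub("-", "", aln[["outgroup"]]), reg$truth$ancestor)
  }
})

test_that("FASTA output round-trips through the reader", {
  m <- builtin_model("uniform", radius = 1)
  p <- simulation_params(n_regions = 3, region_length = 120,
                         ingroup_branch = 0.03, outgroup_branch = 0.03, seed = 2)
  ds <- generate_triplet_dataset(p, m)
  dir <- withr::local_tempdir()
  write_triplet_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- read_triplet_alignments(dir)
  expect_length(back, 3L)
  direct <- dataset_triplets(ds)
  for (reg in names(back)) {
    expect_identical(back[[reg]]$m, direct[[reg]]$m)
  }
})
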