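test_that("coverage_summary unions intervals per reference and per contig", {
  rl <- c(ref1 = 600)
  full <- mk_hit("c1", "ref1", 1, 600, 1, 600)
  cov <- coverage_summary(full, rl)
  expect_equal(cov$covered_all, 1)
  expect_equal(cov$covered_best_single, 1)
  expect_equal(cov$best_contig_id, "c1")

  halves <- dplyr::bind_rows(mk_hit("c1", "ref1", 1, 300, 1, 300),
                             mk_hit("c2", "ref1", 1, 300, 301, 600))
  cov <- coverage_summary(halves, rl)
  expect_equal(cov$covered_all, 1)
  expect_equal(cov$covered_best_single, 0.5)

  # overlapping HSPs of the same contig merge, never sum
  hsp <- dplyr::bind_rows(mk_hit("c1", "ref1", 1, 200, 1, 200),
                          mk_hit("c1", "ref1", 151, 400, 151, 400))
  cov <- coverage_summary(hsp, rl)
  expect_equal(cov$covered_best_single, 400 / 600)
  expect_equal(cov$covered_all,
               oracle_union_length(c(0, 150), c(200, 400)) / 600)
})

test_that("references without hits get zero coverage, no best contig", {
  cov <- coverage_summary(mk_hit("c1", "ref1", 1, 100, 1, 100),
                          c(ref1 = 200, ref2 = 300))
  r2 <- cov[cov$ref_id == "ref2", ]
  expect_equal(r2$covered_all, 0)
  expect_true(is.na(r2$best_contig_id))
})

test_that("completeness and contiguity count thresholds inclusively", {
  cov <- tibble::tibble(
    ref_id = c("r1", "r2", "r3"), ref_length = 1000,
    covered_all = c(0.9, 0.8, 0.5), covered_best_single = c(0.9, 0.8, 0.5),
    best_contig_id = "c")
  expect_equal(completeness(cov, c("r1", "r2", "r3"), 0.8), 100 * 2 / 3)
  expect_equal(contiguity(cov, c("r1", "r2", "r3"), 0.8), 100 * 2 / 3)
  expect_equal(completeness(cov, c("r1", "r2", "r3"), 1), 0)
  expect_error(completeness(cov, character(0), 0.8), "empty")
})

test_that("two half-covering contigs give completeness without contiguity", {
  rl <- c(ref1 = 600, ref2 = 400)
  hits <- dplyr::bind_rows(
    mk_hit("a1", "ref1", 1, 300, 1, 300), mk_hit("a2", "ref1", 1, 300, 301, 600),
    mk_hit("b1", "ref2", 1, 200, 1, 200), mk_hit("b2", "ref2", 1, 200, 201, 400))
  cov <- coverage_summary(hits, rl)
  expect_equal(completeness(cov, threshold = 0.8), 100)
  expect_equal(contiguity(cov, threshold = 0.8), 0)
})

test_that("metric curves are monotone and consistent with single calls", {
  withr::local_seed(2)
  ref <- simulate_reference(40, c(600, 1500), seed = 21)
  sim <- simulate_assembly(ref, seed = 22)
  rl <- stats::setNames(nchar(ref$sequence), ref$id)
  cov <- coverage_summary(sim$hits, rl)
  mc <- metric_curve(cov, thresholds = c(0.5, 0.8, 1.0))
  expect_equal(nrow(mc), 3)
  expect_true(all(diff(mc$completeness) <= 0))
  expect_true(all(diff(mc$contiguity) <= 0))
  expect_true(all(mc$contiguity <= mc$completeness))
  expect_equal(mc$completeness[2], completeness(cov, threshold = 0.8))
  expect_equal(mc$contiguity[2], contiguity(cov, threshold = 0.8))
})

test_that("adding a hit never decreases union coverage", {
  withr::local_seed(77)
  rl <- c(refA = 500)
  hits <- mk_hit("c1", "refA", 1, 100, 50, 149)
  prev <- coverage_summary(hits, rl)$covered_all
  for (k in 1:15) {
    s <- sample(1:450, 1)
    hits <- dplyr::bind_rows(hits, mk_hit(paste0("n", k), "refA",
                                          1, 50, s, s + 49))
    cur <- coverage_summary(hits, rl)$covered_all
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("OHR uses the best-bitscore subject and the interval union", {
  rl <- c(ref1 = 600, ref2 = 500)
  expect_equal(ortholog_hit_ratio(mk_hit("c1", "ref1", 1, 300, 101, 400),
                                  rl)$ohr, 0.5)

  # whole subject covered twice over: capped at 1
  twice <- dplyr::bind_rows(mk_hit("c1", "ref1", 1, 600, 1, 600),
                            mk_hit("c1", "ref1", 601, 1200, 1, 600))
  expect_equal(ortholog_hit_ratio(twice, rl)$ohr, 1)

  # two subjects: summed bitscore decides
  two <- dplyr::bind_rows(mk_hit("c1", "ref1", 1, 300, 1, 300, bits = 500),
                          mk_hit("c1", "ref2", 1, 400, 1, 400, bits = 300))
  o <- ortholog_hit_ratio(two, rl)
  expect_equal(o$subject_id, "ref1")
  expect_equal(o$ohr, 300 / 600)

  # bitscore tie: the lower evalue wins, then the lexicographic subject
  tie <- dplyr::bind_rows(
    mk_hit("c1", "ref2", 1, 300, 1, 300, bits = 400, ev = 1e-60),
    mk_hit("c1", "ref1", 1, 300, 1, 300, bits = 400, ev = 1e-40))
  expect_equal(ortholog_hit_ratio(tie, rl)$subject_id, "ref2")
})

test_that("OHR is invariant to splitting an HSP into adjacent pieces", {
  rl <- c(ref1 = 800)
  whole <- mk_hit("c1", "ref1", 1, 400, 201, 600)
  split <- dplyr::bind_rows(mk_hit("c1", "ref1", 1, 200, 201, 400, bits = 50),
                            mk_hit("c1", "ref1", 201, 400, 401, 600, bits = 50))
  expect_equal(ortholog_hit_ratio(whole, rl)$ohr,
               ortholog_hit_ratio(split, rl)$ohr)
})

test_that("simulated assemblies reproduce their designed coverage exactly", {
  ref <- simulate_reference(60, c(700, 1800), seed = 31)
  sim <- simulate_assembly(ref, dup_rate = 0.05, chimera_rate = 0.04,
                           seed = 32)
  rl <- stats::setNames(nchar(ref$sequence), ref$id)
  cov <- coverage_summary(sim$hits, rl)
  tr <- sim$truth$references
  j <- dplyr::left_join(cov, tr, by = "ref_id",
                        suffix = c("_obs", "_truth"))
  expect_equal(j$covered_all_obs, j$covered_all_truth)
  expect_equal(j$covered_best_single_obs, j$covered_best_single_truth)
})
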