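test_that("site counting matches exhaustive enumeration of single changes", {
  # verified by the brute-force oracle, then frozen
  expect_equal(count_sites("TTT"), oracle_sites("TTT"))
  expect_equal(count_sites("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(count_sites("GGG"), c(s = 1, n = 2))
  expect_equal(count_sites("ATG"), c(s = 0, n = 3))
  for (codon in c("AAA", "CGA", "TGG", "ATC", "CTG")) {
    expect_equal(count_sites(codon), oracle_sites(codon))
  }
  expect_error(count_sites("TAA"), "stop")
  expect_error(count_sites("AXT"), "invalid")
})

test_that("site fractions always sum to 3 under both stop conventions", {
  gc <- oracle_code()
  sense <- names(gc)[gc != "*"]
  for (mode in c("nonsyn", "exclude")) {
    tot <- vapply(sense, function(cd) sum(count_sites(cd, mode)), numeric(1))
    expect_equal(unname(tot), rep(3, length(sense)), tolerance = 1e-12)
  }
})

test_that("codon differences average over minimal mutational pathways", {
  expect_equal(count_differences("GAA", "GAG"), c(sd = 1, nd = 0))
  expect_equal(count_differences("AAA", "AGA"), c(sd = 0, nd = 1))
  # TTT -> GTA: path via GTT is (nonsyn, syn), via TTA is (nonsyn, nonsyn)
  expect_equal(count_differences("TTT", "GTA"), c(sd = 0.5, nd = 1.5))
  expect_equal(count_differences("TTT", "GTA"), oracle_diffs("TTT", "GTA"))
  expect_equal(count_differences("ACG", "ACG"), c(sd = 0, nd = 0))
})

test_that("pathways through stop codons are excluded", {
  # TAT -> TGG: via TGT (Cys) fine, via TAG (stop) excluded
  expect_equal(count_differences("TAT", "TGG"), oracle_diffs("TAT", "TGG"))
  withr::local_seed(6)
  gc <- oracle_code()
  sense <- names(gc)[gc != "*"]
  for (k in 1:30) {
    pair <- sample(sense, 2)
    o <- oracle_diffs(pair[1], pair[2])
    if (is.null(o)) next
    expect_equal(count_differences(pair[1], pair[2]), o, tolerance = 1e-12)
  }
})

test_that("kaks is symmetric and respects the site sum rule", {
  withr::local_seed(14)
  for (k in 1:5) {
    a <- random_cds(40)
    b <- random_cds(40)
    ra <- tidy(kaks(a, b))
    rb <- tidy(kaks(b, a))
    expect_equal(ra, rb)
    expect_equal(ra$S + ra$N, 3 * ra$n_codons_used, tolerance = 1e-9)
  }
})

test_that("kaks agrees with the brute-force oracle to 1e-9", {
  withr::local_seed(15)
  for (k in 1:20) {
    sim <- simulate_divergent_pair(50, runif(1, 0, 0.2), runif(1, 0, 0.3),
                                   seed = 7000 + k)
    got <- kaks(sim$seq_a, sim$seq_b)
    want <- oracle_kaks(sim$seq_a, sim$seq_b)
    for (f in c("S", "N", "Sd", "Nd", "pS", "pN", "Ks", "Ka")) {
      expect_equal(got[[f]], want[[f]], tolerance = 1e-9)
    }
  }
})

test_that("identical sequences give zero divergence, undefined ratio", {
  a <- random_cds(30)
  r <- kaks(a, a)
  expect_equal(r$Sd, 0)
  expect_equal(r$Ka, 0)
  expect_true(is.na(r$ratio))
})

test_that("purely synonymous divergence yields Ka = 0, Ks > 0", {
  sim <- simulate_divergent_pair(200, target_pN = 0, target_pS = 0.1,
                                 seed = 71)
  r <- kaks(sim$seq_a, sim$seq_b)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  expect_equal(r$Nd, 0)
})

test_that("codons with gaps or ambiguity are dropped pairwise", {
  a <- "ATGAAA---GGG"
  b <- "ATGAAGCCCGGG"
  r <- kaks(a, b)
  expect_equal(r$n_codons_used, 3)
  rn <- kaks("ATGANA", "ATGAAA")
  expect_equal(rn$n_codons_used, 1)
  expect_error(kaks("ATG", "ATGAAA"), "equal length")
  expect_error(kaks("---", "AAA"), "usable")
})

test_that("Jukes-Cantor correction reduces to p for small p", {
  for (p in c(0.01, 0.03, 0.049)) {
    ks <- -0.75 * log(1 - 4 * p / 3)
    expect_lte(abs(ks - p), p^2)
  }
  sim <- simulate_divergent_pair(400, 0.02, 0.04, seed = 81)
  r <- kaks(sim$seq_a, sim$seq_b)
  expect_lte(abs(r$Ks - r$pS), r$pS^2)
})

test_that("planted divergence is recovered exactly at one change per codon", {
  for (s in 1:5) {
    sim <- simulate_divergent_pair(300, 0.05, 0.15, seed = 90 + s)
    r <- kaks(sim$seq_a, sim$seq_b)
    expect_equal(r$Sd, sim$truth$Sd)
    expect_equal(r$Nd, sim$truth$Nd)
  }
})

test_that("two-record FASTA input flows through kaks_from_fasta", {
  sim <- simulate_divergent_pair(60, 0.05, 0.1, seed = 55)
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tibble::tibble(id = c("a", "b"),
                             sequence = c(sim$seq_a, sim$seq_b),
                             description = ""), tf)
  expect_equal(tidy(kaks_from_fasta(tf)), tidy(kaks(sim$seq_a, sim$seq_b)))
  write_fasta(tibble::tibble(id = "a", sequence = sim$seq_a,
                             description = ""), tf)
  expect_error(kaks_from_fasta(tf), "exactly 2")
})
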