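make_set <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), sequence = unname(seqs), description = "")
}

test_that("the minimum-length filter is inclusive at the boundary", {
  withr::local_seed(10)
  x <- random_seqset(3)
  x$sequence <- vapply(c(150, 200, 350), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  expect_equal(filter_min_length(x, 200)$id, c("s002", "s003"))
  expect_equal(filter_min_length(x, 1), x)
  expect_equal(nrow(filter_min_length(x, 1000)), 0)
})

test_that("n50 matches the exhaustive oracle on fixed and random inputs", {
  expect_equal(n50(c(4, 3, 3, 2, 2, 2)), oracle_n50(c(4, 3, 3, 2, 2, 2)))
  expect_equal(n50(c(4, 3, 3, 2, 2, 2)), 3)
  expect_equal(n50(7), 7)
  expect_equal(n50(c(5, 5, 5, 5)), 5)
  expect_error(n50(numeric(0)), "empty")
  withr::local_seed(99)
  for (k in 1:25) {
    lens <- sample(1:5000, sample(1:200, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("deduplicate removes identical, contained and rc-contained contigs", {
  x <- make_set(c1 = "ACGTACGT", c2 = "ACGTACGT")
  d <- deduplicate(x)
  expect_equal(d$id, "c1")
  expect_equal(dedup_removed(d),
               tibble::tibble(id = "c2", kept_id = "c1",
                              reason = "identical"))

  x <- make_set(c1 = "ACGTACGTAA", c2 = "GTACGT")
  d <- deduplicate(x)
  expect_equal(d$id, "c1")
  expect_equal(dedup_removed(d)$reason, "contained")

  # c2 equals the reverse complement of a window of c1
  win <- substr("ACGTTGCAGGT", 3, 9)
  x <- make_set(c1 = "ACGTTGCAGGT", c2 = oracle_revcomp(win))
  d <- deduplicate(x)
  expect_equal(d$id, "c1")
  expect_equal(dedup_removed(d)$reason, "contained_rc")
})

test_that("deduplicate keeps the longest member, breaking ties by id", {
  x <- make_set(z9 = "ACGTACGT", a1 = "ACGTACGT", m5 = "CGTAC")
  d <- deduplicate(x)
  expect_equal(d$id, "a1")
  rem <- dedup_removed(d)
  expect_setequal(rem$id, c("z9", "m5"))
  expect_equal(unique(rem$kept_id), "a1")
})

test_that("deduplicate is idempotent and agrees with the quadratic oracle", {
  withr::local_seed(7)
  for (k in 1:20) {
    base <- random_seqset(sample(5:40, 1), len_range = c(15, 60))
    # plant some redundancy
    extra <- base[sample(nrow(base), 3, replace = TRUE), ]
    extra$id <- paste0("x", seq_len(nrow(extra)))
    extra$sequence[2] <- substr(extra$sequence[2], 2,
                                max(3, nchar(extra$sequence[2]) - 1))
    x <- dplyr::bind_rows(base, extra)
    d <- deduplicate(x)
    expect_equal(sort(d$id), oracle_dedup_ids(x$id, x$sequence))
    d2 <- deduplicate(dplyr::select(d, id, sequence, description))
    expect_equal(d2$id, d$id)
    expect_equal(nrow(dedup_removed(d2)), 0)
  }
})

test_that("planting k exact duplicates lowers the nonredundant count by k", {
  withr::local_seed(123)
  x <- random_seqset(30, len_range = c(40, 80))
  k <- 6
  dup <- x[sample(30, k), ]
  dup$id <- paste0("dup", seq_len(k))
  both <- dplyr::bind_rows(x, dup)
  expect_equal(nrow(deduplicate(both)), nrow(deduplicate(x)))
  expect_equal(length_stats(both)$nonredundant_contigs,
               length_stats(both)$total_contigs - k)
})

test_that("length_stats reports the expected arithmetic", {
  withr::local_seed(5)
  x <- random_seqset(3)
  x$sequence <- vapply(c(100, 200, 300), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  s <- length_stats(x)
  expect_equal(s$total_contigs, 3)
  expect_equal(s$total_bases, 600)
  expect_equal(s$mean_length, 200)
  expect_equal(s$n50, 300)
  expect_equal(s$nonredundant_contigs, 3)

  one <- x[1, ]
  s1 <- length_stats(one)
  expect_equal(s1$mean_length, s1$n50)
  expect_error(length_stats(x[0, ]), "empty")
})

test_that("filtered total bases equal the sum of retained lengths", {
  withr::local_seed(31)
  x <- random_seqset(50, len_range = c(50, 400))
  f <- filter_min_length(x, 200)
  expect_equal(length_stats(f, dedup = FALSE)$total_bases,
               sum(nchar(f$sequence)))
})

test_that("merging assemblies unions, labels, and deduplicates", {
  withr::local_seed(8)
  a <- random_seqset(5, len_range = c(30, 60))
  b <- random_seqset(5, len_range = c(30, 60))
  m <- merge_assemblies(list(a, b), c("k25", "k31"))
  expect_equal(nrow(m), 10)
  expect_true(all(grepl("^k(25|31)\\|", m$id)))

  m2 <- merge_assemblies(list(a, a), c("k25", "k31"))
  expect_equal(nrow(m2), nrow(a))

  # one contig of b contained in a contig of a
  b$sequence[1] <- substr(a$sequence[1], 3, 25)
  m3 <- merge_assemblies(list(a, b), c("k25", "k31"))
  expect_equal(sort(m3$id),
               oracle_dedup_ids(c(paste0("k25|", a$id), paste0("k31|", b$id)),
                                c(a$sequence, b$sequence)))
})
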