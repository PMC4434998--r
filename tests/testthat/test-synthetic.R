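test_that("random_dna is seeded, uniform, and leaves the caller's RNG alone", {
  expect_equal(length(random_dna(0)), 0L)
  a <- random_dna(5000, seed = 8)
  b <- random_dna(5000, seed = 8)
  expect_identical(a$symbols, b$symbols)
  expect_false(identical(a$symbols, random_dna(5000, seed = 9)$symbols))
  expect_error(random_dna(-1), "non-negative")

  freq <- table(strsplit(random_dna(1e5, seed = 3)$symbols, "")[[1]]) / 1e5
  expect_true(all(abs(freq - 0.25) < 0.01))

  set.seed(123)
  before <- .Random.seed
  invisible(random_dna(100, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("copy operations reproduce the source exactly at substitution rate zero", {
  ref <- dna_seq("ACGT", name = "r")
  out <- apply_edit_script(ref, script_copy(0, 4, "direct", 0), seed = 1)
  expect_equal(out$target$symbols, "ACGT")
  expect_equal(as.data.frame(out$truth[, c("target_start", "target_end",
                                           "ref_start", "ref_end", "orientation")]),
               data.frame(target_start = 0L, target_end = 4L,
                          ref_start = 0L, ref_end = 4L,
                          orientation = "direct"))

  inv <- apply_edit_script(dna_seq("AACG"), script_copy(0, 4, "inverted", 0),
                           seed = 1)
  expect_equal(inv$target$symbols, "CGTT")

  big <- random_dna(5000, seed = 2)
  cp <- apply_edit_script(big, script_copy(1000, 3000, "direct", 0), seed = 5)
  expect_identical(cp$target$symbols, substr(big$symbols, 1001, 4000))
  icp <- apply_edit_script(big, script_copy(1000, 3000, "inverted", 0), seed = 5)
  expect_identical(icp$target$symbols,
                   reverse_complement(substr(big$symbols, 1001, 4000)))
})

test_that("substitutions hit at the nominal mismatch rate, never silently", {
  ref <- random_dna(1e5, seed = 4)
  out <- apply_edit_script(ref, script_copy(0, 1e5, "direct", 0.01), seed = 6)
  a <- strsplit(ref$symbols, "")[[1]]
  b <- strsplit(out$target$symbols, "")[[1]]
  mismatches <- sum(a != b)
  # every substituted position differs (draws come from the 3 other symbols),
  # so mismatches ~ Binomial(1e5, 0.01): mean 1000, sd ~31
  expect_gt(mismatches, 1000 - 5 * 31)
  expect_lt(mismatches, 1000 + 5 * 31)
})

test_that("truth intervals tile the target and map onto script operations", {
  ref <- random_dna(20000, seed = 10)
  script <- dplyr::bind_rows(
    script_copy(0, 5000, "direct", 0.02),
    script_n_run(2000),
    script_copy(10000, 4000, "inverted", 0),
    script_novel(3000)
  )
  out <- apply_edit_script(ref, script, seed = 11)
  tr <- out$truth
  expect_equal(nrow(tr), nrow(script))
  expect_equal(tr$op, script$op)
  expect_equal(tr$target_start, head(c(0L, cumsum(script$length)), -1))
  expect_equal(tr$target_end, cumsum(script$length))
  expect_equal(length(out$target), sum(script$length))
  # the N block is literal N's before preprocessing
  expect_equal(substr(out$target$symbols, 5001, 7000), strrep("N", 2000))
  expect_error(apply_edit_script(ref, script_copy(19000, 5000), seed = 1),
               "outside")
})

test_that("the per-operation seed stream is stable under script extension", {
  ref <- random_dna(10000, seed = 12)
  s1 <- dplyr::bind_rows(script_copy(0, 3000, "direct", 0.05),
                         script_novel(2000))
  s2 <- dplyr::bind_rows(s1, script_copy(5000, 2000, "inverted", 0.05))
  a <- apply_edit_script(ref, s1, seed = 13)
  b <- apply_edit_script(ref, s2, seed = 13)
  expect_identical(substr(b$target$symbols, 1, 5000), a$target$symbols)
})

test_that("edit scripts round-trip through JSON", {
  script <- planted_script(0.01)
  tf <- withr::local_tempfile(fileext = ".json")
  write_edit_script(script, tf)
  back <- read_edit_script(tf)
  expect_equal(as.data.frame(back), as.data.frame(script))
})

test_that("block permutation preserves length and content multiset", {
  s <- random_dna(10500, seed = 14)
  p <- permute_blocks(s, 1000, seed = 15)
  expect_equal(length(p), length(s))
  expect_false(identical(p$symbols, s$symbols))
  expect_equal(sort(table(strsplit(p$symbols, "")[[1]])),
               sort(table(strsplit(s$symbols, "")[[1]])))
  expect_identical(permute_blocks(s, 1000, seed = 15)$symbols, p$symbols)
})

test_that("fixtures are written as FASTA plus a truth table", {
  ref <- random_dna(4000, seed = 16)
  out <- apply_edit_script(ref, script_copy(0, 4000, "direct", 0), seed = 1)
  prefix <- file.path(withr::local_tempdir(), "fx")
  paths <- write_fixture(ref, out$target, out$truth, prefix)
  expect_true(all(file.exists(paths)))
  tr <- utils::read.delim(paths[3])
  expect_equal(tr$target_end, 4000L)
  expect_equal(read_fasta(paths[2])$symbols, out$target$symbols)
})
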