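# Mapping tests run on a 200 kb analogue of the study fixture (same block
# structure, scaled 1:5) so the full suite stays fast; the megabase-scale
# experiments live in test-acceptance.R.

test_that("self-comparison recovers one full-length direct pair", {
  y <- random_dna(1e5, seed = 31, name = "self")
  x <- dna_seq(y$symbols, name = "self_copy")
  par <- seg_params(threshold = 1, window = 200, min_block = 5000)
  map <- build_map(y, x, k = 14, params = par, seed = 1)
  g <- glance(map)
  expect_equal(g$n_pairs, 1L)
  expect_equal(g$n_inverted, 0L)
  expect_gt(g$target_coverage, 0.99)
  expect_gt(g$reference_coverage, 0.99)
})

test_that("two unrelated random sequences yield an empty map", {
  y <- random_dna(6e4, seed = 32, name = "y")
  x <- random_dna(6e4, seed = 33, name = "x")
  par <- seg_params(threshold = 1, window = 200, min_block = 5000)
  found <- find_target_regions(y, x, 14, par)
  expect_equal(nrow(found$direct), 0L)
  expect_equal(nrow(found$inverted), 0L)
  map <- build_map(y, x, k = 14, params = par, seed = 1)
  expect_equal(nrow(map$pairs), 0L)
  expect_equal(nrow(tidy(map)), 0L)
})

test_that("a planted reverse-complement block appears only in the inverted list", {
  y <- random_dna(1e5, seed = 34, name = "y")
  script <- dplyr::bind_rows(
    script_novel(30000),
    script_copy(20000, 40000, "inverted", 0),
    script_novel(30000)
  )
  fx <- apply_edit_script(y, script, seed = 35)
  par <- seg_params(threshold = 1, window = 200, min_block = 5000)
  found <- find_target_regions(y, fx$target, 14, par)
  expect_equal(nrow(found$direct), 0L)
  expect_equal(nrow(found$inverted), 1L)
  expect_lt(abs(found$inverted$start - 30000), 2 * par$window)
  expect_lt(abs(found$inverted$end - 70000), 2 * par$window)
})

test_that("the planted fixture is recovered with orientations, breakpoints and an unpaired novel block", {
  fx <- small_planted_fixture()
  map <- small_planted_map()
  par <- study_params(0.2)
  td <- tidy(map)
  copies <- fx$truth[fx$truth$op == "copy", ]
  expect_equal(nrow(map$pairs), nrow(copies))
  for (j in seq_len(nrow(copies))) {
    hit <- td[td$orientation == copies$orientation[j] &
                td$target_start < copies$target_end[j] &
                td$target_end > copies$target_start[j], ]
    expect_equal(nrow(hit), 1L)
    expect_lt(abs(hit$target_start - copies$target_start[j]), 2 * par$window)
    expect_lt(abs(hit$target_end - copies$target_end[j]), 2 * par$window)
    expect_lt(abs(hit$ref_start - copies$ref_start[j]), 2 * par$window)
    expect_lt(abs(hit$ref_end - copies$ref_end[j]), 2 * par$window)
  }
  novel <- fx$truth[fx$truth$op == "novel", ]
  for (j in seq_len(nrow(map$pairs))) {
    expect_lt(interval_overlap(map$pairs$target_start[j], map$pairs$target_end[j],
                               novel$target_start, novel$target_end),
              2 * par$window)
  }
})

test_that("direct/inverted conflicts go to the better-explained strand, unmarked stays out", {
  n <- 200L
  prof_d <- rep(2, n); prof_i <- rep(2, n)
  prof_d[11:120] <- 0.3   # direct claims [10,120)
  prof_i[61:160] <- 0.9   # inverted claims [60,160)
  par <- seg_params(threshold = 1, window = 1, min_block = 10)
  direct <- segment_profile(prof_d, par)
  inverted <- segment_profile(prof_i, par)
  out <- resolve_overlaps(direct, inverted, prof_d, prof_i, par)
  expect_equal(out$orientation, c("direct", "inverted"))
  expect_equal(out$start, c(10L, 120L))
  expect_equal(out$end, c(120L, 160L))
  # disputed [60,120) went direct because 0.3 < 0.9
  # a region in neither list is absent from the output
  expect_true(all(out$end <= 160))

  # no conflict: single-orientation regions pass through unchanged
  solo <- resolve_overlaps(direct,
                           segment_profile(rep(2, n), par),
                           prof_d, rep(2, n), par)
  expect_equal(as.data.frame(solo[, c("start", "end")]),
               data.frame(start = 10L, end = 120L))
})

test_that("localisation recovers the source interval of a verbatim copy", {
  y <- random_dna(1e5, seed = 36, name = "y")
  x <- dna_seq(substr(y$symbols, 20001, 60000), name = "block")
  par <- seg_params(threshold = 1, window = 200, min_block = 5000)
  refs <- locate_in_reference(
    list(start = 0L, end = 40000L, orientation = "direct"), x, y, 14, par
  )
  expect_equal(nrow(refs), 1L)
  expect_gt(reciprocal_overlap(refs$start, refs$end, 20000, 60000), 0.9)

  # reverse-complemented copy localises to the same place when re-complemented
  xi <- dna_seq(reverse_complement(substr(y$symbols, 20001, 60000)), name = "iblock")
  refs_i <- locate_in_reference(
    list(start = 0L, end = 40000L, orientation = "inverted"), xi, y, 14, par
  )
  expect_equal(nrow(refs_i), 1L)
  expect_gt(reciprocal_overlap(refs_i$start, refs_i$end, 20000, 60000), 0.9)

  # a novel region shares nothing and localises nowhere
  xr <- random_dna(40000, seed = 37)
  refs_r <- locate_in_reference(
    list(start = 0L, end = 40000L, orientation = "direct"), xr, y, 14, par
  )
  expect_equal(nrow(refs_r), 0L)
})

test_that("masked (originally non-ACGT) stretches stay out of reported pairs and the fill seed does not matter", {
  y <- random_dna(1e5, seed = 38, name = "y")
  script <- dplyr::bind_rows(
    script_copy(0, 40000, "direct", 0.01),
    script_n_run(20000),
    script_copy(60000, 40000, "inverted", 0.01)
  )
  fx <- apply_edit_script(y, script, seed = 39)
  par <- seg_params(threshold = 1, window = 200, min_block = 5000)
  m1 <- build_map(y, fx$target, k = 14, params = par, seed = 1)
  m2 <- build_map(y, fx$target, k = 14, params = par, seed = 2)
  # the all-N block is never inside a pair beyond min_block
  nrun <- fx$truth[fx$truth$op == "n_run", ]
  for (m in list(m1, m2)) {
    for (j in seq_len(nrow(m$pairs))) {
      expect_lt(interval_overlap(m$pairs$target_start[j], m$pairs$target_end[j],
                                 nrun$target_start, nrun$target_end),
                par$min_block)
    }
  }
  # planted blocks contain no N, so the reported pairs do not depend on the
  # fill seed (boundaries only move within the smoothing resolution, since
  # the random fill differs near the region edges)
  expect_equal(nrow(m1$pairs), nrow(m2$pairs))
  expect_equal(m1$pairs$orientation, m2$pairs$orientation)
  expect_true(all(abs(m1$pairs$target_start - m2$pairs$target_start) <= par$window))
  expect_true(all(abs(m1$pairs$target_end - m2$pairs$target_end) <= par$window))
})

test_that("map parameters and the seed are recorded in the result", {
  map <- small_planted_map()
  expect_equal(map$params$k, 14L)
  expect_equal(map$params$alpha, 0.001)
  expect_equal(map$params$threshold, 1)
  expect_equal(map$params$seed, 1L)
  g <- glance(map)
  expect_equal(g$min_block, map$params$min_block)
  # target regions across pairs never overlap
  p <- map$pairs[order(map$pairs$target_start), ]
  if (nrow(p) > 1) {
    expect_true(all(p$target_start[-1] >= p$target_end[-nrow(p)]))
  }
})

test_that("maps round-trip through JSON byte-identically", {
  map <- small_planted_map()
  tf1 <- withr::local_tempfile(fileext = ".json")
  tf2 <- withr::local_tempfile(fileext = ".json")
  write_map_json(map, tf1)
  back <- read_map_json(tf1)
  expect_equal(back$pairs$target_start, map$pairs$target_start)
  expect_equal(back$params, map$params)
  write_map_json(back, tf2)
  expect_identical(readLines(tf1), readLines(tf2))
})

test_that("BED export carries both sides with strand and full-precision bits", {
  map <- small_planted_map()
  prefix <- file.path(withr::local_tempdir(), "map")
  paths <- write_map_bed(map, prefix)
  tgt <- utils::read.delim(paths[1], header = FALSE)
  ref <- utils::read.delim(paths[2], header = FALSE)
  expect_equal(nrow(tgt), nrow(map$pairs))
  expect_equal(nrow(ref), nrow(tidy(map)))
  expect_true(all(tgt$V6 %in% c("+", "-")))
  expect_equal(sum(tgt$V6 == "-"), sum(map$pairs$orientation == "inverted"))
  expect_equal(tgt$V5, map$pairs$mean_bits, tolerance = 1e-12)
  expect_equal(tgt$V2, map$pairs$target_start)
})
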