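# Seeded fixtures shared across test files. Expensive objects (megabase
# pipeline runs) are built once per test session and cached.

.fx_cache <- new.env(parent = emptyenv())

fx_cached <- function(key, builder) {
  if (!exists(key, envir = .fx_cache)) {
    assign(key, builder(), envir = .fx_cache)
  }
  get(key, envir = .fx_cache)
}

# study-scale planted rearrangement: 1 Mb reference; target = 300 kb direct
# copy + 300 kb inverted copy (1% substitutions each) + 200 kb novel +
# 200 kb direct copy (1%)
planted_script <- function(scale = 1) {
  dplyr::bind_rows(
    script_copy(0, 300000 * scale, "direct", 0.01),
    script_copy(300000 * scale, 300000 * scale, "inverted", 0.01),
    script_novel(200000 * scale),
    script_copy(600000 * scale, 200000 * scale, "direct", 0.01)
  )
}

planted_fixture <- function(scale = 1, ref_seed = 101, script_seed = 7) {
  y <- random_dna(1e6 * scale, seed = ref_seed, name = "ref")
  fx <- apply_edit_script(y, planted_script(scale), seed = script_seed,
                          name = "tgt")
  list(reference = y, target = fx$target, truth = fx$truth)
}

# parameters used for all megabase mapping experiments: default model order,
# threshold 1.0 (identical-species regime), default smoothing and 20 kb
# minimum block. Below full scale the smoothing window shrinks with the
# fixture, so brief substitution-cluster excursions above T are bridged
# with merge_gap = 2 * window instead of relying on a wide window.
study_params <- function(scale = 1) {
  window <- max(1000 * scale, 50)
  seg_params(threshold = 1.0, window = window,
             min_block = max(20000 * scale, 1000),
             merge_gap = if (scale >= 1) 0 else 2 * window)
}

full_planted_fixture <- function() fx_cached("planted_1mb", function() planted_fixture(1))

full_planted_map <- function() {
  fx_cached("planted_1mb_map", function() {
    fx <- full_planted_fixture()
    build_map(fx$reference, fx$target, k = 14, params = study_params(1),
              seed = 1)
  })
}

# reduced-scale analogue for fast unit tests (200 kb, same block structure)
small_planted_fixture <- function() fx_cached("planted_200kb", function() planted_fixture(0.2))

small_planted_map <- function() {
  fx_cached("planted_200kb_map", function() {
    fx <- small_planted_fixture()
    build_map(fx$reference, fx$target, k = 14, params = study_params(0.2),
              seed = 1)
  })
}
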