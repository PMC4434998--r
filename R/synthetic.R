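#' Generate a random DNA sequence
#'
#' Symbols are drawn i.i.d. uniformly from `{A, C, G, T}`; the same
#' `(length, seed)` pair always yields the same sequence. The caller's RNG
#' state is left untouched.
#'
#' @param length number of symbols (`>= 0`).
#' @param seed integer seed.
#' @param name sequence label.
#' @return A [dna_seq()].
#' @export
random_dna <- function(length, seed = 1L, name = "random") {
  if (length(length) != 1L || is.na(length) || length < 0) {
    abort("length must be a single non-negative integer")
  }
  length <- as.integer(length)
  if (length == 0L) return(dna_seq("", name = name))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  dna_seq(ints_to_seq(sample.int(4L, length, replace = TRUE) - 1L), name = name)
}

#' Block operations for building a synthetic rearranged target
#'
#' An edit script is a tibble of block operations, applied in order, each
#' contributing a block to the target:
#' * `script_copy()` copies `length` symbols starting at 0-based `src_start`
#'   of the reference, optionally reverse-complemented (`orientation =
#'   "inverted"`), with i.i.d. point substitutions at `substitution_rate`
#'   (a substituted position receives a uniform draw from the three *other*
#'   nucleotides, so the rate is the expected mismatch fraction).
#' * `script_novel()` emits fresh random sequence unrelated to the
#'   reference.
#' * `script_n_run()` emits a run of `N`s (exercising the non-ACGT
#'   preprocessing downstream).
#'
#' Combine operations with [dplyr::bind_rows()] and apply them with
#' [apply_edit_script()].
#'
#' @param src_start 0-based start of the copied block on the reference.
#' @param length block length in symbols.
#' @param orientation `"direct"` or `"inverted"`.
#' @param substitution_rate expected per-symbol mismatch rate in `[0, 1]`.
#' @return A one-row edit-script tibble.
#' @name edit_script
NULL

#' @rdname edit_script
#' @export
script_copy <- function(src_start, length, orientation = c("direct", "inverted"),
                        substitution_rate = 0) {
  orientation <- match.arg(orientation)
  stopifnot(src_start >= 0, length >= 1,
            substitution_rate >= 0, substitution_rate <= 1)
  tibble(op = "copy", src_start = as.integer(src_start),
         length = as.integer(length), orientation = orientation,
         substitution_rate = substitution_rate)
}

#' @rdname edit_script
#' @export
script_novel <- function(length) {
  stopifnot(length >= 1)
  tibble(op = "novel", src_start = NA_integer_, length = as.integer(length),
         orientation = NA_character_, substitution_rate = NA_real_)
}

#' @rdname edit_script
#' @export
script_n_run <- function(length) {
  stopifnot(length >= 1)
  tibble(op = "n_run", src_start = NA_integer_, length = as.integer(length),
         orientation = NA_character_, substitution_rate = NA_real_)
}

# deterministic per-operation seed stream: adding an operation never
# perturbs the randomness used by earlier blocks
.op_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + index * 7919) %% 2147483629)
}

#' Apply an edit script to a reference, with planted ground truth
#'
#' Assembles a target sequence block by block from an edit script and
#' records, for every block, the exact target interval plus (for copies)
#' the source interval and orientation — the planted truth used to validate
#' rearrangement recovery.
#'
#' @param reference a [dna_seq()] over ACGT.
#' @param script an edit-script tibble (see [script_copy()]).
#' @param seed integer seed; expanded deterministically into independent
#'   per-operation streams.
#' @param name label for the generated target.
#' @return A list with `target` (a [dna_seq()]) and `truth`, a tibble with
#'   one row per block: `op`, `target_start`, `target_end`, `ref_start`,
#'   `ref_end`, `orientation` (`NA` for novel and N blocks).
#' @export
apply_edit_script <- function(reference, script, seed = 1L, name = "synthetic_target") {
  stopifnot(inherits(reference, "dna_seq"))
  required <- c("op", "src_start", "length", "orientation", "substitution_rate")
  if (!all(required %in% names(script))) {
    abort("script must have columns op, src_start, length, orientation, substitution_rate")
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  blocks <- character(nrow(script))
  pos <- 0L
  truth <- vector("list", nrow(script))
  for (j in seq_len(nrow(script))) {
    op <- script$op[j]
    len <- script$length[j]
    if (op == "copy") {
      s0 <- script$src_start[j]
      if (s0 < 0 || s0 + len > reference$length) {
        abort(sprintf("copy source [%d,%d) outside reference [0,%d)",
                      s0, s0 + len, reference$length))
      }
      blk <- substr(reference$symbols, s0 + 1L, s0 + len)
      if (script$orientation[j] == "inverted") blk <- reverse_complement(blk)
      rate <- script$substitution_rate[j]
      if (rate > 0) {
        set.seed(.op_seed(seed, j))
        ints <- seq_to_ints(blk)
        hit <- which(runif(len) < rate)
        if (length(hit)) {
          # uniform draw from the three other symbols
          ints[hit] <- (ints[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
        }
        blk <- ints_to_seq(ints)
      }
      blocks[j] <- blk
      truth[[j]] <- tibble(op = "copy", target_start = pos,
                           target_end = pos + len,
                           ref_start = s0, ref_end = s0 + len,
                           orientation = script$orientation[j])
    } else if (op == "novel") {
      blocks[j] <- random_dna(len, seed = .op_seed(seed, j))$symbols
      truth[[j]] <- tibble(op = "novel", target_start = pos,
                           target_end = pos + len,
                           ref_start = NA_integer_, ref_end = NA_integer_,
                           orientation = NA_character_)
    } else if (op == "n_run") {
      blocks[j] <- strrep("N", len)
      truth[[j]] <- tibble(op = "n_run", target_start = pos,
                           target_end = pos + len,
                           ref_start = NA_integer_, ref_end = NA_integer_,
                           orientation = NA_character_)
    } else {
      abort(sprintf("unknown edit-script operation '%s'", op))
    }
    pos <- pos + len
  }
  list(target = dna_seq(paste(blocks, collapse = ""), name = name),
       truth = bind_rows(truth))
}

#' Permute a sequence in fixed-size blocks
#'
#' Splits the sequence into consecutive blocks of `block_size` (the last
#' block may be shorter) and rearranges them in a seeded random order. Used
#' to emulate an unassembled or misassembled reference.
#'
#' @param seq a [dna_seq()].
#' @param block_size block length in symbols.
#' @param seed integer seed for the permutation.
#' @return A [dna_seq()] of the same length.
#' @export
permute_blocks <- function(seq, block_size, seed = 1L) {
  stopifnot(inherits(seq, "dna_seq"), block_size >= 1)
  n <- seq$length
  starts <- seq.int(0L, n - 1L, by = as.integer(block_size))
  ends <- pmin(starts + as.integer(block_size), n)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  ord <- sample.int(length(starts))
  dna_seq(paste(substring(seq$symbols, starts[ord] + 1L, ends[ord]),
                collapse = ""),
          name = paste0(seq$name, "_permuted"))
}

#' Read/write edit scripts as JSON
#'
#' @param script an edit-script tibble.
#' @param path file path.
#' @return `read_edit_script()` returns the tibble; the writer returns the
#'   path invisibly.
#' @export
write_edit_script <- function(script, path) {
  jsonlite::write_json(script, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_edit_script
#' @export
read_edit_script <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble(op = as.character(df$op),
         src_start = as.integer(df$src_start),
         length = as.integer(df$length),
         orientation = as.character(df$orientation),
         substitution_rate = as.numeric(df$substitution_rate))
}

#' Write a synthetic fixture to disk
#'
#' Writes the reference and target as FASTA plus the planted truth as TSV
#' (`target_start`, `target_end`, `ref_start`, `ref_end`, `orientation`).
#'
#' @param reference,target [dna_seq()] objects.
#' @param truth truth tibble from [apply_edit_script()].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(reference, target, truth, prefix) {
  paths <- paste0(prefix, c(".reference.fa", ".target.fa", ".truth.tsv"))
  write_fasta(reference, paths[1])
  write_fasta(target, paths[2])
  utils::write.table(
    truth[, c("target_start", "target_end", "ref_start", "ref_end", "orientation")],
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}
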