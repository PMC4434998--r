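#' DNA sequence container
#'
#' A lightweight container for a single (possibly concatenated) DNA sequence.
#' All coordinates in the package are 0-based, half-open; `masked_intervals`
#' records where the original input held non-ACGT symbols (N runs, IUPAC
#' ambiguity codes) that have been, or are yet to be, replaced by random
#' nucleotides.
#'
#' @param symbols character scalar, the sequence (uppercase).
#' @param name label for the sequence.
#' @param masked_intervals tibble with 0-based half-open `start`, `end`
#'   columns marking originally non-ACGT stretches.
#' @param boundaries integer vector of internal record boundaries (0-based
#'   offsets) when several FASTA records were concatenated.
#' @return An object of class `dna_seq`.
#' @export
dna_seq <- function(symbols, name = "seq",
                    masked_intervals = tibble(start = integer(), end = integer()),
                    boundaries = integer()) {
  stopifnot(is.character(symbols), length(symbols) == 1L)
  structure(
    list(
      name = name,
      symbols = toupper(symbols),
      length = nchar(symbols),
      masked_intervals = as_tibble(masked_intervals),
      boundaries = as.integer(boundaries)
    ),
    class = "dna_seq"
  )
}

#' @export
length.dna_seq <- function(x) x$length

#' @export
print.dna_seq <- function(x, ...) {
  cat(sprintf("<dna_seq> %s: %s bp", x$name, format(x$length, big.mark = ",")))
  if (nrow(x$masked_intervals) > 0) {
    cat(sprintf(", %d masked interval(s) (%s bp)",
                nrow(x$masked_intervals),
                format(sum(x$masked_intervals$end - x$masked_intervals$start),
                       big.mark = ",")))
  }
  if (length(x$boundaries) > 0) {
    cat(sprintf(", %d record boundary(ies)", length(x$boundaries)))
  }
  cat("\n")
  head_n <- min(60L, x$length)
  if (head_n > 0) {
    cat(substr(x$symbols, 1L, head_n), if (x$length > head_n) "..." else "", "\n")
  }
  invisible(x)
}

#' Read a FASTA file
#'
#' Reads one or more FASTA records. Symbols are uppercased; non-ACGT symbols
#' (N and IUPAC ambiguity codes) are kept as-is and should be randomised with
#' [replace_non_acgt()] before model training.
#'
#' @param path path to a FASTA file.
#' @param concatenate if `TRUE` (default), multiple records are joined in
#'   file order into one sequence, recording the junction offsets in
#'   `boundaries`. If `FALSE`, an error is raised for multi-record input.
#' @return A [dna_seq()].
#' @export
read_fasta <- function(path, concatenate = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty FASTA file: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !startsWith(first, ">")) {
    abort(sprintf("not FASTA (no '>' header on first line): %s", path))
  }
  recs <- Biostrings::readDNAStringSet(path)
  if (length(recs) == 0) abort(sprintf("no records in FASTA file: %s", path))
  nm <- sub("\\s.*$", "", names(recs)[1])
  if (length(recs) == 1L) {
    return(dna_seq(as.character(recs[[1]]), name = nm))
  }
  if (!concatenate) {
    abort(sprintf("%d records in %s; set concatenate = TRUE to join them", length(recs), path))
  }
  lens <- Biostrings::width(recs)
  dna_seq(paste(as.character(recs), collapse = ""),
          name = nm,
          boundaries = cumsum(lens)[-length(lens)])
}

#' Write a sequence as FASTA
#'
#' @param seq a [dna_seq()].
#' @param path output path; lines are wrapped at 60 columns.
#' @export
write_fasta <- function(seq, path) {
  stopifnot(inherits(seq, "dna_seq"))
  x <- Biostrings::BStringSet(seq$symbols)
  names(x) <- seq$name
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Replace non-ACGT symbols by uniformly random nucleotides
#'
#' Positions outside `{A,C,G,T}` carry no usable sequence information; they
#' are substituted by symbols drawn uniformly from the four nucleotides so
#' that they form high-information (incompressible) stretches that cannot
#' share information with any other sequence, while the original length is
#' preserved. Lowercase input is uppercased first. The replaced stretches are
#' recorded in `masked_intervals`.
#'
#' @param seq a [dna_seq()] or character scalar.
#' @param seed integer seed controlling the random fill (default 1); the same
#'   `(sequence, seed)` pair always produces the same output.
#' @return A [dna_seq()] whose symbols are all in `{A,C,G,T}`.
#' @export
replace_non_acgt <- function(seq, seed = 1L) {
  if (is.character(seq)) seq <- dna_seq(seq)
  stopifnot(inherits(seq, "dna_seq"))
  s <- toupper(seq$symbols)
  bytes <- utf8ToInt(s)
  bad <- is.na(.byte_lut[bytes])
  if (!any(bad)) {
    return(dna_seq(s, name = seq$name,
                   masked_intervals = tibble(start = integer(), end = integer()),
                   boundaries = seq$boundaries))
  }
  n_bad <- sum(bad)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  bytes[bad] <- utf8ToInt("ACGT")[sample.int(4L, n_bad, replace = TRUE)]
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  dna_seq(intToUtf8(bytes), name = seq$name,
          masked_intervals = tibble(start = as.integer(starts[r$values]),
                                    end = as.integer(ends[r$values])),
          boundaries = seq$boundaries)
}

#' Reverse complement
#'
#' Returns the opposite-strand sequence: reversed, with A<->T and C<->G
#' swapped. Masked intervals and record boundaries are mirrored to the new
#' coordinate system. Applying it twice is the identity.
#'
#' @param seq a [dna_seq()] or character scalar over ACGT.
#' @return Same type as the input.
#' @export
reverse_complement <- function(seq) {
  if (is.character(seq)) {
    return(as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq))))
  }
  stopifnot(inherits(seq, "dna_seq"))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq$symbols)))
  n <- seq$length
  mi <- seq$masked_intervals
  if (nrow(mi) > 0) {
    mi <- tibble(start = n - rev(mi$end), end = n - rev(mi$start))
  }
  dna_seq(rc, name = seq$name,
          masked_intervals = mi,
          boundaries = if (length(seq$boundaries)) sort(n - seq$boundaries) else integer())
}

# Preserve the caller's RNG state across internal seeded draws.
.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
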