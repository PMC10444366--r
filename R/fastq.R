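#' Count guides in a FASTQ file by exact sequence match
#'
#' Assigns each read to the unique guide whose protospacer sequence occurs
#' as an exact forward-strand substring of the read. Reads matching no
#' guide are counted unassigned; reads containing the sequences of two or
#' more distinct guides are counted ambiguous and discarded. This is a
#' deterministic counter for amplicon-style screen sequencing, not an
#' aligner: no mismatches, no reverse complement.
#'
#' @param fastq Path to a FASTQ file (4-line records; qualities ignored).
#' @param library A \code{guide_library} with a \code{sequence} column.
#' @return A list with \code{counts} (named integer vector, one entry per
#'   library guide, in library order) and \code{stats} (named integer
#'   vector: \code{assigned}, \code{unassigned}, \code{ambiguous},
#'   \code{total}; the first three always sum to \code{total}).
#' @export
count_guides_from_fastq <- function(fastq, library) {
  if (is.null(library$sequence)) {
    stop("guide library has no sequences; cannot count reads", call. = FALSE)
  }
  lines <- readLines(fastq)
  if (length(lines) == 0L) {
    reads <- character(0)
  } else {
    if (length(lines) %% 4L != 0L) {
      stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4 (record %d truncated)",
                   length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
    }
    hdr <- lines[seq(1L, length(lines), by = 4L)]
    plus <- lines[seq(3L, length(lines), by = 4L)]
    bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
    if (length(bad) > 0L) {
      stop(sprintf("malformed FASTQ record at index %d", bad[1L]),
           call. = FALSE)
    }
    reads <- lines[seq(2L, length(lines), by = 4L)]
  }
  n_guides <- nrow(library)
  counts <- stats::setNames(integer(n_guides), library$guide_id)
  stats <- c(assigned = 0L, unassigned = 0L, ambiguous = 0L,
             total = length(reads))
  if (length(reads) > 0L) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(library$sequence))
    hits <- Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(toupper(reads)))
    matched <- hits > 0L                       # guides x reads
    n_match <- colSums(matched)
    stats[["unassigned"]] <- sum(n_match == 0L)
    stats[["ambiguous"]] <- sum(n_match >= 2L)
    stats[["assigned"]] <- sum(n_match == 1L)
    ok <- which(n_match == 1L)
    if (length(ok) > 0L) {
      idx <- apply(matched[, ok, drop = FALSE], 2L, which.max)
      tab <- tabulate(idx, nbins = n_guides)
      counts <- counts + as.integer(tab)
    }
  }
  list(counts = counts, stats = stats)
}
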