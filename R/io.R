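#' Read a raw sgRNA read-count table
#'
#' Parses a tab-separated count table with guide identifiers in the first
#' column and one column of raw integer read counts per sequenced sample.
#' Lines starting with \code{#} are ignored.
#'
#' @param path Path to a tab-separated file. The first column holds guide
#'   ids, the header row holds sample ids.
#' @return An integer matrix (guides x samples) with guide ids as rownames
#'   and sample ids as colnames, in file order.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("guide_id\ts1\ts2", "g1\t10\t20", "g2\t5\t8"), tf)
#' read_count_table(tf)
#' @export
read_count_table <- function(path) {
  df <- read_tsv_checked(path, what = "count table")
  if (ncol(df) < 2L) {
    stop("count table must have at least one sample column", call. = FALSE)
  }
  guides <- as.character(df[[1L]])
  dup <- unique(guides[duplicated(guides)])
  if (length(dup) > 0L) {
    stop("duplicated guide id(s) in count table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  samples <- colnames(df)[-1L]
  counts <- matrix(NA_integer_, nrow = length(guides), ncol = length(samples),
                   dimnames = list(guides, samples))
  for (j in seq_along(samples)) {
    raw <- as.character(df[[j + 1L]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.finite(val) | val < 0 | val != round(val))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-integer or negative count at guide '%s', sample '%s' (value '%s')",
        guides[bad[1L]], samples[j], raw[bad[1L]]), call. = FALSE)
    }
    counts[, j] <- as.integer(val)
  }
  counts
}

#' Read a guide-library configuration table
#'
#' The library configuration maps every guide to its target gene and,
#' optionally, carries the guide protospacer sequence used for exact-match
#' FASTQ counting.
#'
#' @param path Path to a tab-separated file with columns \code{guide_id},
#'   \code{gene_id} and, optionally, \code{sequence}.
#' @return A data frame of class \code{guide_library} with columns
#'   \code{guide_id}, \code{gene_id} and (if present in the file)
#'   \code{sequence}, validated: unique guide ids, one gene per guide,
#'   sequences uppercase A/C/G/T of uniform length.
#' @export
read_library_config <- function(path) {
  df <- read_tsv_checked(path, what = "library configuration")
  need <- c("guide_id", "gene_id")
  if (!all(need %in% colnames(df))) {
    stop("library configuration must have columns 'guide_id' and 'gene_id'",
         call. = FALSE)
  }
  lib <- data.frame(guide_id = as.character(df$guide_id),
                    gene_id = as.character(df$gene_id),
                    stringsAsFactors = FALSE)
  if ("sequence" %in% colnames(df)) {
    lib$sequence <- toupper(as.character(df$sequence))
  }
  validate_guide_library(lib)
}

#' Construct and validate a guide library
#'
#' @param lib A data frame with columns \code{guide_id}, \code{gene_id} and
#'   optional \code{sequence}.
#' @return The validated data frame with class \code{guide_library}.
#' @export
validate_guide_library <- function(lib) {
  dup <- unique(lib$guide_id[duplicated(lib$guide_id)])
  if (length(dup) > 0L) {
    stop("guide id(s) mapped more than once (possibly to two genes): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(lib$guide_id)) || any(is.na(lib$gene_id)) ||
      any(lib$guide_id == "") || any(lib$gene_id == "")) {
    stop("guide_id and gene_id must be non-missing", call. = FALSE)
  }
  if (!is.null(lib$sequence)) {
    bad <- grepl("[^ACGT]", lib$sequence)
    if (any(bad)) {
      stop("malformed guide sequence (non-ACGT) for guide(s): ",
           paste(lib$guide_id[bad][seq_len(min(5, sum(bad)))], collapse = ", "),
           call. = FALSE)
    }
    if (length(unique(nchar(lib$sequence))) > 1L) {
      stop("guide sequences must have uniform length", call. = FALSE)
    }
  }
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Read a sample sheet
#'
#' The sample sheet describes every sequenced sample of the screen: which
#' genotype context it came from (\code{control} or \code{mutant}), the
#' passage timepoint in days, and the replicate label.
#'
#' @param path Path to a tab-separated file with columns \code{sample_id},
#'   \code{context}, \code{timepoint_days}, \code{replicate}.
#' @return A data frame of class \code{sample_sheet}. If some context has
#'   no timepoint-0 sample a warning is raised and the attribute
#'   \code{missing_t0} lists the affected contexts (scoring against T0
#'   will fail later for those contexts).
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv_checked(path, what = "sample sheet")
  need <- c("sample_id", "context", "timepoint_days", "replicate")
  if (!all(need %in% colnames(df))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  sheet <- data.frame(sample_id = as.character(df$sample_id),
                      context = as.character(df$context),
                      timepoint_days = as.integer(df$timepoint_days),
                      replicate = as.character(df$replicate),
                      stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet
#'
#' @param sheet A data frame with columns \code{sample_id}, \code{context},
#'   \code{timepoint_days}, \code{replicate}.
#' @return The validated data frame with class \code{sample_sheet}.
#' @export
validate_sample_sheet <- function(sheet) {
  if (!all(sheet$context %in% c("control", "mutant"))) {
    stop("context must be 'control' or 'mutant'", call. = FALSE)
  }
  if (any(is.na(sheet$timepoint_days)) || any(sheet$timepoint_days < 0L)) {
    stop("timepoint_days must be nonnegative integers", call. = FALSE)
  }
  dup <- unique(sheet$sample_id[duplicated(sheet$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicated sample id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(sheet$context, sheet$timepoint_days, sheet$replicate, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicated (context, timepoint, replicate) triple(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  no_t0 <- setdiff(unique(sheet$context),
                   unique(sheet$context[sheet$timepoint_days == 0L]))
  if (length(no_t0) > 0L) {
    warning("no timepoint-0 sample for context(s): ",
            paste(no_t0, collapse = ", "),
            "; these contexts cannot be scored against T0", call. = FALSE)
    attr(sheet, "missing_t0") <- no_t0
  }
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a one-gene-per-line essential-gene standard
#'
#' @param path Path to a plain-text file, one gene id per line; \code{#}
#'   comments and blank lines are ignored.
#' @return Character vector of unique gene ids.
#' @export
read_essential_genes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty essential-gene list", call. = FALSE)
  unique(lines)
}

#' Read a gene-set annotation table
#'
#' @param path Path to a tab-separated file with columns \code{term_id},
#'   \code{gene_id} and optional \code{term_name}.
#' @return A data frame with one row per (term, gene) pair.
#' @export
read_annotations <- function(path) {
  df <- read_tsv_checked(path, what = "annotation table")
  need <- c("term_id", "gene_id")
  if (!all(need %in% colnames(df))) {
    stop("annotation table must have columns 'term_id' and 'gene_id'",
         call. = FALSE)
  }
  out <- data.frame(term_id = as.character(df$term_id),
                    gene_id = as.character(df$gene_id),
                    stringsAsFactors = FALSE)
  if ("term_name" %in% colnames(df)) {
    out$term_name <- as.character(df$term_name)
  }
  out
}

#' Write a result table deterministically
#'
#' Writes any result data frame (fitness table, GI results, gene-set
#' results) as tab-separated text with a fixed column order and stable
#' float formatting (scientific notation, 9 significant digits), so two
#' writes of the same table are byte-identical and a re-read reproduces the
#' values to formatting precision.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_results <- function(x, path) {
  if (!is.data.frame(x)) stop("x must be a data frame", call. = FALSE)
  out <- x
  for (j in seq_along(out)) {
    col <- out[[j]]
    if (is.double(col)) {
      fmt <- sprintf("%.8e", col)
      fmt[is.na(col)] <- "NA"
      out[[j]] <- fmt
    } else if (is.factor(col)) {
      out[[j]] <- as.character(col)
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     na = "NA")
  invisible(path)
}

#' Write an integer count matrix as TSV
#'
#' @param counts Integer matrix with guide rownames and sample colnames.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(guide_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# Shared TSV reader: tab-separated, UTF-8, '#' comments ignored,
# header preserved verbatim. Errors on empty files.
read_tsv_checked <- function(path, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", quote = ""),
    error = function(e) {
      stop(sprintf("cannot parse %s '%s': %s", what, path, conditionMessage(e)),
           call. = FALSE)
    })
  if (nrow(df) == 0L) {
    stop(sprintf("empty %s: %s", what, path), call. = FALSE)
  }
  df
}
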