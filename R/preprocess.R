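#' Trim the 3' adapter from reads
#'
#' 3'-anchored adapter removal: for each read, finds the best (longest) suffix
#' matching a prefix of `adapter3` with mismatch rate at most
#' `max_error_rate` and overlap at least `min_overlap`, and keeps the read
#' prefix before it. Reads with no adapter-like suffix are returned untrimmed
#' and flagged, so downstream filters decide their fate; empty reads are
#' rejected.
#'
#' @param reads Character vector of read sequences, or a tibble with a `seq`
#'   column (e.g. from [read_fastq_tbl()]).
#' @param adapter3 3' adapter sequence (DNA space).
#' @param min_overlap Minimum suffix/prefix overlap (>= 3).
#' @param max_error_rate Maximum mismatch fraction within the overlap,
#'   in `[0, 0.5)`.
#' @return Tibble with columns `read_id` (if given), `insert`, `trimmed`
#'   (logical), `rejected` (logical, empty reads), `reason`.
#' @examples
#' trim_adapter("GGGGGGGGGGGGGGGGGGGGGGTGGAATTCTCGGGTGCCAAGG")
#' @export
trim_adapter <- function(reads, adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                         min_overlap = 3, max_error_rate = 0.1) {
  if (min_overlap < 3) stop("min_overlap must be >= 3")
  if (max_error_rate < 0 || max_error_rate >= 0.5)
    stop("max_error_rate must be in [0, 0.5)")
  ids <- NULL
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    reads <- reads$seq
  }
  reads <- dna_space(reads)
  empty <- !nzchar(reads) | is.na(reads)
  res <- cpp_trim_adapter(ifelse(empty, "A", reads), dna_space(adapter3),
                          as.integer(min_overlap), max_error_rate)
  insert <- substr(reads, 1, res$insert_length)
  out <- tibble::tibble(
    insert = ifelse(empty, NA_character_, insert),
    trimmed = res$trimmed & !empty,
    rejected = empty,
    reason = ifelse(empty, "empty read",
                    ifelse(res$trimmed, NA_character_, "no adapter match"))
  )
  if (!is.null(ids)) out <- dplyr::bind_cols(tibble::tibble(read_id = ids), out)
  out
}

#' Filter inserts by length
#'
#' Keeps inserts with length in `[min_len, max_len]` (bounds inclusive:
#' the discard rule is strictly shorter-than / longer-than). Discard counts
#' are attached as the `"discards"` attribute.
#'
#' @param inserts Character vector of insert sequences, or a tibble with an
#'   `insert` column.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @return The retained inserts (same shape as the input), with attribute
#'   `discards = c(short = , long = )`.
#' @export
length_filter <- function(inserts, min_len = 15, max_len = 80) {
  seqs <- if (is.data.frame(inserts)) inserts$insert else inserts
  len <- nchar(seqs)
  keep <- !is.na(seqs) & len >= min_len & len <= max_len
  short <- sum(!is.na(seqs) & len < min_len)
  long <- sum(!is.na(seqs) & len > max_len)
  out <- if (is.data.frame(inserts)) inserts[keep, ] else inserts[keep]
  attr(out, "discards") <- c(short = short, long = long,
                             na = sum(is.na(seqs)))
  out
}

#' Remove contaminant-derived inserts
#'
#' Removes any insert that occurs as an exact substring of a contaminant
#' sequence or of its reverse complement. This replaces genome alignment with
#' a deterministic contaminant-list filter: adequate for rRNA-like carryover
#' at desk scale, and exactly reproducible.
#'
#' @param inserts Character vector or tibble with an `insert` column.
#' @param contaminants Tibble `name`,`seq` (lengths unrestricted), or a
#'   character vector of sequences.
#' @return Retained inserts (same shape as input), with attribute
#'   `removed` = number of contaminant-matched inserts.
#' @export
contaminant_filter <- function(inserts, contaminants) {
  seqs <- if (is.data.frame(inserts)) inserts$insert else inserts
  cseq <- if (is.data.frame(contaminants)) contaminants$seq else contaminants
  cseq <- dna_space(cseq)
  if (length(cseq) == 0 || length(seqs) == 0) {
    out <- inserts
    attr(out, "removed") <- 0L
    return(out)
  }
  haystack <- paste(c(cseq, rc(cseq)), collapse = "#")
  uniq <- unique(seqs)
  is_cont <- vapply(uniq, function(s) grepl(s, haystack, fixed = TRUE),
                    logical(1))
  drop <- seqs %in% uniq[is_cont]
  out <- if (is.data.frame(inserts)) inserts[!drop, ] else inserts[!drop]
  attr(out, "removed") <- sum(drop)
  out
}

#' Collapse inserts to a unique-sequence count table
#'
#' @param inserts Character vector of inserts (one element per read), or a
#'   tibble with an `insert` column.
#' @return Tibble `insert`, `count`, `fraction` (of the reads given), sorted
#'   by decreasing count.
#' @export
collapse_inserts <- function(inserts) {
  seqs <- if (is.data.frame(inserts)) inserts$insert else inserts
  if (length(seqs) == 0) {
    return(tibble::tibble(insert = character(), count = integer(),
                          fraction = numeric()))
  }
  tibble::tibble(insert = seqs) |>
    dplyr::count(.data$insert, name = "count") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$insert)
}

#' Select highly enriched species
#'
#' Retains unique inserts whose fraction of total post-length-filter reads is
#' strictly greater than `threshold` (default 0.1%). The removed read mass is
#' attached as the `"removed_mass"` attribute so fractions remain accountable.
#'
#' @param table Insert count table from [collapse_inserts()].
#' @param threshold Strict lower bound on the read fraction.
#' @return The enriched rows of `table` (fractions kept on the original
#'   denominator), with attributes `removed_mass` (fraction) and
#'   `removed_species` (count).
#' @export
abundance_filter <- function(table, threshold = 0.001) {
  if (nrow(table) == 0) stop("abundance_filter: empty insert table")
  keep <- table$fraction > threshold
  out <- table[keep, ]
  attr(out, "removed_mass") <- sum(table$fraction[!keep])
  attr(out, "removed_species") <- sum(!keep)
  out
}

#' Preprocess a small-RNA library to an insert count table
#'
#' Runs the full preprocessing chain: adapter trimming, inclusive 15--80 nt
#' length filtering, contaminant removal, collapsing to unique inserts, and
#' the strict >0.1% enrichment filter. Per-stage read counts are attached so
#' conservation (`reads_in = retained + short + long + contaminant`) is
#' auditable; retrieve them with [preprocess_stats()].
#'
#' @param reads A reads tibble ([read_fastq_tbl()]), a `mimic_sim`, or a path
#'   to a FASTQ file.
#' @param adapter3,min_overlap,max_error_rate Adapter trimming parameters
#'   (see [trim_adapter()]).
#' @param min_len,max_len Length filter bounds, inclusive.
#' @param contaminants Optional contaminant tibble/vector.
#' @param min_frac Enrichment threshold (strict) applied per unique insert;
#'   set to `NULL` to skip.
#' @return An insert table tibble (`insert`, `count`, `fraction`) of enriched
#'   species, with a `"stats"` attribute; `fraction` is relative to all reads
#'   that survived length + contaminant filtering.
#' @export
preprocess_fastq <- function(reads, adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                             min_overlap = 3, max_error_rate = 0.1,
                             min_len = 15, max_len = 80,
                             contaminants = NULL, min_frac = 0.001) {
  if (inherits(reads, "mimic_sim")) reads <- reads$reads
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- read_fastq_tbl(reads)
  n_in <- nrow(reads)
  tr <- trim_adapter(reads, adapter3, min_overlap, max_error_rate)
  lf <- length_filter(tr[!tr$rejected, ], min_len, max_len)
  disc <- attr(lf, "discards")
  if (is.null(contaminants)) {
    contaminants <- tibble::tibble(name = character(), seq = character())
  }
  cf <- contaminant_filter(lf, contaminants)
  n_cont <- attr(cf, "removed")
  tab <- collapse_inserts(cf)
  stats <- tibble::tibble(
    reads_in = n_in,
    rejected_empty = sum(tr$rejected),
    adapterless = sum(!tr$trimmed & !tr$rejected),
    discarded_short = unname(disc["short"]),
    discarded_long = unname(disc["long"]),
    contaminant = n_cont,
    retained = nrow(cf)
  )
  out <- if (!is.null(min_frac)) abundance_filter(tab, min_frac) else tab
  attr(out, "stats") <- stats
  attr(out, "full_table") <- tab
  class(out) <- c("insert_table", class(out))
  out
}

#' Per-stage read accounting of a preprocessed library
#'
#' @param x An insert table from [preprocess_fastq()].
#' @return One-row tibble of per-stage read counts.
#' @export
preprocess_stats <- function(x) attr(x, "stats")

#' Write an insert table as TSV
#'
#' @param x Insert table tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_insert_table <- function(x, path) {
  write.table(as.data.frame(x)[, c("insert", "count", "fraction")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
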