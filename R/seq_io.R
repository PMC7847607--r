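#' Read transcript or promoter sequences from FASTA
#'
#' Sequences are uppercased and any U is converted to T so that all
#' downstream matching happens in a single DNA alphabet; records that
#' contained U are flagged so they can be displayed as RNA again.
#' Coordinates throughout the package are 1-based and fully closed.
#'
#' @param path Path to a (multi-record) FASTA file, wrapped or unwrapped.
#' @param kind Sequence kind, `"transcript"` or `"promoter"`.
#' @return A data.frame with columns `id`, `sequence` (DNA, uppercase),
#'   `kind`, `length` and `rna` (logical display flag).
#' @export
read_fasta <- function(path, kind = c("transcript", "promoter")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seq_records(names(set), as.character(set), kind = kind)
}

#' Build a sequence-record collection from character vectors
#'
#' @param ids Record identifiers (must be unique and non-empty).
#' @param sequences Nucleotide strings over A/C/G/T or A/C/G/U.
#' @param kind `"transcript"` or `"promoter"`.
#' @return A data.frame of sequence records (see [read_fasta()]).
#' @export
seq_records <- function(ids, sequences, kind = c("transcript", "promoter")) {
  kind <- match.arg(kind)
  ids <- sub("\\s.*$", "", as.character(ids))  # FASTA description after first token dropped
  if (any(is.na(ids) | ids == "")) {
    stop("malformed FASTA header: empty record id", call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  raw <- toupper(as.character(sequences))
  if (any(nchar(raw) == 0)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(raw) == 0], collapse = ", "), call. = FALSE)
  }
  is_rna <- grepl("U", raw, fixed = TRUE)
  seqs <- to_dna(raw)
  assert_dna(seqs, "FASTA sequence")
  data.frame(id = ids, sequence = seqs, kind = kind,
             length = nchar(seqs), rna = is_rna,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' Records flagged as RNA are written back in the RNA alphabet.
#'
#' @param records A sequence-record data.frame (see [seq_records()]).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  out <- ifelse(records$rna, to_rna(records$sequence), records$sequence)
  set <- Biostrings::BStringSet(out)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a collapsed small-RNA (or degradome tag) library
#'
#' Two dialects are supported: collapsed FASTA, where every header ends in
#' `_<count>`, and two-column TSV with a `sequence`/`count` header. Reads
#' outside the accepted length window are kept in the library total (RPM is
#' computed against the whole, pre-filter library) but flagged `excluded`
#' so they are ignored by the analysis stages.
#'
#' @param path Input path.
#' @param format `"auto"` (default, by extension/content), `"collapsed_fasta"`
#'   or `"tsv"`.
#' @param name Library name; defaults to the file name.
#' @param min_len,max_len Accepted read-length window in nt.
#' @return An object of class `srna_library`: a list with `name`,
#'   `total_count` and a `reads` data.frame (`sequence`, `length`, `count`,
#'   `rpm`, `excluded`).
#' @export
read_srna_library <- function(path, format = c("auto", "collapsed_fasta", "tsv"),
                              name = NULL, min_len = 15, max_len = 30) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  name <- name %||% basename(path)
  if (format == "auto") {
    first <- readLines(path, n = 1)
    format <- if (startsWith(first, ">")) "collapsed_fasta" else "tsv"
  }
  if (format == "collapsed_fasta") {
    set <- Biostrings::readBStringSet(path)
    hdr <- names(set)
    counts <- suppressWarnings(as.integer(sub("^.*_", "", hdr)))
    bad <- which(is.na(counts) | !grepl("_[0-9]+$", hdr))
    if (length(bad)) {
      stop("collapsed FASTA header without trailing _<count>: ",
           paste(utils::head(hdr[bad], 3), collapse = ", "), call. = FALSE)
    }
    seqs <- as.character(set)
  } else {
    tab <- utils::read.delim(path, header = TRUE, colClasses = "character",
                             stringsAsFactors = FALSE)
    need <- c("sequence", "count")
    if (!all(need %in% names(tab))) {
      stop("TSV library must have columns 'sequence' and 'count'", call. = FALSE)
    }
    counts <- suppressWarnings(as.numeric(tab$count))
    bad <- which(is.na(counts) | counts != floor(counts) | counts < 0)
    if (length(bad)) {
      stop("non-integer count at line ", bad[1] + 1L, " of ", path, call. = FALSE)
    }
    counts <- as.integer(counts)
    seqs <- tab$sequence
  }
  srna_library(seqs, counts, name = name, min_len = min_len, max_len = max_len)
}

#' Construct a small-RNA library from sequences and counts
#'
#' Duplicate sequences are collapsed by summing counts. `total_count` is
#' fixed at construction (the pre-filter library size) and is the RPM
#' denominator for [normalize_rpm()].
#'
#' @inheritParams read_srna_library
#' @param sequences Read sequences (DNA or RNA alphabet).
#' @param counts Non-negative integer read counts, one per sequence.
#' @return An `srna_library` object.
#' @export
srna_library <- function(sequences, counts, name = "library",
                         min_len = 15, max_len = 30) {
  stopifnot(length(sequences) == length(counts))
  seqs <- to_dna(sequences)
  if (length(seqs)) assert_dna(seqs, "read sequence")
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("negative read count", call. = FALSE)
  if (anyDuplicated(seqs)) {
    agg <- rowsum(counts, seqs)
    seqs <- rownames(agg)
    counts <- as.integer(agg[, 1])
  }
  len <- nchar(seqs)
  reads <- data.frame(sequence = seqs, length = len, count = counts,
                      rpm = rep(NA_real_, length(seqs)),
                      excluded = len < min_len | len > max_len,
                      stringsAsFactors = FALSE)
  structure(list(name = name, total_count = sum(counts), reads = reads),
            class = "srna_library")
}

#' Normalize a library to reads per million
#'
#' Every read's RPM is `count * 1e6 / total_count`, where `total_count` is
#' the library total before any length filtering. Counts are unchanged.
#'
#' @param library An `srna_library`.
#' @return The library with the `rpm` column filled in.
#' @export
normalize_rpm <- function(library) {
  stopifnot(inherits(library, "srna_library"))
  if (library$total_count <= 0) stop("empty library: total_count is 0", call. = FALSE)
  library$reads$rpm <- library$reads$count * 1e6 / library$total_count
  library
}

#' Write a small-RNA library as TSV
#'
#' @param library An `srna_library`.
#' @param path Output path; a `sequence`/`count` TSV with a header row.
#' @export
write_srna_library <- function(library, path) {
  utils::write.table(library$reads[, c("sequence", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.srna_library <- function(x, ...) {
  cat(sprintf("srna_library '%s': %d unique reads, total_count %d (%d excluded by length)\n",
              x$name, nrow(x$reads), x$total_count, sum(x$reads$excluded)))
  invisible(x)
}

# reads retained for analysis (inside the length window), normalized
analysis_reads <- function(library) {
  if (all(is.na(library$reads$rpm))) library <- normalize_rpm(library)
  library$reads[!library$reads$excluded, , drop = FALSE]
}
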