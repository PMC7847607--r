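# Internal sequence helpers. All matching is done in the DNA alphabet;
# RNA input (U) is normalized to T on the way in and restored for display.

to_dna <- function(x) chartr("U", "T", toupper(x))

to_rna <- function(x) chartr("T", "U", toupper(x))

revcomp <- function(x) {
  comp <- chartr("ACGTU", "TGCAA", toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

assert_dna <- function(x, what = "sequence") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside A/C/G/T (after U->T): %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

# All start positions (1-based) of exact, possibly overlapping, occurrences
# of `query` in `subject`. DNA alphabet only, so no regex metacharacters.
find_all <- function(subject, query) {
  if (nchar(query) == 0 || nchar(query) > nchar(subject)) return(integer(0))
  m <- gregexpr(paste0("(?=", query, ")"), subject, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_df <- function(...) {
  cols <- list(...)
  structure(as.data.frame(cols, stringsAsFactors = FALSE), row.names = integer(0))
}
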