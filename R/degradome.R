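#' Build a per-position degradome 5'-tag profile (T-plot data)
#'
#' Degradome/PARE tags are 5' fragments of cleaved mRNAs, so they are
#' matched on the sense strand only; each exact match contributes the
#' tag's RPM at its 5' coordinate (the match start). Distinct tags whose
#' 5' ends coincide are summed.
#'
#' @param degradome A normalized `srna_library` of degradome tags.
#' @param transcript A single sequence record (one row).
#' @return An object of class `degradome_profile`: list with
#'   `transcript_id`, `library_name`, `length` and a `signal` data.frame
#'   (`position`, `rpm`) holding only non-zero positions.
#' @export
build_profile <- function(degradome, transcript) {
  tags <- analysis_reads(degradome)
  pos <- integer(0); rpm <- numeric(0)
  tx <- transcript$sequence[1]
  for (r in seq_len(nrow(tags))) {
    hits <- find_all(tx, tags$sequence[r])
    if (length(hits)) {
      pos <- c(pos, hits)
      rpm <- c(rpm, rep(tags$rpm[r], length(hits)))
    }
  }
  if (length(pos)) {
    agg <- rowsum(rpm, pos)
    signal <- data.frame(position = as.integer(rownames(agg)), rpm = agg[, 1])
    signal <- signal[order(signal$position), , drop = FALSE]
    rownames(signal) <- NULL
  } else {
    signal <- empty_df(position = integer(), rpm = numeric())
  }
  structure(list(transcript_id = transcript$id[1],
                 library_name = degradome$name,
                 length = transcript$length[1], signal = signal),
            class = "degradome_profile")
}

#' @export
print.degradome_profile <- function(x, ...) {
  cat(sprintf("degradome_profile: %s on %s, %d positions with signal\n",
              x$library_name, x$transcript_id, nrow(x$signal)))
  invisible(x)
}

#' Detect dominant cleavage signals in a degradome profile
#'
#' A position is called a cleavage signal when its RPM reaches `min_rpm`
#' and dominates its local background: dominance = rpm / max(highest RPM
#' at any other position within +/- `flank` nt, `eps`).
#'
#' @param profile A `degradome_profile`.
#' @param window Optional 1-based closed interval `c(lo, hi)` restricting
#'   the scan; `NULL` scans the whole transcript.
#' @param min_rpm Minimum signal RPM (default 1).
#' @param min_dominance Minimum dominance ratio (default 2).
#' @param flank Background half-window in nt (default 50).
#' @param eps Background floor in RPM (default 0.1).
#' @return A data.frame of signals (`position`, `rpm`, `dominance`,
#'   `library_name`), sorted by RPM descending, ties by position.
#' @export
detect_cleavage <- function(profile, window = NULL, min_rpm = 1,
                            min_dominance = 2, flank = 50, eps = 0.1) {
  sig <- profile$signal
  empty <- empty_df(position = integer(), rpm = numeric(),
                    dominance = numeric(), library_name = character())
  if (!nrow(sig)) return(empty)
  cand <- sig
  if (!is.null(window)) {
    cand <- cand[cand$position >= window[1] & cand$position <= window[2], , drop = FALSE]
  }
  cand <- cand[cand$rpm >= min_rpm, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  bg <- vapply(cand$position, function(p) {
    near <- sig$rpm[sig$position != p & abs(sig$position - p) <= flank]
    max(c(near, 0))
  }, numeric(1))
  dom <- cand$rpm / pmax(bg, eps)
  keep <- dom >= min_dominance
  res <- data.frame(position = cand$position[keep], rpm = cand$rpm[keep],
                    dominance = dom[keep],
                    library_name = rep(profile$library_name, sum(keep)),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$rpm, res$position), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Is a cleavage signal at a candidate region's flank?
#'
#' True when the signal sits within `tolerance` nt of the region start, or
#' is register-concordant (congruent to the region anchor mod k) — i.e.
#' it could be the primary register-setting cleavage for the phasing
#' process.
#'
#' @param position Signal position(s), 1-based.
#' @param region One candidate-region row (see [find_candidate_regions()]).
#' @param tolerance Distance tolerance in nt (default 2).
#' @return Logical vector.
#' @export
flank_check <- function(position, region, tolerance = 2) {
  near <- abs(position - region$region_start[1]) <= tolerance
  on_register <- (position - region$anchor[1]) %% region$k[1] == 0
  near | on_register
}
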