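#' Phasing score of a five-register window
#'
#' The statistic contrasts in-phase read abundance with out-of-phase
#' complexity inside a window of five consecutive phase registers:
#'
#'   score = (n - 2) * ln(1 + 10 * p_sum / (1 + u_sum))
#'
#' where `n` is the number of the five registers occupied by at least one
#' unique k-nt read in phase, `p_sum` the total read count of all in-phase
#' k-nt reads in the window, and `u_sum` the number of unique out-of-phase
#' k-nt reads in the window. With fewer than three occupied registers the
#' score is zero or negative and the window cannot pass the locus filter.
#'
#' @param n Occupied registers, 0-5 (vectorized).
#' @param p_sum Total in-phase read count (>= 0).
#' @param u_sum Unique out-of-phase read count (>= 0).
#' @return Numeric score(s).
#' @export
window_score <- function(n, p_sum, u_sum) {
  if (any(n < 0 | n > 5)) stop("n must be between 0 and 5", call. = FALSE)
  if (any(p_sum < 0) || any(u_sum < 0)) {
    stop("p_sum and u_sum must be non-negative", call. = FALSE)
  }
  (n - 2) * log(1 + 10 * p_sum / (1 + u_sum))
}

#' Sliding five-register phasing-score profile
#'
#' One window is laid per register start across the span; each window
#' covers five consecutive registers (5k nt). Both strands contribute
#' through the 2-nt overhang phase rule of [classify_phase()]. Only k-nt
#' reads are tallied (in-phase read counts for p, unique out-of-phase
#' reads for U).
#'
#' @param placements Read placements on the transcript (see [map_reads()]).
#' @param anchor Register origin.
#' @param k Cycle length, 21 or 24.
#' @param span_start,span_end 1-based closed interval to profile.
#' @param transcript_id Transcript id recorded in the output.
#' @return A data.frame: `transcript_id`, `window_start`, `n`, `p_sum`,
#'   `u_sum`, `score` — one row per window.
#' @export
score_profile <- function(placements, anchor, k, span_start, span_end,
                          transcript_id = NA_character_) {
  k <- check_k(k)
  empty <- empty_df(transcript_id = character(), window_start = integer(),
                    n = integer(), p_sum = numeric(), u_sum = integer(),
                    score = numeric())
  if (span_end - span_start + 1 < 5 * k) {
    warning("span shorter than five registers (", 5 * k, " nt): empty profile")
    return(empty)
  }
  # first register at or after span_start in the anchor's residue class
  t0 <- span_start + (anchor - span_start) %% k
  starts <- seq.int(t0, span_end - 5L * k + 1L, by = k)
  if (!length(starts)) return(empty)

  p <- placements[placements$length == k, , drop = FALSE]
  if (!is.na(transcript_id) && nrow(p)) {
    p <- p[p$transcript_id == transcript_id, , drop = FALSE]
  }
  in_phase <- if (nrow(p)) classify_phase(p$five_prime_pos, p$strand, anchor, k) else logical(0)
  reg <- if (nrow(p)) placement_register(p$five_prime_pos, p$strand, k) else integer(0)

  rows <- lapply(starts, function(w) {
    hi <- w + 5L * k - 1L
    inw <- nrow(p) > 0 & p$five_prime_pos >= w & p$five_prime_pos <= hi
    ip <- inw & in_phase
    oop <- inw & !in_phase
    data.frame(transcript_id = transcript_id, window_start = w,
               n = length(unique(reg[ip])),
               p_sum = sum(p$count[ip]),
               u_sum = length(unique(p$sequence[oop])),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$score <- window_score(res$n, res$p_sum, res$u_sum)
  res
}

#' Maximum phasing score of a profile and the locus filter
#'
#' A candidate locus passes the phasing filter iff its maximum window
#' score is strictly above 1.
#'
#' @param profile Output of [score_profile()].
#' @param threshold Filter bound (default 1; strict inequality).
#' @return A list with `max_score` and logical `pass`.
#' @export
region_max_score <- function(profile, threshold = 1) {
  if (!nrow(profile)) stop("empty phasing-score profile", call. = FALSE)
  m <- max(profile$score)
  list(max_score = m, pass = m > threshold)
}
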