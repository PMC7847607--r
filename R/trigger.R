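# miRU-style complementarity penalties: Watson-Crick 0, G:U wobble 0.5,
# mismatch 1.0, doubled at sRNA positions 2-7 (the 5' core). Rows are the
# sRNA base (DNA alphabet, T == U), columns the target (sense) base.
penalty_matrix <- local({
  m <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  m["A", "T"] <- 0; m["C", "G"] <- 0; m["G", "C"] <- 0; m["T", "A"] <- 0
  m["G", "T"] <- 0.5  # G:U wobble (target U printed as T)
  m["T", "G"] <- 0.5  # U:G wobble
  m
})

srna_position_weights <- function(L) {
  w <- rep(1, L)
  core <- intersect(2:7, seq_len(L))
  w[core] <- 2
  w
}

#' Score sRNA:target complementarity (miRU-style penalty)
#'
#' The sRNA is aligned antiparallel and ungapped against a same-length
#' sense-strand target window; sRNA position i (from the 5' end) faces the
#' target base at the window's 3' end minus i - 1. Per-position penalties:
#' Watson-Crick pair 0, G:U wobble 0.5, mismatch 1.0; penalties are
#' doubled at sRNA positions 2-7.
#'
#' @param srna sRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param target_window Sense-strand target window, 5'->3', same length.
#' @return Total penalty (0 = perfect complement).
#' @export
score_complementarity <- function(srna, target_window) {
  s <- to_dna(srna); t <- to_dna(target_window)
  if (nchar(s) != nchar(t)) {
    stop("sRNA and target window must have equal length", call. = FALSE)
  }
  assert_dna(s, "sRNA"); assert_dna(t, "target window")
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  tc <- rev(strsplit(t, "", fixed = TRUE)[[1]])  # sRNA pos i faces window end - i + 1
  sum(penalty_matrix[cbind(sc, tc)] * srna_position_weights(length(sc)))
}

# Penalties of an sRNA against every window of a transcript, vectorized
# over window starts. Returns numeric vector indexed by window start.
score_all_windows <- function(srna, tx_chars) {
  s <- to_dna(srna)
  L <- nchar(s)
  N <- length(tx_chars)
  if (L > N) return(numeric(0))
  nw <- N - L + 1L
  w <- srna_position_weights(L)
  # reversed sRNA: index r pairs target offset r - 1 within the window
  a <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  wr <- rev(w)
  acc <- numeric(nw)
  for (r in seq_len(L)) {
    acc <- acc + wr[r] * penalty_matrix[a[r], tx_chars[r:(r + nw - 1L)]]
  }
  acc
}

#' Predicted cleavage position of an sRNA-guided cut
#'
#' RISC cleaves the target opposite the 10th sRNA nucleotide counted from
#' the sRNA 5' end — the 5' end of the downstream fragment. With a
#' 1-based closed binding interval on the target this is
#' `binding_end - 9`, for 21- and 22-nt guides alike.
#'
#' @param binding_start,binding_end 1-based closed binding interval on the
#'   target (vectorized).
#' @return Predicted cleavage position(s).
#' @export
predict_cleavage_site <- function(binding_start, binding_end) {
  if (any(binding_end < binding_start)) {
    stop("binding_end must be >= binding_start", call. = FALSE)
  }
  if (any(binding_end - binding_start + 1 < 10)) {
    stop("binding span shorter than 10 nt has no position-10 cut", call. = FALSE)
  }
  binding_end - 9L
}

#' Find candidate sRNA triggers for a phasiRNA production region
#'
#' Scans every supplied sRNA (library reads of 18-24 nt, plus an optional
#' known-miRNA set) against all windows of the transcript; alignments with
#' penalty at most `max_score` whose predicted cleavage site passes the
#' region [flank_check()] are returned, sorted by penalty then abundance.
#'
#' @param library A normalized `srna_library` (candidate novel triggers).
#' @param transcript A single sequence record (one row).
#' @param region One candidate-region row.
#' @param known_mirnas Optional data.frame with columns `id`, `sequence`.
#' @param max_score Penalty cutoff (default 3).
#' @param flank_tolerance Tolerance passed to [flank_check()] (default 2).
#' @param min_len,max_len Candidate read-length window (default 18-24).
#' @return A data.frame of trigger alignments: `srna_id`, `srna_sequence`
#'   (RNA), `transcript_id`, `binding_start`, `binding_end`, `score`,
#'   `predicted_cleavage`, `rpm`.
#' @export
find_trigger <- function(library, transcript, region, known_mirnas = NULL,
                         max_score = 3, flank_tolerance = 2,
                         min_len = 18, max_len = 24) {
  reads <- analysis_reads(library)
  reads <- reads[reads$length >= min_len & reads$length <= max_len, , drop = FALSE]
  cands <- data.frame(id = paste0("read:", reads$sequence),
                      sequence = reads$sequence, rpm = reads$rpm,
                      stringsAsFactors = FALSE)
  if (!is.null(known_mirnas) && nrow(known_mirnas)) {
    km <- data.frame(id = known_mirnas$id,
                     sequence = to_dna(known_mirnas$sequence),
                     rpm = 0, stringsAsFactors = FALSE)
    # a known miRNA present in the library keeps its measured abundance
    hit <- match(km$sequence, cands$sequence)
    km$rpm[!is.na(hit)] <- cands$rpm[hit[!is.na(hit)]]
    cands <- rbind(km, cands[!(cands$sequence %in% km$sequence), , drop = FALSE])
  }
  tx_chars <- strsplit(transcript$sequence[1], "", fixed = TRUE)[[1]]
  out <- list()
  for (i in seq_len(nrow(cands))) {
    L <- nchar(cands$sequence[i])
    if (L < 10) next
    pen <- score_all_windows(cands$sequence[i], tx_chars)
    hit <- which(pen <= max_score)
    if (!length(hit)) next
    bs <- hit; be <- hit + L - 1L
    cut <- predict_cleavage_site(bs, be)
    ok <- flank_check(cut, region, tolerance = flank_tolerance)
    if (!any(ok)) next
    out[[length(out) + 1L]] <- data.frame(
      srna_id = cands$id[i], srna_sequence = to_rna(cands$sequence[i]),
      transcript_id = transcript$id[1],
      binding_start = bs[ok], binding_end = be[ok],
      score = pen[hit][ok], predicted_cleavage = cut[ok],
      rpm = cands$rpm[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(empty_df(srna_id = character(), srna_sequence = character(),
                    transcript_id = character(), binding_start = integer(),
                    binding_end = integer(), score = numeric(),
                    predicted_cleavage = integer(), rpm = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$score, -res$rpm, res$binding_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Validate trigger alignments against degradome profiles
#'
#' An alignment is validated when at least one degradome library shows a
#' dominant cleavage signal exactly at the predicted cleavage position
#' (within `jitter` nt, default 0).
#'
#' @param alignments Output of [find_trigger()].
#' @param profiles List of `degradome_profile` objects for the transcript.
#' @param min_rpm,min_dominance,flank,eps Passed to [detect_cleavage()].
#' @param jitter Allowed positional slack in nt (default 0).
#' @return `alignments` with `validated` (logical) and
#'   `validating_libraries` (comma-separated) columns appended.
#' @export
validate_trigger <- function(alignments, profiles, min_rpm = 1,
                             min_dominance = 2, flank = 50, eps = 0.1,
                             jitter = 0) {
  alignments$validated <- logical(nrow(alignments))
  alignments$validating_libraries <- character(nrow(alignments))
  if (!nrow(alignments)) return(alignments)
  signals <- lapply(profiles, detect_cleavage, min_rpm = min_rpm,
                    min_dominance = min_dominance, flank = flank, eps = eps)
  for (i in seq_len(nrow(alignments))) {
    libs <- character(0)
    for (j in seq_along(signals)) {
      if (profiles[[j]]$transcript_id != alignments$transcript_id[i]) next
      if (any(abs(signals[[j]]$position - alignments$predicted_cleavage[i]) <= jitter)) {
        libs <- c(libs, profiles[[j]]$library_name)
      }
    }
    alignments$validated[i] <- length(libs) > 0
    alignments$validating_libraries[i] <- paste(unique(libs), collapse = ",")
  }
  alignments
}
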