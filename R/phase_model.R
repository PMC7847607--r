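#' Map library reads exactly onto transcripts (both strands)
#'
#' Every exact occurrence of every retained read — or of its reverse
#' complement for the antisense strand — is reported; a read may map to
#' several transcripts and positions. The 5' coordinate of a minus-strand
#' placement is the sense coordinate of its rightmost base.
#'
#' @param library A normalized `srna_library`.
#' @param transcripts Sequence records (see [read_fasta()]).
#' @param lengths Optional integer vector; only reads of these lengths are
#'   mapped (e.g. `21` when hunting 21-nt phasiRNAs). `NULL` maps all
#'   retained reads.
#' @return A data.frame of placements: `sequence`, `transcript_id`,
#'   `start`, `end`, `strand`, `five_prime_pos`, `length`, `count`, `rpm`.
#' @export
map_reads <- function(library, transcripts, lengths = NULL) {
  reads <- analysis_reads(library)
  if (!is.null(lengths)) reads <- reads[reads$length %in% lengths, , drop = FALSE]
  out <- vector("list", nrow(transcripts) * max(1L, nrow(reads)))
  n <- 0L
  for (t in seq_len(nrow(transcripts))) {
    tx <- transcripts$sequence[t]
    tid <- transcripts$id[t]
    for (r in seq_len(nrow(reads))) {
      s <- reads$sequence[r]
      L <- reads$length[r]
      plus <- find_all(tx, s)
      minus <- find_all(tx, revcomp(s))
      if (length(plus) + length(minus) == 0) next
      n <- n + 1L
      out[[n]] <- data.frame(
        sequence = s, transcript_id = tid,
        start = c(plus, minus),
        end = c(plus, minus) + L - 1L,
        strand = rep(c("+", "-"), c(length(plus), length(minus))),
        five_prime_pos = c(plus, minus + L - 1L),
        length = L, count = reads$count[r], rpm = reads$rpm[r],
        stringsAsFactors = FALSE)
    }
  }
  if (n == 0L) {
    return(empty_df(sequence = character(), transcript_id = character(),
                    start = integer(), end = integer(), strand = character(),
                    five_prime_pos = integer(), length = integer(),
                    count = integer(), rpm = numeric()))
  }
  res <- do.call(rbind, out[seq_len(n)])
  rownames(res) <- NULL
  res
}

check_k <- function(k) {
  if (!length(k) == 1 || !k %in% c(21, 24)) {
    stop("cycle length k must be 21 or 24", call. = FALSE)
  }
  as.integer(k)
}

#' Classify a placement as in phase or out of phase
#'
#' A register grid with cycle `k` anchored at `anchor` holds duplexes whose
#' top strand starts at `anchor + m*k`. Dicer duplexes carry 2-nt 3'
#' overhangs at both ends, so the bottom-strand 5' end of the duplex at
#' `t` sits at sense coordinate `t + k - 3`. Hence a plus-strand read is in
#' phase iff its 5' position is congruent to `anchor` (mod k), and a
#' minus-strand read iff congruent to `anchor + k - 3` (mod k).
#'
#' @param five_prime_pos 1-based sense-strand coordinate(s) of the read 5' end.
#' @param strand `"+"` or `"-"` (recycled).
#' @param anchor Register origin (1-based).
#' @param k Cycle length, 21 or 24.
#' @return Logical vector.
#' @export
classify_phase <- function(five_prime_pos, strand, anchor, k) {
  k <- check_k(k)
  offset <- ifelse(strand == "+", 0L, k - 3L)
  (five_prime_pos - anchor - offset) %% k == 0
}

# sense coordinate of the duplex top-strand start ("register") that a
# placement occupies, assuming it is in phase
placement_register <- function(five_prime_pos, strand, k) {
  ifelse(strand == "+", five_prime_pos, five_prime_pos - (k - 3L))
}

#' Detect candidate phasiRNA production regions
#'
#' For each of the k residue classes of possible anchors, duplex registers
#' occupied by at least one k-nt read (on either strand, under the 2-nt
#' overhang phase rule) are collected and maximal runs of consecutive
#' occupied duplexes are reported. Runs of at least `min_duplexes` tandem
#' duplexes become candidate regions; the region spans the top strand of
#' the first through last occupied duplex.
#'
#' @param placements Placements of k-nt reads on one transcript
#'   (from [map_reads()]).
#' @param transcript A single sequence record (one row).
#' @param k Cycle length, 21 or 24.
#' @param min_duplexes Minimum tandem occupied duplexes (default 5).
#' @param min_rpm Minimum summed RPM for a duplex to count as occupied
#'   (default 0: any mapped read is "detectable").
#' @return A data.frame of regions: `transcript_id`, `k`, `anchor`,
#'   `region_start`, `region_end`, `n_occupied_tandem`, `phase` (anchor
#'   residue, 0-based), `rpm` (summed in-phase RPM in the run).
#' @export
find_candidate_regions <- function(placements, transcript, k,
                                   min_duplexes = 5, min_rpm = 0) {
  k <- check_k(k)
  empty <- empty_df(transcript_id = character(), k = integer(),
                    anchor = integer(), region_start = integer(),
                    region_end = integer(), n_occupied_tandem = integer(),
                    phase = integer(), rpm = numeric())
  p <- placements[placements$length == k &
                    placements$transcript_id == transcript$id[1], , drop = FALSE]
  if (!nrow(p)) return(empty)
  reg <- placement_register(p$five_prime_pos, p$strand, k)
  keep <- reg >= 1L & (reg + k - 1L) <= transcript$length[1]
  p <- p[keep, , drop = FALSE]; reg <- reg[keep]
  if (!nrow(p)) return(empty)
  rpm_by_reg <- rowsum(p$rpm, reg)
  regs <- as.integer(rownames(rpm_by_reg))
  occupied <- regs[rpm_by_reg[, 1] > min_rpm]
  if (!length(occupied)) return(empty)
  out <- list()
  for (phase in unique(occupied %% k)) {
    t_occ <- sort(occupied[occupied %% k == phase])
    run_id <- cumsum(c(1L, diff(t_occ) != k))
    for (ri in unique(run_id)) {
      run <- t_occ[run_id == ri]
      if (length(run) < min_duplexes) next
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = transcript$id[1], k = k, anchor = run[1],
        region_start = run[1], region_end = run[length(run)] + k - 1L,
        n_occupied_tandem = length(run), phase = as.integer(phase),
        rpm = sum(rpm_by_reg[as.character(run), 1]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$region_start, res$phase), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge candidate runs in the same phase into a hull
#'
#' Reported regions are maximal runs of tandem occupied duplexes. Loci
#' whose occupancy has gaps appear as several runs in one residue class;
#' this helper also reports the merged hull per (transcript, k, phase).
#'
#' @param regions Output of [find_candidate_regions()].
#' @return A data.frame with one hull row per (transcript_id, k, phase).
#' @export
region_hull <- function(regions) {
  if (!nrow(regions)) return(regions)
  key <- interaction(regions$transcript_id, regions$k, regions$phase, drop = TRUE)
  parts <- lapply(split(regions, key), function(g) {
    data.frame(transcript_id = g$transcript_id[1], k = g$k[1],
               anchor = min(g$anchor),
               region_start = min(g$region_start),
               region_end = max(g$region_end),
               n_occupied_tandem = sum(g$n_occupied_tandem),
               phase = g$phase[1], rpm = sum(g$rpm),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res[order(res$transcript_id, res$k, res$region_start), , drop = FALSE]
}
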