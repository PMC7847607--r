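# Brute-force oracles, independent of the package's implementations, plus
# small constructors for hand-built placements and sequences.

rc <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# every start of `query` in `subject`, by explicit substring comparison
oracle_find_all <- function(subject, query) {
  L <- nchar(query)
  starts <- integer(0)
  for (s in seq_len(nchar(subject) - L + 1)) {
    if (substr(subject, s, s + L - 1) == query) starts <- c(starts, s)
  }
  starts
}

# hand-built placement rows (the columns the phase/scoring code consumes)
placement_df <- function(five_prime_pos, strand, k = 21, count = 1,
                         rpm = 1, sequence = NULL, transcript_id = "t1") {
  n <- length(five_prime_pos)
  data.frame(
    sequence = rep_len(sequence %||% sprintf("READ%04d", seq_len(n)),
                       n),
    transcript_id = rep_len(transcript_id, n),
    start = ifelse(strand == "+", five_prime_pos, five_prime_pos - k + 1L),
    end = ifelse(strand == "+", five_prime_pos + k - 1L, five_prime_pos),
    strand = strand, five_prime_pos = as.integer(five_prime_pos),
    length = rep_len(as.integer(k), n),
    count = rep_len(count, n), rpm = rep_len(rpm, n),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force candidate-region finder: tries every anchor residue and
# walks registers one by one
oracle_regions <- function(placements, txlen, k, min_duplexes = 5) {
  occupied <- function(t) {
    any(placements$strand == "+" & placements$five_prime_pos == t) ||
      any(placements$strand == "-" & placements$five_prime_pos == t + k - 3)
  }
  out <- list()
  for (a in seq_len(k)) {
    ts <- seq(a, txlen - k + 1, by = k)
    occ <- vapply(ts, occupied, logical(1))
    run <- 0L; run_start <- NA_integer_
    flush <- function(run, run_start, last_t) {
      if (run >= min_duplexes) {
        data.frame(anchor = run_start, region_start = run_start,
                   region_end = last_t + k - 1L, n = run)
      } else NULL
    }
    for (i in seq_along(ts)) {
      if (occ[i]) {
        if (run == 0L) run_start <- ts[i]
        run <- run + 1L
      } else if (run > 0L) {
        out[[length(out) + 1L]] <- flush(run, run_start, ts[i - 1])
        run <- 0L
      }
    }
    if (run > 0L) out[[length(out) + 1L]] <- flush(run, run_start, ts[length(ts)])
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$region_start, res$anchor %% k), , drop = FALSE]
}

# explicit five-register window tally for one window start
oracle_window_tally <- function(placements, anchor, k, w) {
  hi <- w + 5 * k - 1
  inw <- placements[placements$five_prime_pos >= w &
                      placements$five_prime_pos <= hi &
                      placements$length == k, , drop = FALSE]
  in_phase <- (inw$five_prime_pos - anchor -
                 ifelse(inw$strand == "+", 0, k - 3)) %% k == 0
  reg <- ifelse(inw$strand == "+", inw$five_prime_pos,
                inw$five_prime_pos - (k - 3))
  list(n = length(unique(reg[in_phase])),
       p_sum = sum(inw$count[in_phase]),
       u_sum = length(unique(inw$sequence[!in_phase])))
}

# brute-force dominant-peak scan over a dense rpm vector
oracle_peaks <- function(rpm_by_pos, min_rpm, min_dominance, flank = 50,
                         eps = 0.1) {
  pos <- which(rpm_by_pos > 0)
  keep <- logical(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (rpm_by_pos[p] < min_rpm) next
    lo <- max(1, p - flank); hi <- min(length(rpm_by_pos), p + flank)
    bg <- max(c(rpm_by_pos[setdiff(lo:hi, p)], 0))
    keep[i] <- rpm_by_pos[p] / max(bg, eps) >= min_dominance
  }
  found <- pos[keep]
  found[order(-rpm_by_pos[found], found)]
}

# brute-force three-letter bisulfite matcher: every offset, both strands,
# comparing base by base in the collapsed alphabet (C->T for the plus
# strand, G->A for the reverse-complement read against the minus strand)
oracle_bisulfite_sites <- function(read, promoter) {
  L <- nchar(read)
  hits <- list()
  collapse_eq <- function(a, b, from, to) {
    chartr(from, to, a) == chartr(from, to, b)
  }
  rcread <- rc(read)
  for (s in seq_len(nchar(promoter) - L + 1)) {
    ref <- substr(promoter, s, s + L - 1)
    ok_plus <- TRUE; ok_minus <- TRUE
    for (j in seq_len(L)) {
      fb <- substr(ref, j, j)
      if (!collapse_eq(substr(read, j, j), fb, "C", "T")) ok_plus <- FALSE
      if (!collapse_eq(substr(rcread, j, j), fb, "G", "A")) ok_minus <- FALSE
      if (!ok_plus && !ok_minus) break
    }
    if (ok_plus) hits[[length(hits) + 1L]] <- c(s, 1L)
    if (ok_minus) hits[[length(hits) + 1L]] <- c(s, -1L)
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}
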