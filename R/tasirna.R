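#' Format a phasiRNA name
#'
#' Names follow the field's D-position grammar,
#' `Locus(anchor)k 5'|3'D<i>(strand)`, e.g.
#' `LOC_Os02g18750.1(189)21 3'D26(+)`: duplex index i counted away from
#' the trigger-cleavage anchor, on the 3' fragment (`3'D`) or into the
#' upstream 5' fragment (`5'D`).
#'
#' @param locus_id Locus (transcript) id.
#' @param anchor Register origin printed in parentheses.
#' @param k Cycle length (21 or 24).
#' @param side `"3'"` or `"5'"`.
#' @param index Duplex index, >= 1.
#' @param strand `"+"` or `"-"`.
#' @return Character name(s).
#' @export
phasirna_name <- function(locus_id, anchor, k, side, index, strand) {
  stopifnot(all(side %in% c("3'", "5'")))
  sprintf("%s(%d)%d %sD%d(%s)", locus_id, as.integer(anchor), as.integer(k),
          side, as.integer(index), strand)
}

#' Parse a phasiRNA name back into its fields
#'
#' Tolerates the typographic variants seen in print: straight or curly
#' apostrophes, optional spaces around `k` and before the strand.
#'
#' @param name Character vector of phasiRNA names.
#' @return A data.frame with `locus_id`, `anchor`, `k`, `side`, `index`,
#'   `strand`.
#' @export
parse_phasirna_name <- function(name) {
  rx <- "^(.*)\\((\\d+)\\)\\s*(\\d+)\\s*([35])['’′]\\s*D\\s*(\\d+)\\s*\\(([+−-])\\)$"
  m <- regmatches(name, regexec(rx, name))
  bad <- vapply(m, length, integer(1)) != 7
  if (any(bad)) {
    stop("unparseable phasiRNA name: ", paste(name[bad], collapse = "; "),
         call. = FALSE)
  }
  f <- do.call(rbind, m)
  data.frame(locus_id = f[, 2], anchor = as.integer(f[, 3]),
             k = as.integer(f[, 4]), side = paste0(f[, 5], "'"),
             index = as.integer(f[, 6]),
             strand = ifelse(f[, 7] == "−", "-", f[, 7]),
             stringsAsFactors = FALSE)
}

#' Enumerate phasiRNAs from a PHAS locus register grid
#'
#' Starting from the trigger-cleavage anchor, duplexes are laid every k nt
#' downstream (`3'D1, 3'D2, ...`, `3'D1` starting at the anchor itself) or
#' upstream (`5'D1` ending immediately before the anchor). Each duplex
#' yields the top-strand k-mer (+) and, two nt 5'-shifted on the sense
#' scale, the reverse complement bottom strand (-). Abundance is taken
#' from matching library reads (0 RPM when undetected).
#'
#' @param transcript A single sequence record (one row).
#' @param anchor Register origin (1-based).
#' @param k Cycle length, 21 or 24.
#' @param n_duplexes Number of duplex indices to enumerate.
#' @param side `"3'"` (downstream, default) or `"5'"` (upstream).
#' @param library Optional normalized `srna_library` supplying RPM.
#' @return A data.frame: `name`, `locus_id`, `anchor`, `k`, `side`,
#'   `index`, `strand`, `start`, `end`, `sequence` (RNA), `rpm`.
#' @export
enumerate_phasirnas <- function(transcript, anchor, k, n_duplexes,
                                side = c("3'", "5'"), library = NULL) {
  side <- match.arg(side)
  k <- check_k(k)
  txlen <- transcript$length[1]
  if (anchor < 1 || anchor > txlen) stop("anchor off transcript", call. = FALSE)
  tx <- transcript$sequence[1]
  rows <- list()
  for (i in seq_len(n_duplexes)) {
    top_start <- if (side == "3'") anchor + (i - 1L) * k else anchor - i * k
    top_end <- top_start + k - 1L
    bot_start <- top_start - 2L
    bot_end <- top_end - 2L
    if (top_start >= 1 && top_end <= txlen) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = transcript$id[1], anchor = anchor, k = k, side = side,
        index = i, strand = "+", start = top_start, end = top_end,
        sequence = to_rna(substr(tx, top_start, top_end)),
        stringsAsFactors = FALSE)
    }
    if (bot_start >= 1 && bot_end <= txlen) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = transcript$id[1], anchor = anchor, k = k, side = side,
        index = i, strand = "-", start = bot_start, end = bot_end,
        sequence = to_rna(revcomp(substr(tx, bot_start, bot_end))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(empty_df(name = character(), locus_id = character(),
                    anchor = integer(), k = integer(), side = character(),
                    index = integer(), strand = character(),
                    start = integer(), end = integer(),
                    sequence = character(), rpm = numeric()))
  }
  res <- do.call(rbind, rows)
  res$name <- phasirna_name(res$locus_id, res$anchor, res$k, res$side,
                            res$index, res$strand)
  res$rpm <- 0
  if (!is.null(library)) {
    reads <- analysis_reads(library)
    hit <- match(to_dna(res$sequence), reads$sequence)
    res$rpm[!is.na(hit)] <- reads$rpm[hit[!is.na(hit)]]
  }
  res[, c("name", "locus_id", "anchor", "k", "side", "index", "strand",
          "start", "end", "sequence", "rpm")]
}

#' Predict targets of phasiRNAs across a transcript set
#'
#' Each phasiRNA is scanned against every window of every transcript with
#' the miRU-style penalty of [score_complementarity()]; windows with
#' penalty at most `max_score` become candidate interactions with
#' predicted cut site `miru_end - 9`.
#'
#' @param phasirnas Data.frame from [enumerate_phasirnas()] (or any frame
#'   with `name` and `sequence` columns); rows with `rpm == 0` are skipped
#'   when an `rpm` column is present (undetected phasiRNAs are not
#'   recruited for prediction).
#' @param transcripts Sequence records to scan.
#' @param max_score Penalty cutoff (default 3).
#' @param exclude Transcript ids to skip (e.g. the source locus).
#' @return A data.frame: `phasirna`, `target_id`, `miru_start`,
#'   `miru_end`, `score`, `predicted_cut`.
#' @export
predict_targets <- function(phasirnas, transcripts, max_score = 3,
                            exclude = character(0)) {
  empty <- empty_df(phasirna = character(), target_id = character(),
                    miru_start = integer(), miru_end = integer(),
                    score = numeric(), predicted_cut = integer())
  if (!nrow(phasirnas)) return(empty)
  if ("rpm" %in% names(phasirnas)) {
    phasirnas <- phasirnas[phasirnas$rpm > 0, , drop = FALSE]
  }
  if (!nrow(phasirnas)) return(empty)
  keep_tx <- !(transcripts$id %in% exclude)
  out <- list()
  for (t in which(keep_tx)) {
    tx_chars <- strsplit(transcripts$sequence[t], "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(phasirnas))) {
      L <- nchar(phasirnas$sequence[i])
      pen <- score_all_windows(phasirnas$sequence[i], tx_chars)
      hit <- which(pen <= max_score)
      if (!length(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        phasirna = phasirnas$name[i], target_id = transcripts$id[t],
        miru_start = hit, miru_end = hit + L - 1L, score = pen[hit],
        predicted_cut = hit + L - 10L, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$phasirna, res$target_id, res$miru_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Validate predicted interactions against degradome profiles
#'
#' An interaction is validated when at least one degradome library has a
#' dominant cleavage signal at the predicted cut site on the target.
#'
#' @param interactions Output of [predict_targets()].
#' @param profiles List of `degradome_profile` objects (any transcripts).
#' @param min_rpm,min_dominance,flank,eps Passed to [detect_cleavage()].
#' @param jitter Allowed positional slack in nt (default 0).
#' @return `interactions` with `validated` and `validating_libraries`.
#' @export
validate_interactions <- function(interactions, profiles, min_rpm = 1,
                                  min_dominance = 2, flank = 50, eps = 0.1,
                                  jitter = 0) {
  interactions$validated <- logical(nrow(interactions))
  interactions$validating_libraries <- character(nrow(interactions))
  if (!nrow(interactions)) return(interactions)
  signals <- lapply(profiles, detect_cleavage, min_rpm = min_rpm,
                    min_dominance = min_dominance, flank = flank, eps = eps)
  tx_of <- vapply(profiles, `[[`, character(1), "transcript_id")
  lib_of <- vapply(profiles, `[[`, character(1), "library_name")
  for (i in seq_len(nrow(interactions))) {
    js <- which(tx_of == interactions$target_id[i])
    libs <- character(0)
    for (j in js) {
      if (any(abs(signals[[j]]$position - interactions$predicted_cut[i]) <= jitter)) {
        libs <- c(libs, lib_of[j])
      }
    }
    interactions$validated[i] <- length(libs) > 0
    interactions$validating_libraries[i] <- paste(unique(libs), collapse = ",")
  }
  interactions
}

#' Edge table of the validated phasiRNA-target network
#'
#' @param interactions Validated interactions (see
#'   [validate_interactions()]); only rows with `validated == TRUE` become
#'   edges. Duplicate edges are removed.
#' @param annotations Optional data.frame (`id`, `annotation`) used to
#'   annotate target nodes.
#' @return A data.frame of edges: `phasirna`, `target_id`, `score`,
#'   `predicted_cut`, `target_annotation`.
#' @export
build_network_table <- function(interactions, annotations = NULL) {
  v <- if (nrow(interactions) && "validated" %in% names(interactions)) {
    interactions[interactions$validated, , drop = FALSE]
  } else {
    interactions[integer(0), , drop = FALSE]
  }
  if (!nrow(v)) {
    return(empty_df(phasirna = character(), target_id = character(),
                    score = numeric(), predicted_cut = integer(),
                    target_annotation = character()))
  }
  v <- v[!duplicated(v[, c("phasirna", "target_id", "predicted_cut")]), ,
         drop = FALSE]
  ann <- rep(NA_character_, nrow(v))
  if (!is.null(annotations)) {
    hit <- match(v$target_id, annotations$id)
    ann[!is.na(hit)] <- annotations$annotation[hit[!is.na(hit)]]
  }
  res <- data.frame(phasirna = v$phasirna, target_id = v$target_id,
                    score = v$score, predicted_cut = v$predicted_cut,
                    target_annotation = ann, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
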