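#' Find 24-nt phasiRNA binding sites on promoters
#'
#' Zero-mismatch, full-length search: a promoter hit is every exact
#' occurrence of the phasiRNA's reverse complement (orientation
#' `"complementary"`, the RdDM-relevant configuration) and, flagged
#' separately, of its identical DNA sequence (orientation `"identical"`).
#'
#' @param phasirnas Data.frame with `name` and `sequence` columns
#'   (RNA or DNA alphabet), e.g. from [enumerate_phasirnas()] with k = 24.
#' @param promoters Promoter sequence records.
#' @return A data.frame: `phasirna`, `sequence`, `promoter_id`, `start`,
#'   `end`, `orientation`.
#' @export
find_promoter_hits <- function(phasirnas, promoters) {
  out <- list()
  for (i in seq_len(nrow(phasirnas))) {
    s <- to_dna(phasirnas$sequence[i])
    for (p in seq_len(nrow(promoters))) {
      for (ori in c("complementary", "identical")) {
        q <- if (ori == "complementary") revcomp(s) else s
        hits <- find_all(promoters$sequence[p], q)
        if (!length(hits)) next
        out[[length(out) + 1L]] <- data.frame(
          phasirna = phasirnas$name[i], sequence = phasirnas$sequence[i],
          promoter_id = promoters$id[p], start = hits,
          end = hits + nchar(s) - 1L, orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(empty_df(phasirna = character(), sequence = character(),
                    promoter_id = character(), start = integer(),
                    end = integer(), orientation = character()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify a cytosine's sequence context (CG / CHG / CHH)
#'
#' Standard trinucleotide rule, H = A/C/T: CG when the next base 3' of the
#' cytosine is G, CHG when the base after next is G, CHH otherwise. On the
#' minus strand the rule is applied to the reverse complement. Cytosines
#' within 2 nt of the 3' end use the available bases and default to CHH
#' when the needed base is missing.
#'
#' @param sequence Plus-strand DNA string.
#' @param position 1-based position of the cytosine (on `strand`).
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"` or `"CHH"`.
#' @export
classify_context <- function(sequence, position, strand = "+") {
  sequence <- to_dna(sequence)
  n <- nchar(sequence)
  base_at <- function(p) if (p >= 1 && p <= n) substr(sequence, p, p) else NA_character_
  if (strand == "+") {
    if (!identical(base_at(position), "C")) stop("base at position is not C", call. = FALSE)
    b1 <- base_at(position + 1); b2 <- base_at(position + 2)
  } else {
    if (!identical(base_at(position), "G")) stop("base at position is not C on minus strand", call. = FALSE)
    b1 <- base_at(position - 1); b2 <- base_at(position - 2)
    b1 <- if (is.na(b1)) b1 else chartr("ACGT", "TGCA", b1)
    b2 <- if (is.na(b2)) b2 else chartr("ACGT", "TGCA", b2)
  }
  if (identical(b1, "G")) return("CG")
  if (identical(b2, "G")) return("CHG")
  "CHH"
}

# all cytosines of a promoter on both strands with their contexts
cytosine_table <- function(promoter) {
  seq <- promoter$sequence[1]
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  plus <- which(chars == "C")
  minus <- which(chars == "G")
  pos <- c(plus, minus)
  strand <- rep(c("+", "-"), c(length(plus), length(minus)))
  ctx <- mapply(function(p, s) classify_context(seq, p, s), pos, strand,
                USE.NAMES = FALSE)
  if (!length(pos)) {
    return(empty_df(position = integer(), strand = character(),
                    context = character()))
  }
  res <- data.frame(position = pos, strand = strand,
                    context = as.character(ctx), stringsAsFactors = FALSE)
  res[order(res$position, res$strand), , drop = FALSE]
}

# Bisulfite placements of one read across promoters under three-letter
# matching: plus strand compares C->T collapses; minus strand compares the
# reverse complement under G->A collapse.
bisulfite_placements <- function(read, promoters) {
  out <- list()
  r_ct <- chartr("C", "T", read)
  rc <- revcomp(read)
  rc_ga <- chartr("G", "A", rc)
  for (p in seq_len(nrow(promoters))) {
    ref <- promoters$sequence[p]
    plus <- find_all(chartr("C", "T", ref), r_ct)
    minus <- find_all(chartr("G", "A", ref), rc_ga)
    if (length(plus)) {
      out[[length(out) + 1L]] <- data.frame(
        promoter_id = promoters$id[p], start = plus, strand = "+",
        stringsAsFactors = FALSE)
    }
    if (length(minus)) {
      out[[length(out) + 1L]] <- data.frame(
        promoter_id = promoters$id[p], start = minus, strand = "-",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Map bisulfite reads to promoters (three-letter matching)
#'
#' A read maps where it matches a promoter exactly after collapsing the
#' bisulfite-convertible base (C->T against the plus strand; G->A against
#' the reverse complement for minus-strand reads). Only reads with exactly
#' one placement across all supplied promoters are retained. At every
#' covered reference cytosine, a retained C in the read is methylated
#' evidence and a converted T is unmethylated evidence; counts are
#' weighted by the collapsed read count.
#'
#' @param library An `srna_library` of bisulfite reads (any length;
#'   length-window flags are ignored here).
#' @param promoters Promoter sequence records.
#' @return A data.frame of per-cytosine counts: `promoter_id`, `position`,
#'   `strand`, `meth_count`, `total_count`.
#' @export
map_bisulfite_reads <- function(library, promoters) {
  reads <- library$reads
  acc <- list()
  for (i in seq_len(nrow(reads))) {
    read <- reads$sequence[i]
    pl <- bisulfite_placements(read, promoters)
    if (is.null(pl) || nrow(pl) != 1) next  # unmapped or non-unique
    pid <- pl$promoter_id[1]
    ref <- promoters$sequence[promoters$id == pid]
    L <- nchar(read)
    offs <- seq_len(L)
    ref_chars <- strsplit(substr(ref, pl$start[1], pl$start[1] + L - 1L),
                          "", fixed = TRUE)[[1]]
    if (pl$strand[1] == "+") {
      rd_chars <- strsplit(read, "", fixed = TRUE)[[1]]
      cyt <- which(ref_chars == "C")
      meth <- rd_chars[cyt] == "C"
      strand <- "+"
    } else {
      rc_chars <- strsplit(revcomp(read), "", fixed = TRUE)[[1]]
      cyt <- which(ref_chars == "G")
      meth <- rc_chars[cyt] == "G"
      strand <- "-"
    }
    if (!length(cyt)) next
    acc[[length(acc) + 1L]] <- data.frame(
      promoter_id = pid, position = pl$start[1] + cyt - 1L, strand = strand,
      meth_count = ifelse(meth, reads$count[i], 0L),
      total_count = reads$count[i], stringsAsFactors = FALSE)
  }
  if (!length(acc)) {
    return(empty_df(promoter_id = character(), position = integer(),
                    strand = character(), meth_count = integer(),
                    total_count = integer()))
  }
  all <- do.call(rbind, acc)
  agg <- stats::aggregate(cbind(meth_count, total_count) ~ promoter_id + position + strand,
                          data = all, FUN = sum)
  agg <- agg[order(agg$promoter_id, agg$position, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Per-cytosine methylation profile of a promoter
#'
#' Every cytosine on both strands is reported with its context and its
#' coverage normalized to reads per million of the bisulfite library:
#' `methylated_rpm = meth_count * 1e6 / library_total`. The conventional
#' methylated fraction (`meth_count / total_count`) is emitted alongside.
#'
#' @param counts Per-cytosine counts from [map_bisulfite_reads()].
#' @param library_total Bisulfite library total read count (> 0).
#' @param promoter A single promoter record (one row).
#' @return A data.frame: `promoter_id`, `position`, `strand`, `context`,
#'   `meth_count`, `total_count`, `methylated_rpm`, `total_rpm`,
#'   `fraction` (NA where uncovered).
#' @export
methylation_profile <- function(counts, library_total, promoter) {
  if (library_total <= 0) stop("bisulfite library_total is 0", call. = FALSE)
  ctab <- cytosine_table(promoter)
  ctab$promoter_id <- promoter$id[1]
  cnt <- counts[counts$promoter_id == promoter$id[1], , drop = FALSE]
  key <- paste(ctab$position, ctab$strand)
  hit <- match(key, paste(cnt$position, cnt$strand))
  ctab$meth_count <- ifelse(is.na(hit), 0L, cnt$meth_count[hit])
  ctab$total_count <- ifelse(is.na(hit), 0L, cnt$total_count[hit])
  ctab$methylated_rpm <- ctab$meth_count * 1e6 / library_total
  ctab$total_rpm <- ctab$total_count * 1e6 / library_total
  ctab$fraction <- ifelse(ctab$total_count > 0,
                          ctab$meth_count / ctab$total_count, NA_real_)
  rownames(ctab) <- NULL
  ctab[, c("promoter_id", "position", "strand", "context", "meth_count",
           "total_count", "methylated_rpm", "total_rpm", "fraction")]
}

#' Per-context methylation totals of a profile
#'
#' @param profile Output of [methylation_profile()].
#' @return A data.frame with one row per context (`CG`, `CHG`, `CHH`) and
#'   summed `methylated_rpm`, `total_rpm` and cytosine counts.
#' @export
context_summary <- function(profile) {
  ctxs <- c("CG", "CHG", "CHH")
  do.call(rbind, lapply(ctxs, function(cx) {
    g <- profile[profile$context == cx, , drop = FALSE]
    data.frame(context = cx, n_cytosines = nrow(g),
               methylated_rpm = sum(g$methylated_rpm),
               total_rpm = sum(g$total_rpm), stringsAsFactors = FALSE)
  }))
}

#' Expression of a gene as total RPM of exactly matching reads
#'
#' @param rnaseq A normalized `srna_library` of RNA-seq reads.
#' @param cdna A single cDNA sequence record (one row).
#' @return Summed RPM of all reads matching the cDNA sense strand exactly
#'   (each unique read counted once regardless of multiple positions).
#' @export
expression_rpm <- function(rnaseq, cdna) {
  reads <- analysis_reads(rnaseq)
  if (!nrow(reads)) return(0)
  hits <- vapply(reads$sequence, function(s) {
    length(find_all(cdna$sequence[1], s)) > 0
  }, logical(1))
  sum(reads$rpm[hits])
}

#' Compare two tissues for RdDM consistency
#'
#' The RdDM expectation for a 24-nt phasiRNA target promoter: CHH
#' methylation is higher in the tissue where the phasiRNA is expressed,
#' and the target gene's expression is lower there. CG and CHG totals are
#' reported but do not enter the call (they are maintained by
#' methyltransferases independent of the siRNA pathway).
#'
#' @param profile_expressing,profile_other Methylation profiles
#'   ([methylation_profile()]) of the target promoter in the
#'   phasiRNA-expressing tissue and the other tissue.
#' @param expr_expressing,expr_other Target-gene expression (RPM) in the
#'   two tissues.
#' @param tissue_expressing,tissue_other Tissue labels for the report.
#' @return A list: per-context totals for both tissues, the two
#'   expression values, and logical `consistent`.
#' @export
compare_tissues <- function(profile_expressing, profile_other,
                            expr_expressing, expr_other,
                            tissue_expressing = "expressing",
                            tissue_other = "other") {
  se <- context_summary(profile_expressing)
  so <- context_summary(profile_other)
  chh_e <- se$methylated_rpm[se$context == "CHH"]
  chh_o <- so$methylated_rpm[so$context == "CHH"]
  list(tissue_expressing = tissue_expressing, tissue_other = tissue_other,
       context_expressing = se, context_other = so,
       chh_methylated_rpm = c(chh_e, chh_o),
       expression_rpm = c(expr_expressing, expr_other),
       consistent = chh_e > chh_o && expr_expressing < expr_other)
}
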