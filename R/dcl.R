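#' Call DCL dependence of a PHAS locus
#'
#' Sums the RPM of in-phase k-nt reads within the region for a wild-type
#' and a dcl-mutant library and calls the locus DCL-dependent when the
#' wild-type/mutant fold change reaches `threshold`. A pseudo-floor `eps`
#' on the mutant RPM keeps the fold finite for fully depleted mutants.
#'
#' @param region One candidate-region row (see [find_candidate_regions()]).
#' @param transcript The matching sequence record (one row).
#' @param wt,mutant Normalized `srna_library` objects (wild type and
#'   dcl mutant).
#' @param threshold Fold-change cutoff (default 2).
#' @param eps Mutant RPM pseudo-floor (default 0.1).
#' @return A one-row data.frame: `locus_id`, `k`, `wt_rpm`, `mutant_rpm`,
#'   `fold`, `dependent`.
#' @export
call_dependence <- function(region, transcript, wt, mutant,
                            threshold = 2, eps = 0.1) {
  k <- region$k[1]
  phased_rpm <- function(lib) {
    pl <- map_reads(lib, transcript, lengths = k)
    if (!nrow(pl)) return(0)
    ip <- classify_phase(pl$five_prime_pos, pl$strand, region$anchor[1], k)
    reg <- placement_register(pl$five_prime_pos, pl$strand, k)
    inside <- reg >= region$region_start[1] & (reg + k - 1) <= region$region_end[1]
    sum(pl$rpm[ip & inside])
  }
  wt_rpm <- phased_rpm(wt)
  mutant_rpm <- phased_rpm(mutant)
  fold <- wt_rpm / max(mutant_rpm, eps)
  data.frame(locus_id = region$transcript_id[1], k = k,
             wt_rpm = wt_rpm, mutant_rpm = mutant_rpm, fold = fold,
             dependent = fold >= threshold, stringsAsFactors = FALSE)
}
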