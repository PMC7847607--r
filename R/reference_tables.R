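ref_table <- function(file) {
  path <- system.file("extdata", file, package = "phasloc", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
}

#' Reported rice PHAS loci with their sRNA triggers
#'
#' Compendium of published 21- and 24-nt rice PHAS loci: production
#' region, trigger identity and sequence, trigger binding site on the
#' precursor and the degradome-observed cleavage site. Used as worked
#' examples for the cleavage-position rule.
#'
#' @return A data.frame with one row per (locus, trigger) pair.
#' @export
reference_phas_loci <- function() ref_table("rice_phas_loci.tsv")

#' Reported rice tasiRNA-target interactions
#'
#' Published 21-nt tasiRNA target interactions: tasiRNA D-position name
#' and sequence, target transcript, miRU binding interval and the
#' tasiRNA-mediated cut site.
#'
#' @return A data.frame with one row per interaction.
#' @export
reference_tasirna_targets <- function() ref_table("rice_tasirna_targets.tsv")

#' Reported 24-nt phasiRNA binding sites on a rice promoter
#'
#' Published promoter binding sites of retrotransposon-derived 24-nt
#' phasiRNAs on the promoter of a casein kinase gene (the RdDM case
#' study).
#'
#' @return A data.frame with one row per promoter hit.
#' @export
reference_promoter_hits <- function() ref_table("rice_24nt_promoter_hits.tsv")
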