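#' Default analysis parameters
#'
#' Every threshold the screening procedure uses, with its default:
#' `min_duplexes` (5 tandem occupied duplexes), `min_score` (phasing-score
#' bound, strict), `max_trigger_score` / `max_target_score` (miRU penalty
#' cutoffs), `min_rpm` and `min_dominance` (degradome signal calling),
#' `flank_tolerance` (nt around the region start for the trigger cut),
#' `jitter` (positional slack for degradome validation), `fold_threshold`
#' and `eps` (DCL dependence), `min_duplex_rpm` (duplex occupancy floor),
#' `ks` (cycle lengths screened).
#'
#' @param ... Overrides of the defaults.
#' @return A named list of parameters.
#' @export
phas_params <- function(...) {
  p <- list(min_duplexes = 5, min_score = 1, max_trigger_score = 3,
            max_target_score = 3, min_rpm = 1, min_dominance = 2,
            flank_tolerance = 2, jitter = 0, fold_threshold = 2,
            eps = 0.1, min_duplex_rpm = 0, ks = c(21L, 24L))
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(over)] <- over
  p
}

params_log <- function(params) {
  vapply(names(params), function(nm) {
    sprintf("%s = %s", nm, paste(params[[nm]], collapse = ","))
  }, character(1))
}

#' Run the full PHAS-locus discovery analysis
#'
#' Executes the screening chain on every supplied small-RNA library:
#' exact read mapping, candidate-region detection (at least
#' `min_duplexes` tandem occupied duplexes), the strict phasing-score
#' filter, degradome cleavage support inside the production region,
#' trigger search and degradome validation, phasiRNA enumeration from
#' validated 21-nt loci, target prediction and validation, and (when
#' mutant libraries are supplied) DCL-dependence calls.
#'
#' @param transcripts Transcript records ([read_fasta()]).
#' @param srna_libraries One `srna_library` or a list of them.
#' @param degradome_libraries One `srna_library` of degradome tags or a
#'   list of them.
#' @param known_mirnas Optional data.frame (`id`, `sequence`) of known
#'   miRNAs added to the trigger search space.
#' @param mutant_libraries Optional named list of dcl-mutant libraries
#'   keyed by cycle length (`"21"`, `"24"`).
#' @param params See [phas_params()].
#' @return A list: `loci` (one row per accepted locus with trigger and
#'   validation columns), `regions` (all candidate regions),
#'   `score_profiles`, `phasirnas`, `interactions`, `network`,
#'   `dcl_calls`, `log`.
#' @export
run_phas_discovery <- function(transcripts, srna_libraries,
                               degradome_libraries, known_mirnas = NULL,
                               mutant_libraries = NULL,
                               params = phas_params()) {
  if (missing(transcripts) || !nrow(transcripts)) {
    stop("no transcripts supplied", call. = FALSE)
  }
  if (inherits(srna_libraries, "srna_library")) srna_libraries <- list(srna_libraries)
  if (inherits(degradome_libraries, "srna_library")) degradome_libraries <- list(degradome_libraries)
  if (!length(srna_libraries)) stop("no small-RNA library supplied", call. = FALSE)
  if (!length(degradome_libraries)) stop("no degradome library supplied", call. = FALSE)
  srna_libraries <- lapply(srna_libraries, normalize_rpm)
  degradome_libraries <- lapply(degradome_libraries, normalize_rpm)

  # degradome profiles are per (library, transcript), built lazily
  prof_cache <- new.env(parent = emptyenv())
  profile_for <- function(tid) {
    key <- tid
    if (!is.null(prof_cache[[key]])) return(prof_cache[[key]])
    tx <- transcripts[transcripts$id == tid, , drop = FALSE]
    ps <- lapply(degradome_libraries, build_profile, transcript = tx)
    prof_cache[[key]] <- ps
    ps
  }

  all_regions <- list(); loci <- list(); profiles <- list()
  phasirnas <- list(); interactions <- list(); dcl_calls <- list()

  for (k in params$ks) {
    for (lib in srna_libraries) {
      placements <- map_reads(lib, transcripts, lengths = k)
      if (!nrow(placements)) next
      for (tid in unique(placements$transcript_id)) {
        tx <- transcripts[transcripts$id == tid, , drop = FALSE]
        regs <- find_candidate_regions(placements, tx, k,
                                       min_duplexes = params$min_duplexes,
                                       min_rpm = params$min_duplex_rpm)
        if (!nrow(regs)) next
        regs$library <- lib$name
        all_regions[[length(all_regions) + 1L]] <- regs
        for (ri in seq_len(nrow(regs))) {
          region <- regs[ri, , drop = FALSE]
          prof <- score_profile(placements, region$anchor, k,
                                region$region_start, region$region_end,
                                transcript_id = tid)
          if (!nrow(prof)) next
          ms <- region_max_score(prof, threshold = params$min_score)
          profiles[[paste(lib$name, tid, k, region$anchor, sep = ":")]] <- prof
          if (!ms$pass) next
          dprofiles <- profile_for(tid)
          sigs <- lapply(dprofiles, detect_cleavage,
                         window = c(region$region_start - params$flank_tolerance,
                                    region$region_end),
                         min_rpm = params$min_rpm,
                         min_dominance = params$min_dominance,
                         eps = params$eps)
          has_sig <- any(vapply(sigs, nrow, integer(1)) > 0)
          if (!has_sig) next
          trig <- find_trigger(lib, tx, region, known_mirnas = known_mirnas,
                               max_score = params$max_trigger_score,
                               flank_tolerance = params$flank_tolerance)
          trig <- validate_trigger(trig, dprofiles,
                                   min_rpm = params$min_rpm,
                                   min_dominance = params$min_dominance,
                                   eps = params$eps, jitter = params$jitter)
          best <- if (any(trig$validated)) trig[trig$validated, ][1, , drop = FALSE]
                  else if (nrow(trig)) trig[1, , drop = FALSE] else NULL
          loci[[length(loci) + 1L]] <- data.frame(
            locus_id = tid, k = k, library = lib$name,
            anchor = region$anchor,
            region_start = region$region_start,
            region_end = region$region_end,
            n_occupied_tandem = region$n_occupied_tandem,
            max_phasing_score = ms$max_score,
            trigger_id = if (is.null(best)) NA_character_ else best$srna_id,
            trigger_sequence = if (is.null(best)) NA_character_ else best$srna_sequence,
            binding_start = if (is.null(best)) NA_integer_ else best$binding_start,
            binding_end = if (is.null(best)) NA_integer_ else best$binding_end,
            cleavage_site = if (is.null(best)) NA_integer_ else best$predicted_cleavage,
            trigger_validated = if (is.null(best)) FALSE else best$validated,
            validating_libraries = if (is.null(best)) "" else best$validating_libraries,
            stringsAsFactors = FALSE)

          mut <- mutant_libraries[[as.character(k)]]
          if (!is.null(mut)) {
            dcl_calls[[length(dcl_calls) + 1L]] <-
              cbind(call_dependence(region, tx, lib, normalize_rpm(mut),
                                    threshold = params$fold_threshold,
                                    eps = params$eps),
                    library = lib$name, stringsAsFactors = FALSE)
          }

          if (k == 21 && !is.null(best)) {
            ph_anchor <- if (!is.na(best$predicted_cleavage[1]))
              best$predicted_cleavage[1] else region$anchor
            ph <- enumerate_phasirnas(tx, ph_anchor, k,
                                      n_duplexes = region$n_occupied_tandem,
                                      side = "3'", library = lib)
            ph <- ph[ph$rpm > 0, , drop = FALSE]
            if (nrow(ph)) {
              phasirnas[[length(phasirnas) + 1L]] <- ph
              ints <- predict_targets(ph, transcripts,
                                      max_score = params$max_target_score,
                                      exclude = tid)
              if (nrow(ints)) {
                tprofiles <- unlist(lapply(unique(ints$target_id), profile_for),
                                    recursive = FALSE)
                ints <- validate_interactions(ints, tprofiles,
                                              min_rpm = params$min_rpm,
                                              min_dominance = params$min_dominance,
                                              eps = params$eps,
                                              jitter = params$jitter)
                interactions[[length(interactions) + 1L]] <- ints
              }
            }
          }
        }
      }
    }
  }

  bind <- function(lst) if (length(lst)) {
    r <- do.call(rbind, lst); rownames(r) <- NULL; r
  } else NULL
  loci_df <- bind(loci)
  if (!is.null(loci_df)) {
    # same locus found by several libraries: keep the best-scoring record
    loci_df <- loci_df[order(-loci_df$max_phasing_score), , drop = FALSE]
    key <- paste(loci_df$locus_id, loci_df$k, loci_df$anchor %% loci_df$k,
                 loci_df$region_start, loci_df$region_end)
    loci_df <- loci_df[!duplicated(key), , drop = FALSE]
    loci_df <- loci_df[order(loci_df$locus_id, loci_df$k, loci_df$region_start), ,
                       drop = FALSE]
    rownames(loci_df) <- NULL
  }
  ints_df <- bind(interactions)
  list(loci = loci_df %||% empty_loci(),
       regions = bind(all_regions) %||% NULL,
       score_profiles = profiles,
       phasirnas = bind(phasirnas),
       interactions = ints_df,
       network = if (!is.null(ints_df)) build_network_table(ints_df) else NULL,
       dcl_calls = bind(dcl_calls),
       log = params_log(params))
}

empty_loci <- function() {
  empty_df(locus_id = character(), k = integer(), library = character(),
           anchor = integer(), region_start = integer(),
           region_end = integer(), n_occupied_tandem = integer(),
           max_phasing_score = numeric(), trigger_id = character(),
           trigger_sequence = character(), binding_start = integer(),
           binding_end = integer(), cleavage_site = integer(),
           trigger_validated = logical(), validating_libraries = character())
}

#' Run the 24-nt phasiRNA / promoter methylation (RdDM) analysis
#'
#' Finds zero-mismatch binding sites of 24-nt phasiRNAs on promoters,
#' profiles per-cytosine CG/CHG/CHH methylation from bisulfite libraries
#' per tissue, computes target-gene expression per tissue, and tests the
#' RdDM consistency expectation (higher CHH methylation and lower target
#' expression in the phasiRNA-expressing tissue).
#'
#' @param promoters Promoter records ([read_fasta()] with
#'   `kind = "promoter"`).
#' @param phasirnas Data.frame with `name`, `sequence` (24-nt, RNA or DNA).
#' @param bisulfite_libraries Named list of `srna_library` keyed by tissue.
#' @param rnaseq_libraries Named list of `srna_library` keyed by tissue.
#' @param target_cdna Single cDNA record of the promoter's gene.
#' @param expressing_tissue Name of the tissue where the phasiRNAs are
#'   expressed (must be one of the library names).
#' @param params See [phas_params()] (unused thresholds are ignored).
#' @return A list: `hits`, `methylation` (per-tissue per-cytosine
#'   profiles), `context` (per-tissue context summaries), `expression`
#'   (named RPM vector), `comparison` (see [compare_tissues()], `NULL`
#'   with a warning when only one tissue is supplied), `log`.
#' @export
run_rddm <- function(promoters, phasirnas, bisulfite_libraries,
                     rnaseq_libraries, target_cdna,
                     expressing_tissue = names(bisulfite_libraries)[1],
                     params = phas_params()) {
  if (missing(promoters) || !nrow(promoters)) stop("no promoters supplied", call. = FALSE)
  if (!length(bisulfite_libraries)) stop("no bisulfite library supplied", call. = FALSE)
  if (!expressing_tissue %in% names(bisulfite_libraries)) {
    stop("expressing_tissue not among bisulfite libraries", call. = FALSE)
  }
  hits <- if (nrow(phasirnas)) find_promoter_hits(phasirnas, promoters)
          else find_promoter_hits(phasirnas[integer(0), , drop = FALSE], promoters)
  target_promoters <- if (nrow(hits)) unique(hits$promoter_id) else promoters$id[1]
  prom <- promoters[promoters$id == target_promoters[1], , drop = FALSE]

  methylation <- list(); context <- list()
  for (tissue in names(bisulfite_libraries)) {
    lib <- bisulfite_libraries[[tissue]]
    counts <- map_bisulfite_reads(lib, promoters)
    profile <- methylation_profile(counts, lib$total_count, prom)
    methylation[[tissue]] <- profile
    context[[tissue]] <- context_summary(profile)
  }
  expression <- vapply(rnaseq_libraries, function(lib) {
    expression_rpm(normalize_rpm(lib), target_cdna)
  }, numeric(1))

  comparison <- NULL
  others <- setdiff(names(bisulfite_libraries), expressing_tissue)
  if (length(others)) {
    other <- others[1]
    comparison <- compare_tissues(methylation[[expressing_tissue]],
                                  methylation[[other]],
                                  expression[[expressing_tissue]],
                                  expression[[other]],
                                  tissue_expressing = expressing_tissue,
                                  tissue_other = other)
  } else {
    warning("single tissue supplied: RdDM comparison skipped")
  }
  list(hits = hits, methylation = methylation, context = context,
       expression = expression, comparison = comparison,
       log = params_log(params))
}
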