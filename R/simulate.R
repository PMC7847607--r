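# Seeded generators that plant ground-truth phasiRNA biology into random
# sequence, emulating the library types the analysis consumes: phased
# 21-/24-nt reads on a planted locus with out-of-phase noise, degradome
# tag pileups at the trigger cleavage site, dcl-mutant libraries with
# thinned phasiRNAs, promoters carrying 24-mer complements, and bisulfite
# reads with context- and tissue-specific methylation.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a planted PHAS-locus scenario
#'
#' Builds one transcript carrying a phased locus among random background
#' transcripts. In-phase reads are drawn at every duplex (both strands,
#' minus strand at the k-3 offset of the 2-nt overhang geometry) with
#' Poisson depth; out-of-phase k-nt noise reads are added at `noise_rate`
#' times the in-phase read total; the trigger is a perfect complement of
#' the window ending 9 nt into the region, so its predicted cleavage site
#' equals the anchor; degradome tags pile up at that site over a sparse
#' unit background.
#'
#' @param k Cycle length, 21 or 24.
#' @param n_duplexes Planted occupied duplexes (>= 5).
#' @param depth Poisson mean read count per duplex strand.
#' @param noise_rate Out-of-phase read total as a fraction of the in-phase
#'   total.
#' @param n_background,background_length Decoy transcripts.
#' @param anchor Planted register origin on the locus transcript.
#' @param degradome_depth Poisson mean count of the cleavage-site tag.
#' @param degradome_background Number of unit background tags.
#' @param plant_locus When `FALSE`, a noise-only negative control is
#'   generated: no phased reads, no trigger, no cleavage pileup — only
#'   out-of-phase reads (at the volume the planted locus would have had)
#'   and degradome background.
#' @param seed Integer seed; same seed, identical scenario.
#' @param dir Optional directory: writes `transcripts.fasta`, `srna.tsv`,
#'   `degradome.tsv` and `manifest.json` there.
#' @return A list: `transcripts` (records), `srna` and `degradome`
#'   (normalized `srna_library`), `manifest` (ground truth).
#' @export
make_phas_scenario <- function(k = 21, n_duplexes = 8, depth = 20,
                               noise_rate = 0.1, n_background = 3,
                               background_length = 1500, anchor = 300,
                               degradome_depth = 50, degradome_background = 20,
                               plant_locus = TRUE, seed = 1, dir = NULL) {
  k <- check_k(k)
  if (n_duplexes < 5) stop("n_duplexes must be >= 5", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (noise_rate < 0) stop("noise_rate must be >= 0", call. = FALSE)
  if (anchor <= 12) stop("anchor must leave room for the trigger binding site", call. = FALSE)
  set.seed(seed)

  locus_len <- anchor + n_duplexes * k + 150L
  locus_id <- "PHAS_TX"
  tx_seqs <- c(rand_seq(locus_len),
               vapply(seq_len(n_background), function(i) rand_seq(background_length),
                      character(1)))
  tx_ids <- c(locus_id, sprintf("BG_TX%d", seq_len(n_background)))
  transcripts <- seq_records(tx_ids, tx_seqs, kind = "transcript")
  locus_seq <- transcripts$sequence[1]

  # trigger: perfect complement of the window whose position-10 cut is the anchor
  binding_end <- anchor + 9L
  binding_start <- binding_end - 20L
  trigger_dna <- revcomp(substr(locus_seq, binding_start, binding_end))

  seqs <- character(0); counts <- integer(0); phased <- character(0)
  if (plant_locus) {
    for (i in seq_len(n_duplexes)) {
      t <- anchor + (i - 1L) * k
      plus <- substr(locus_seq, t, t + k - 1L)
      minus <- revcomp(substr(locus_seq, t - 2L, t + k - 3L))
      for (s in c(plus, minus)) {
        cnt <- stats::rpois(1, depth)
        if (cnt > 0) {
          seqs <- c(seqs, s); counts <- c(counts, cnt)
          phased <- c(phased, s)
        }
      }
    }
  }
  in_phase_total <- if (plant_locus) sum(counts) else 2L * n_duplexes * depth
  n_noise <- round(noise_rate * in_phase_total)
  guard <- 0L
  while (n_noise > 0 && guard < 50L * n_noise) {
    guard <- guard + 1L
    ti <- sample.int(nrow(transcripts), 1)
    txs <- transcripts$sequence[ti]
    start <- sample.int(nchar(txs) - k + 1L, 1)
    strand <- sample(c("+", "-"), 1)
    if (ti == 1L) {
      fp <- if (strand == "+") start else start + k - 1L
      if (classify_phase(fp, strand, anchor, k)) next  # keep noise out of phase
    }
    s <- substr(txs, start, start + k - 1L)
    if (strand == "-") s <- revcomp(s)
    if (s %in% phased) next
    seqs <- c(seqs, s); counts <- c(counts, 1L)
    n_noise <- n_noise - 1L
  }
  if (plant_locus) {
    trig_count <- stats::rpois(1, depth) + 1L
    seqs <- c(seqs, trigger_dna); counts <- c(counts, trig_count)
  }
  srna <- normalize_rpm(srna_library(seqs, counts, name = sprintf("sim_srna_seed%d", seed)))

  cleavage_site <- anchor
  dseqs <- character(0); dcounts <- integer(0)
  if (plant_locus) {
    dseqs <- substr(locus_seq, cleavage_site, cleavage_site + 19L)
    dcounts <- stats::rpois(1, degradome_depth) + 1L
  }
  placed <- 0L
  while (placed < degradome_background) {
    ti <- sample.int(nrow(transcripts), 1)
    txs <- transcripts$sequence[ti]
    start <- sample.int(nchar(txs) - 19L, 1)
    if (ti == 1L && abs(start - cleavage_site) < 5L) next
    dseqs <- c(dseqs, substr(txs, start, start + 19L))
    dcounts <- c(dcounts, 1L)
    placed <- placed + 1L
  }
  degradome <- normalize_rpm(srna_library(dseqs, dcounts,
                                          name = sprintf("sim_degradome_seed%d", seed),
                                          min_len = 15, max_len = 30))

  manifest <- list(seed = seed, k = k, locus_id = locus_id, anchor = anchor,
                   plant_locus = plant_locus, n_duplexes = n_duplexes,
                   region_start = anchor,
                   region_end = anchor + n_duplexes * k - 1L,
                   trigger_sequence = to_rna(trigger_dna),
                   binding_start = binding_start, binding_end = binding_end,
                   cleavage_site = cleavage_site, depth = depth,
                   noise_rate = noise_rate,
                   phased_sequences = unique(phased))
  scenario <- list(transcripts = transcripts, srna = srna,
                   degradome = degradome, manifest = manifest)
  if (!is.null(dir)) write_phas_scenario(scenario, dir)
  scenario
}

write_phas_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(scenario$transcripts, file.path(dir, "transcripts.fasta"))
  write_srna_library(scenario$srna, file.path(dir, "srna.tsv"))
  write_srna_library(scenario$degradome, file.path(dir, "degradome.tsv"))
  jsonlite::write_json(scenario$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Thin phased reads to emulate a dcl-mutant library
#'
#' In-phase (planted phasiRNA) read counts are binomially thinned with
#' retention probability `depletion`; all other reads are untouched.
#' `depletion = 0` removes the phasiRNAs entirely, `depletion = 1` leaves
#' the library unchanged.
#'
#' @param wt A wild-type `srna_library`.
#' @param phased_sequences DNA sequences of the planted phasiRNAs
#'   (`manifest$phased_sequences`).
#' @param depletion Retention probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A new normalized `srna_library`.
#' @export
make_mutant_library <- function(wt, phased_sequences, depletion, seed = 1) {
  if (depletion < 0 || depletion > 1) {
    stop("depletion must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  reads <- wt$reads
  hit <- reads$sequence %in% to_dna(phased_sequences)
  reads$count[hit] <- stats::rbinom(sum(hit), reads$count[hit], depletion)
  reads <- reads[reads$count > 0, , drop = FALSE]
  normalize_rpm(srna_library(reads$sequence, reads$count,
                             name = paste0(wt$name, "_dclmut")))
}

#' Generate a planted RdDM scenario
#'
#' One promoter carries perfect reverse complements of a set of synthetic
#' 24-nt phasiRNAs at known coordinates. Bisulfite reads are drawn from
#' both strands with per-context, per-tissue methylation rates (an
#' unmethylated cytosine converts to T at `conversion` rate); RNA-seq
#' libraries give the target gene lower coverage in the
#' phasiRNA-expressing tissue.
#'
#' @param n_phasirnas Number of planted 24-mers.
#' @param promoter_length Promoter length in nt (>= 10 + 40 * n_phasirnas).
#' @param meth Named list of per-tissue context rates, e.g.
#'   `list(panicle = c(CG = .8, CHG = .4, CHH = .6), root = ...)`.
#' @param conversion Bisulfite conversion rate of unmethylated cytosines.
#' @param n_bis_reads Bisulfite reads per tissue.
#' @param read_length Bisulfite read length in nt.
#' @param expr_depth Named vector: RNA-seq reads covering the target per
#'   tissue.
#' @param expressing_tissue Tissue in which the phasiRNAs are expressed.
#' @param seed Integer seed.
#' @param dir Optional output directory (FASTA + TSVs + manifest).
#' @return A list: `promoters`, `phasirnas` (name/sequence), `bisulfite`
#'   and `rnaseq` (named library lists), `cdna`, `manifest`.
#' @export
make_rddm_scenario <- function(n_phasirnas = 5, promoter_length = 220,
                               meth = list(panicle = c(CG = 0.8, CHG = 0.4, CHH = 0.6),
                                           root = c(CG = 0.8, CHG = 0.4, CHH = 0.05)),
                               conversion = 1.0, n_bis_reads = 300,
                               read_length = 60,
                               expr_depth = c(panicle = 20, root = 200),
                               expressing_tissue = "panicle",
                               seed = 1, dir = NULL) {
  if (promoter_length < 10 + 40 * n_phasirnas) {
    stop("promoter too short for the requested number of planted sites", call. = FALSE)
  }
  if (conversion < 0 || conversion > 1) stop("conversion must be in [0, 1]", call. = FALSE)
  set.seed(seed)
  promoter <- seq_records("PROM_1", rand_seq(promoter_length), kind = "promoter")
  starts <- seq(10L, by = 40L, length.out = n_phasirnas)
  phas <- data.frame(
    name = phasirna_name("SYN_24PHAS", 1000L, 24L, "5'", seq_len(n_phasirnas), "+"),
    sequence = to_rna(revcomp(substr(rep(promoter$sequence, n_phasirnas),
                                     starts, starts + 23L))),
    stringsAsFactors = FALSE)
  hits <- data.frame(name = phas$name, start = starts, end = starts + 23L)

  ctx <- cytosine_table(promoter)
  ctx_key <- paste(ctx$position, ctx$strand)
  draw_bis <- function(rates) {
    seqs <- character(n_bis_reads)
    for (r in seq_len(n_bis_reads)) {
      s <- sample.int(promoter_length - read_length + 1L, 1)
      strand <- sample(c("+", "-"), 1)
      ref <- substr(promoter$sequence, s, s + read_length - 1L)
      chars <- strsplit(if (strand == "+") ref else revcomp(ref), "", fixed = TRUE)[[1]]
      for (j in which(chars == "C")) {
        pos <- if (strand == "+") s + j - 1L else s + read_length - j
        cx <- ctx$context[match(paste(pos, strand), ctx_key)]
        methylated <- stats::runif(1) < rates[[cx]]
        if (!methylated && stats::runif(1) < conversion) chars[j] <- "T"
      }
      seqs[r] <- paste(chars, collapse = "")
    }
    seqs
  }
  bisulfite <- lapply(names(meth), function(tissue) {
    normalize_rpm(srna_library(draw_bis(meth[[tissue]]), rep(1L, n_bis_reads),
                               name = paste0("bis_", tissue),
                               min_len = 1, max_len = 10 * read_length))
  })
  names(bisulfite) <- names(meth)

  cdna <- seq_records("TARGET_GENE", rand_seq(800), kind = "transcript")
  draw_rnaseq <- function(tissue) {
    n_t <- as.integer(expr_depth[[tissue]])
    s <- sample.int(800 - 49L, n_t, replace = TRUE)
    target_reads <- substr(rep(cdna$sequence, n_t), s, s + 49L)
    bg <- vapply(seq_len(100), function(i) rand_seq(50), character(1))
    normalize_rpm(srna_library(c(target_reads, bg),
                               rep(1L, n_t + 100L),
                               name = paste0("rnaseq_", tissue),
                               min_len = 1, max_len = 100))
  }
  rnaseq <- lapply(names(expr_depth), draw_rnaseq)
  names(rnaseq) <- names(expr_depth)

  manifest <- list(seed = seed, n_phasirnas = n_phasirnas,
                   promoter_id = "PROM_1", hits = hits, meth = meth,
                   conversion = conversion,
                   expr_depth = as.list(expr_depth),
                   expressing_tissue = expressing_tissue)
  scenario <- list(promoters = promoter, phasirnas = phas,
                   bisulfite = bisulfite, rnaseq = rnaseq, cdna = cdna,
                   manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(promoter, file.path(dir, "promoters.fasta"))
    write_fasta(cdna, file.path(dir, "target_cdna.fasta"))
    for (tissue in names(bisulfite)) {
      write_srna_library(bisulfite[[tissue]],
                         file.path(dir, paste0("bisulfite_", tissue, ".tsv")))
      write_srna_library(rnaseq[[tissue]],
                         file.path(dir, paste0("rnaseq_", tissue, ".tsv")))
    }
    utils::write.table(phas, file.path(dir, "phasirnas.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  scenario
}
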