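test_that("promoter hits are exact 24-mer complements (or identical copies)", {
  set.seed(14)
  phas <- data.frame(name = "p24", sequence = "AUCAUGACUUGGGUAUUACGUUUC",
                     stringsAsFactors = FALSE)
  dna <- chartr("U", "T", phas$sequence)
  before <- random_dna(110)
  prom_seq <- paste0(before, rc(dna), random_dna(66))
  prom <- seq_records("prom1", prom_seq, kind = "promoter")
  hits <- find_promoter_hits(phas, prom)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 111)
  expect_equal(hits$end, 134)
  expect_equal(hits$orientation, "complementary")

  # identical-strand occurrence is reported under its own flag
  prom2 <- seq_records("prom2", paste0(random_dna(50), dna, random_dna(50)),
                       kind = "promoter")
  hits2 <- find_promoter_hits(phas, prom2)
  expect_equal(hits2$orientation, "identical")
  expect_equal(hits2$start, 51)

  none <- seq_records("prom3", random_dna(200), kind = "promoter")
  expect_equal(nrow(find_promoter_hits(phas, none)), 0)
})

test_that("cytosine contexts follow the trinucleotide rule on both strands", {
  expect_equal(classify_context("ACGTA", 2), "CG")
  expect_equal(classify_context("ACAGT", 2), "CHG")
  expect_equal(classify_context("ACATT", 2), "CHH")
  expect_error(classify_context("ACGTA", 1), "not C")
  # truncated 3' triplets default to CHH unless the CG base is present
  expect_equal(classify_context("AAC", 3), "CHH")
  expect_equal(classify_context("AACG", 3), "CG")
  expect_equal(classify_context("AACT", 3), "CHH")
  # minus strand reads 3' leftwards through the complement
  expect_equal(classify_context("CGTTT", 2, "-"), "CG")    # minus C at 2, next G at 1
  expect_equal(classify_context("ACGTT", 3, "-"), "CG")
  expect_equal(classify_context("CAGTT", 3, "-"), "CHG")
  expect_equal(classify_context("TTGTT", 3, "-"), "CHH")
})

test_that("context classification partitions all cytosines", {
  for (seed in 1:5) {
    set.seed(seed)
    prom <- seq_records("p", random_dna(300), kind = "promoter")
    ctab <- phasloc:::cytosine_table(prom)
    chars <- strsplit(prom$sequence, "")[[1]]
    expect_equal(nrow(ctab), sum(chars == "C") + sum(chars == "G"))
    expect_true(all(ctab$context %in% c("CG", "CHG", "CHH")))
  }
})

test_that("bisulfite reads map under three-letter collapse, uniquely", {
  set.seed(15)
  prom <- seq_records("p1", random_dna(200), kind = "promoter")
  intact <- substr(prom$sequence, 1, 50)
  converted <- chartr("C", "T", intact)
  lib <- srna_library(c(intact, converted), c(2, 3), min_len = 1, max_len = 100)
  counts <- map_bisulfite_reads(lib, prom)
  covered_c <- counts[counts$strand == "+", ]
  # intact read contributes methylated evidence, converted read unmethylated
  expect_true(all(covered_c$meth_count == 2))
  expect_true(all(covered_c$total_count == 5))

  # a read matching two promoters is discarded as non-unique
  twoproms <- seq_records(c("a", "b"),
                          c(prom$sequence, paste0(substr(prom$sequence, 1, 60),
                                                  random_dna(100))),
                          kind = "promoter")
  lib2 <- srna_library(substr(prom$sequence, 1, 40), 5, min_len = 1, max_len = 100)
  expect_equal(nrow(map_bisulfite_reads(lib2, twoproms)), 0)
})

test_that("three-letter placement agrees with a brute-force scan", {
  for (seed in 1:4) {
    set.seed(seed)
    prom <- seq_records("p", random_dna(400), kind = "promoter")
    s <- sample(350, 1)
    read <- substr(prom$sequence, s, s + 39)
    # convert a random subset of cytosines
    chars <- strsplit(read, "")[[1]]
    cs <- which(chars == "C")
    conv <- cs[sample(c(TRUE, FALSE), length(cs), replace = TRUE)]
    chars[conv] <- "T"
    read <- paste(chars, collapse = "")
    variant <- if (seed %% 2 == 0) rc(read) else read
    got <- phasloc:::bisulfite_placements(variant, prom)
    got_key <- sort(paste(got$start, got$strand))
    want <- oracle_bisulfite_sites(variant, prom$sequence)
    want_key <- sort(paste(want[, 1], ifelse(want[, 2] > 0, "+", "-")))
    expect_equal(got_key, want_key)
  }
})

test_that("methylation profiles convert counts to library-scaled RPM", {
  prom <- seq_records("p", "AACGAA", kind = "promoter")  # one CG cytosine at 3
  counts <- data.frame(promoter_id = "p", position = 3L, strand = "+",
                       meth_count = 2L, total_count = 4L,
                       stringsAsFactors = FALSE)
  prof <- methylation_profile(counts, library_total = 4, promoter = prom)
  row <- prof[prof$position == 3 & prof$strand == "+", ]
  expect_equal(row$context, "CG")
  expect_equal(row$methylated_rpm, 5e5)
  expect_equal(row$total_rpm, 1e6)
  expect_equal(row$fraction, 0.5)
  expect_error(methylation_profile(counts, 0, prom), "library_total")
  # context totals equal the sum over member cytosines
  cs <- context_summary(prof)
  expect_equal(sum(cs$methylated_rpm), sum(prof$methylated_rpm))
  expect_equal(sum(cs$n_cytosines), nrow(prof))
})

test_that("generator extremes: no methylation means zero methylated RPM everywhere", {
  zero <- make_rddm_scenario(
    meth = list(panicle = c(CG = 0, CHG = 0, CHH = 0),
                root = c(CG = 0, CHG = 0, CHH = 0)),
    conversion = 1, seed = 22)
  counts <- map_bisulfite_reads(zero$bisulfite$panicle, zero$promoters)
  prof <- methylation_profile(counts, zero$bisulfite$panicle$total_count,
                              zero$promoters)
  expect_true(all(prof$methylated_rpm == 0))

  full <- make_rddm_scenario(
    meth = list(panicle = c(CG = 1, CHG = 1, CHH = 1),
                root = c(CG = 1, CHG = 1, CHH = 1)),
    conversion = 1, seed = 23)
  counts2 <- map_bisulfite_reads(full$bisulfite$panicle, full$promoters)
  prof2 <- methylation_profile(counts2, full$bisulfite$panicle$total_count,
                               full$promoters)
  expect_equal(prof2$methylated_rpm, prof2$total_rpm)
})

test_that("expression is the summed RPM of exactly matching reads", {
  set.seed(16)
  cdna <- seq_records("g1", random_dna(500))
  matching <- substr(rep(cdna$sequence, 3), c(10, 100, 300), c(39, 129, 329))
  filler <- random_dna(30)
  lib <- normalize_rpm(srna_library(c(matching, filler),
                                    c(1, 1, 1, 999997), min_len = 1, max_len = 50))
  expect_equal(expression_rpm(lib, cdna), 3.0)
  nohit <- normalize_rpm(srna_library(random_dna(30), 10, min_len = 1, max_len = 50))
  expect_equal(expression_rpm(nohit, cdna), 0)
})

test_that("RdDM consistency needs higher CHH and lower expression together", {
  prof_hi <- data.frame(context = c("CG", "CHH", "CHH"),
                        methylated_rpm = c(5, 40, 30), total_rpm = c(10, 50, 40))
  prof_lo <- data.frame(context = c("CG", "CHH", "CHH"),
                        methylated_rpm = c(5, 2, 1), total_rpm = c(10, 50, 40))
  expect_true(compare_tissues(prof_hi, prof_lo, 10, 100)$consistent)
  expect_false(compare_tissues(prof_hi, prof_hi, 10, 100)$consistent)  # equal CHH
  expect_false(compare_tissues(prof_hi, prof_lo, 100, 10)$consistent)  # expr wrong way
})
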