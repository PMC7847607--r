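test_that("phasiRNA D-position names round-trip through the grammar", {
  tx <- seq_records("LOC_test.1", random_dna(700))
  ph <- enumerate_phasirnas(tx, anchor = 189, k = 21, n_duplexes = 6)
  parsed <- parse_phasirna_name(ph$name)
  expect_equal(parsed$locus_id, ph$locus_id)
  expect_equal(parsed$anchor, ph$anchor)
  expect_equal(parsed$k, ph$k)
  expect_equal(parsed$side, ph$side)
  expect_equal(parsed$index, ph$index)
  expect_equal(parsed$strand, ph$strand)

  # printed typographic variants parse too
  v <- parse_phasirna_name(c("LOC_Os02g18750.1(189)21 3’D26 (+)",
                             "LOC_Os01g37325.1(1684) 24 5’D12(+)",
                             "LOC_Os06g30680.1(62)21 3′ D2(+)"))
  expect_equal(v$index, c(26L, 12L, 2L))
  expect_equal(v$k, c(21L, 24L, 21L))
  expect_equal(v$side, c("3'", "5'", "3'"))
  expect_error(parse_phasirna_name("not a name"), "unparseable")
})

test_that("enumeration walks the register grid with the 2-nt offset", {
  set.seed(6)
  tx <- seq_records("LOC_x", random_dna(400))
  s <- tx$sequence
  ph <- enumerate_phasirnas(tx, anchor = 189, k = 21, n_duplexes = 2)
  get <- function(i, strand) ph$sequence[ph$index == i & ph$strand == strand]
  expect_equal(get(1, "+"), chartr("T", "U", substr(s, 189, 209)))
  expect_equal(get(2, "+"), chartr("T", "U", substr(s, 210, 230)))
  expect_equal(get(1, "-"), chartr("T", "U", rc(substr(s, 187, 207))))

  # 5' side counts upstream from the anchor
  up <- enumerate_phasirnas(tx, anchor = 189, k = 21, n_duplexes = 2, side = "5'")
  expect_equal(up$sequence[up$index == 1 & up$strand == "+"],
               chartr("T", "U", substr(s, 168, 188)))
  expect_error(enumerate_phasirnas(tx, anchor = 999, k = 21, n_duplexes = 2),
               "anchor off transcript")
})

test_that("enumerated phasiRNAs pick up abundance from the library", {
  set.seed(12)
  tx <- seq_records("LOC_y", random_dna(400))
  d1 <- substr(tx$sequence, 100, 120)
  lib <- normalize_rpm(srna_library(c(d1, random_dna(21)), c(40, 60)))
  ph <- enumerate_phasirnas(tx, anchor = 100, k = 21, n_duplexes = 3,
                            library = lib)
  expect_equal(ph$rpm[ph$index == 1 & ph$strand == "+"], 4e5)
  expect_true(all(ph$rpm[ph$index > 1] == 0))
})

test_that("target prediction finds planted complements and applies the cut rule", {
  set.seed(30)
  phas_seq <- random_dna(21)
  decoy1 <- random_dna(900)
  site <- 300
  decoy2 <- paste0(substr(random_dna(900), 1, site - 1), rc(phas_seq),
                   random_dna(200))
  txs <- seq_records(c("d1", "d2"), c(decoy1, decoy2))
  ph <- data.frame(name = "syn 3'D1(+)", sequence = chartr("T", "U", phas_seq),
                   rpm = 10, stringsAsFactors = FALSE)
  ints <- predict_targets(ph, txs)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$target_id, "d2")
  expect_equal(ints$score, 0)
  expect_equal(ints$miru_start, site)
  expect_equal(ints$miru_end, site + 20)
  expect_equal(ints$predicted_cut, ints$miru_end - 9)

  # an undetected phasiRNA (rpm 0) is not recruited
  ph0 <- ph; ph0$rpm <- 0
  expect_equal(nrow(predict_targets(ph0, txs)), 0)
})

test_that("interaction validation needs an exact degradome peak at the cut", {
  set.seed(31)
  phas_seq <- random_dna(21)
  target <- paste0(random_dna(499), rc(phas_seq), random_dna(200))
  txs <- seq_records("tg", target)
  ints <- predict_targets(
    data.frame(name = "p1", sequence = phas_seq, rpm = 5), txs)
  cut <- ints$predicted_cut[1]
  peak_lib <- normalize_rpm(srna_library(
    c(substr(target, cut, cut + 19), substr(target, 50, 69)), c(30, 1),
    name = "degV"))
  off_lib <- normalize_rpm(srna_library(
    c(substr(target, cut + 3, cut + 22), substr(target, 50, 69)), c(30, 1),
    name = "degO"))
  v <- validate_interactions(ints, list(build_profile(peak_lib, txs[1, ])))
  expect_true(v$validated[1])
  o <- validate_interactions(ints, list(build_profile(off_lib, txs[1, ])))
  expect_false(o$validated[1])
})

test_that("the network edge table deduplicates and survives empty input", {
  ints <- data.frame(phasirna = c("p1", "p1", "p2"),
                     target_id = c("t1", "t1", "t2"),
                     miru_start = c(10L, 10L, 5L), miru_end = c(30L, 30L, 25L),
                     score = c(0, 0, 1), predicted_cut = c(21L, 21L, 16L),
                     validated = c(TRUE, TRUE, FALSE),
                     validating_libraries = c("a", "a", ""),
                     stringsAsFactors = FALSE)
  net <- build_network_table(ints, annotations = data.frame(
    id = "t1", annotation = "kinase", stringsAsFactors = FALSE))
  expect_equal(nrow(net), 1)  # duplicate edge collapsed, unvalidated dropped
  expect_equal(net$target_annotation, "kinase")
  empty <- build_network_table(ints[0, , drop = FALSE])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("phasirna", "target_id", "score") %in% names(empty)))
})

test_that("reference interaction intervals all satisfy the cut-site invariants", {
  tab <- reference_tasirna_targets()
  expect_equal(nrow(tab), 41)
  expect_true(all(tab$cut_site >= tab$miru_start & tab$cut_site <= tab$miru_end))
  parsed <- parse_phasirna_name(tab$tasirna_id)
  expect_true(all(parsed$k == 21))
  expect_true(all(nchar(tab$tasirna_sequence) == 21))
})
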