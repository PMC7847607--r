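test_that("reads map exactly on both strands with correct 5' geometry", {
  set.seed(1)
  tx <- seq_records("t1", random_dna(500))
  probe <- substr(tx$sequence, 100, 120)
  lib <- normalize_rpm(srna_library(c(probe, rc(probe)), c(4, 6)))
  pl <- map_reads(lib, tx)
  plus <- pl[pl$strand == "+", ]
  minus <- pl[pl$strand == "-", ]
  # probe matches sense at 100; its revcomp therefore maps antisense there too
  expect_true(any(plus$start == 100 & plus$five_prime_pos == 100))
  expect_true(any(minus$start == 100 & minus$five_prime_pos == 120))
})

test_that("multi-copy reads yield one placement per occurrence (oracle check)", {
  unit <- random_dna(30)
  tx <- seq_records("rep", paste0(unit, random_dna(40), unit, random_dna(30)))
  probe <- substr(unit, 3, 23)
  lib <- normalize_rpm(srna_library(probe, 5))
  pl <- map_reads(lib, tx)
  expect_equal(nrow(pl[pl$strand == "+", ]), 2)
  expect_equal(sort(pl$start[pl$strand == "+"]),
               oracle_find_all(tx$sequence, probe))

  set.seed(7)
  for (i in 1:5) {
    tx2 <- seq_records("t", random_dna(300))
    start <- sample(280, 1)
    r <- substr(tx2$sequence, start, start + 20)
    pl2 <- map_reads(normalize_rpm(srna_library(r, 1)), tx2)
    expect_equal(sort(pl2$start[pl2$strand == "+"]),
                 oracle_find_all(tx2$sequence, r))
    expect_equal(sort(pl2$start[pl2$strand == "-"]),
                 oracle_find_all(tx2$sequence, rc(r)))
  }
})

test_that("phase classification follows the 2-nt overhang duplex geometry", {
  anchor <- 101
  expect_true(classify_phase(anchor + 2 * 21, "+", anchor, 21))
  expect_true(classify_phase(anchor + 21 - 3, "-", anchor, 21))
  expect_false(classify_phase(anchor + 11, "+", anchor, 21))
  expect_error(classify_phase(100, "+", 1, 22), "21 or 24")

  # invariance under anchor shifts by whole cycles
  for (k in c(21, 24)) {
    pos <- sample(500, 20)
    strands <- sample(c("+", "-"), 20, replace = TRUE)
    base <- classify_phase(pos, strands, anchor, k)
    for (shift in c(-3, -1, 1, 5)) {
      expect_equal(classify_phase(pos, strands, anchor + shift * k, k), base)
    }
  }
})

test_that("candidate regions are maximal runs of tandem occupied duplexes", {
  tx <- seq_records("t1", random_dna(400))
  # six consecutive registers, anchor 101
  pl <- placement_df(seq(101, by = 21, length.out = 6), rep("+", 6),
                     transcript_id = "t1")
  regs <- find_candidate_regions(pl, tx, 21)
  expect_equal(nrow(regs), 1)
  expect_equal(regs$anchor, 101)
  expect_equal(regs$region_start, 101)
  expect_equal(regs$region_end, 226)
  expect_equal(regs$n_occupied_tandem, 6)

  # a hole splits the run below the threshold
  holed <- pl[-3, ]
  expect_equal(nrow(find_candidate_regions(holed, tx, 21)), 0)

  # exactly five tandem duplexes is accepted (boundary)
  five <- placement_df(seq(101, by = 21, length.out = 5), rep("+", 5))
  expect_equal(find_candidate_regions(five, tx, 21)$n_occupied_tandem, 5)
  # and four is not
  four <- placement_df(seq(101, by = 21, length.out = 4), rep("+", 4))
  expect_equal(nrow(find_candidate_regions(four, tx, 21)), 0)
})

test_that("minus-strand occupancy counts through the k-3 offset", {
  tx <- seq_records("t1", random_dna(400))
  # registers alternate sense / antisense evidence
  regs_pos <- seq(50, by = 21, length.out = 6)
  strands <- rep(c("+", "-"), 3)
  fpp <- ifelse(strands == "+", regs_pos, regs_pos + 21 - 3)
  pl <- placement_df(fpp, strands)
  regs <- find_candidate_regions(pl, tx, 21)
  expect_equal(regs$n_occupied_tandem, 6)
  expect_equal(regs$anchor, 50)
})

test_that("region detection agrees with a brute-force oracle on random cases", {
  for (seed in 1:6) {
    set.seed(seed)
    k <- sample(c(21L, 24L), 1)
    txlen <- sample(800:2000, 1)
    tx <- seq_records("t1", random_dna(txlen))
    anchor <- sample(50:150, 1)
    n_run <- sample(3:9, 1)
    occupied <- anchor + k * (seq_len(n_run) - 1)
    occupied <- occupied[sample(c(TRUE, FALSE), n_run, replace = TRUE, prob = c(.8, .2))]
    noise_fpp <- sample(txlen - k, 15)
    strands <- sample(c("+", "-"), length(occupied) + 15, replace = TRUE)
    fpp <- c(ifelse(strands[seq_along(occupied)] == "+", occupied, occupied + k - 3),
             noise_fpp)
    pl <- placement_df(fpp, strands, k = k)
    pl <- pl[pl$five_prime_pos >= 1 &
               pl$five_prime_pos - ifelse(pl$strand == "+", 0, k - 3) + k - 1 <= txlen, ]
    got <- find_candidate_regions(pl, tx, k)
    want <- oracle_regions(pl, txlen, k)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$region_start, want$region_start)
      expect_equal(got$region_end, want$region_end)
      expect_equal(got$n_occupied_tandem, want$n)
    }
  }
})

test_that("region hulls merge runs within one residue class", {
  tx <- seq_records("t1", random_dna(600))
  fpp <- c(seq(10, by = 21, length.out = 5), seq(10 + 21 * 7, by = 21, length.out = 5))
  pl <- placement_df(fpp, rep("+", 10))
  regs <- find_candidate_regions(pl, tx, 21)
  expect_equal(nrow(regs), 2)
  hull <- region_hull(regs)
  expect_equal(nrow(hull), 1)
  expect_equal(hull$region_start, 10)
  expect_equal(hull$region_end, max(regs$region_end))
  expect_equal(hull$n_occupied_tandem, 10)
})
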