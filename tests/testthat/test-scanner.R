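test_that("find_coordination_sites reports all and only C/H/Y positions", {
  rec <- protein_record("t", "AHAYACA")
  sites <- find_coordination_sites(rec)
  expect_equal(sites$position, c(2L, 4L, 6L))
  expect_equal(sites$ligand, c("H", "Y", "C"))
  expect_equal(nrow(find_coordination_sites(protein_record("t", "AGLVFW"))), 0)
  expect_equal(find_coordination_sites(protein_record("t", "ACA"))$position, 2L)
})

test_that("site finding agrees with a brute-force character scan", {
  set.seed(101)
  for (i in 1:50) {
    s <- random_sequence(sample(1:80, 1))
    rec <- protein_record("t", s)
    expect_equal(find_coordination_sites(rec)$position, oracle_sites(s))
    expect_length(scan_record(rec), length(oracle_sites(s)))
  }
})

test_that("extract_window takes 4 residues each side and flags truncation", {
  w <- make_window("AAAACAAAA", 5)
  expect_equal(w$sequence, "AAAACAAAA")
  expect_equal(w$center_offset, 4L)
  expect_false(w$left_truncated)
  expect_false(w$right_truncated)

  w <- make_window("ACAAAAAAA", 2)
  expect_equal(w$sequence, "ACAAAA")
  expect_equal(w$center_offset, 1L)
  expect_true(w$left_truncated)
  expect_false(w$right_truncated)

  # terminal site: single-sided window
  w <- make_window("CAAAAA", 1)
  expect_equal(w$sequence, "CAAAA")
  expect_equal(w$center_offset, 0L)
})

test_that("window invariants hold over random sequences", {
  set.seed(102)
  for (i in 1:40) {
    s <- random_sequence(sample(1:60, 1))
    rec <- protein_record("t", s)
    for (w in scan_record(rec)) {
      expect_lte(nchar(w$sequence), 9L)
      expect_equal(nchar(w$sequence) == 9L,
                   !w$left_truncated && !w$right_truncated)
      expect_equal(substr(w$sequence, w$center_offset + 1, w$center_offset + 1),
                   w$ligand)
      # window content equals the corresponding slice of the record
      lo <- w$position - w$center_offset
      expect_equal(w$sequence,
                   substr(s, lo, lo + nchar(w$sequence) - 1))
      if (nrow(w$ancillary_sites) > 0) {
        idx <- w$ancillary_sites$offset + w$center_offset + 1
        expect_equal(substring(w$sequence, idx, idx), w$ancillary_sites$ligand)
        expect_true(all(w$ancillary_sites$offset != 0))
      }
    }
  }
})

test_that("extract_window rejects non-site positions", {
  rec <- protein_record("t", "AACAA")
  expect_error(extract_window(rec, 1), "not a coordination site")
  expect_error(extract_window(rec, 99), "outside")
})

test_that("net charge counts K/R as +1 and D/E as -1, His neutral", {
  expect_equal(net_charge("AAAACAAAA"), 0L)
  expect_equal(net_charge("RKAACAAAA"), 2L)
  expect_equal(net_charge("DEAACAAKR"), 0L)
  expect_equal(net_charge("HHHHH"), 0L)
  set.seed(103)
  for (i in 1:40) {
    s <- random_sequence(sample(1:30, 1))
    expect_equal(net_charge(s), oracle_charge(s))
    s2 <- random_sequence(sample(1:30, 1))
    expect_equal(net_charge(paste0(s, s2)), net_charge(s) + net_charge(s2))
  }
})

test_that("CP detection requires Cys at P0 with Pro at +1", {
  expect_true(detect_cp(make_window("AAAACPAAA", 5)))
  expect_false(detect_cp(make_window("AAAAHAAAA", 5)))
  expect_false(detect_cp(make_window("AAAAC", 5)))       # no +1 residue
  expect_false(detect_cp(make_window("AAAACAPAA", 5)))   # P not adjacent
  w <- make_window("AAAACPAAA", 5)
  expect_equal(substr(w$sequence, w$center_offset + 1, w$center_offset + 2), "CP")
})

test_that("ancillary sites are in-window C/H/Y at nonzero offsets", {
  expect_equal(nrow(make_window("AAAACAAAA", 5)$ancillary_sites), 0)
  anc <- make_window("HAAACAAAA", 5)$ancillary_sites
  expect_equal(anc$ligand, "H")
  expect_equal(anc$offset, -4L)
  anc <- make_window("YAAAHAAAY", 5)$ancillary_sites
  expect_equal(anc$ligand, c("Y", "Y"))
  expect_equal(anc$offset, c(-4L, 4L))
})

test_that("a class II HXXXC peptide shows the 3-residue spacer geometry", {
  # the distal His sits at offset -4 from the central Cys, leaving a spacer
  # of three residues between the two coordinating side chains
  w <- make_window("HAAACAAAA", 5)
  anc <- w$ancillary_sites
  expect_equal(anc$ligand, "H")
  expect_equal(anc$offset, -4L)
  expect_equal(abs(anc$offset) - 1L, 3L)
})
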