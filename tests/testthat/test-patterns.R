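test_that("parse_pattern reads the PROSITE element dialect", {
  p <- parse_pattern("C-P")
  expect_length(p$elements, 2)
  expect_equal(p$elements[[1]], list(kind = "fixed", residues = "C",
                                     min = 1L, max = 1L))

  p <- parse_pattern("[HY]-x(3)-C")
  expect_equal(p$elements[[1]]$kind, "set")
  expect_setequal(p$elements[[1]]$residues, c("H", "Y"))
  expect_equal(p$elements[[2]][c("kind", "min", "max")],
               list(kind = "wild", min = 3L, max = 3L))

  p <- parse_pattern("C-x(2,4)-{P}.")
  expect_equal(p$elements[[2]][c("min", "max")], list(min = 2L, max = 4L))
  expect_equal(p$elements[[3]]$kind, "exclude")
  expect_equal(p$elements[[3]]$residues, "P")

  p <- parse_pattern("<A-x-G>")
  expect_true(p$anchored_start)
  expect_true(p$anchored_end)

  # case-insensitive
  expect_equal(parse_pattern("c-p")$elements,
               parse_pattern("C-P")$elements)
})

test_that("parse_pattern rejects malformed patterns with offsets", {
  expect_error(parse_pattern("C--P"), "empty element")
  expect_error(parse_pattern("C-[HY"), "malformed")
  expect_error(parse_pattern("C-x(4,2)"), "bad repeat")
  expect_error(parse_pattern("C-x(0)"), "bad repeat")
  expect_error(parse_pattern(""), "empty pattern")
  expect_error(parse_pattern("C-P!"), "offset 3")
})

test_that("match_pattern handles the documented examples", {
  hits <- match_pattern("C-P", protein_record("t", "ACPA"))
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 3L)
  expect_equal(hits$match, "CP")

  hits <- match_pattern("[HY]-x(3)-C", protein_record("t", "AHAAACA"))
  expect_equal(hits[, c("start", "end")], data.frame(start = 2L, end = 6L))

  expect_equal(nrow(match_pattern("<A", protein_record("t", "BAB"))), 0)
  expect_equal(match_pattern("<B", protein_record("t", "BAB"))$start, 1L)
  expect_equal(match_pattern("B>", protein_record("t", "BAB"))$start, 3L)
})

test_that("ranged repeats report the shortest match at each start", {
  hits <- match_pattern("C-x(1,3)-H", protein_record("t", "CAHAH"))
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 3L)  # CAH, not CAHAH
})

test_that("an all-fixed pattern matches exactly its substring occurrences", {
  set.seed(107)
  for (i in 1:20) {
    s <- random_sequence(sample(10:50, 1))
    k <- sample(2:3, 1)
    sub <- random_sequence(k)
    pat <- paste(strsplit(sub, "")[[1]], collapse = "-")
    hits <- match_pattern(pat, protein_record("t", s))
    expected <- unlist(gregexpr(sub, s, fixed = TRUE))
    expected <- expected[expected > 0]
    # gregexpr reports non-overlapping matches only; recover all starts
    expected <- which(vapply(seq_len(nchar(s) - k + 1), function(j) {
      substr(s, j, j + k - 1) == sub
    }, logical(1)))
    expect_equal(hits$start, as.integer(expected))
  }
})

test_that("sequence 'X' satisfies only wildcard elements", {
  rec <- protein_record("t", "AXA")
  expect_equal(nrow(match_pattern("A-A", rec)), 0)
  expect_equal(match_pattern("A-x-A", rec)$start, 1L)
  expect_equal(nrow(match_pattern("[AX]", rec)), 2)  # the two A positions
  expect_equal(nrow(match_pattern("{Z}", rec)), 2)
})

test_that("matcher agrees with the brute-force substring oracle", {
  set.seed(108)
  n_pairs <- 400
  for (i in seq_len(n_pairs)) {
    s <- random_sequence(sample(1:50, 1),
                         alphabet = c(std20[1:8], "X", "H", "Y", "C", "P"))
    pat <- parse_pattern(random_pattern_text())
    rec <- protein_record("t", s)
    got <- match_pattern(pat, rec)
    want <- oracle_match(pat, s)
    expect_equal(got$start, want$start,
                 info = sprintf("pattern %s on %s", pat$source_text, s))
    expect_equal(got$end, want$end,
                 info = sprintf("pattern %s on %s", pat$source_text, s))
  }
})

test_that("scan_database concatenates per-record hits deterministically", {
  recs <- list(protein_record("r1", "ACPAACP"), protein_record("r2", "CPAA"),
               protein_record("r3", "AAAA"))
  tab <- scan_database(list("C-P"), recs)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$record_id, c("r1", "r1", "r2"))
  expect_equal(tab$start, c(2L, 6L, 1L))

  expect_equal(nrow(scan_database(list("C-P"), list())), 0)

  # composition: database rows for one pattern equal match_pattern
  multi <- scan_database(list("C-P", "A-A"), recs)
  for (r in recs) {
    sub <- multi[multi$record_id == r$identifier & multi$pattern == "C-P", ]
    expect_equal(sub$start, match_pattern("C-P", r)$start)
  }
})
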