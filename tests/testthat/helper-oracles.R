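# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-derivations, kept separate from the package code
# paths they check.

std20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")

random_sequence <- function(len, alphabet = std20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Oracle: coordination-site positions by plain character comparison.
oracle_sites <- function(residues, ligands = c("C", "H", "Y")) {
  chars <- strsplit(residues, "")[[1]]
  out <- integer(0)
  for (i in seq_along(chars)) if (chars[i] %in% ligands) out <- c(out, i)
  out
}

# Oracle: net charge by explicit per-residue lookup.
oracle_charge <- function(residues) {
  chars <- strsplit(residues, "")[[1]]
  total <- 0L
  for (ch in chars) {
    if (ch %in% c("K", "R")) total <- total + 1L
    if (ch %in% c("D", "E")) total <- total - 1L
  }
  total
}

# Oracle: PROSITE matching by exhaustive substring checking. A substring
# matches iff the element list can consume it exactly; per start the
# smallest matching end is reported.
oracle_residue_ok <- function(res, elem) {
  if (elem$kind == "wild") return(TRUE)
  if (res == "X") return(FALSE)
  switch(elem$kind,
         fixed = res == elem$residues,
         set = res %in% elem$residues,
         exclude = !(res %in% elem$residues))
}

oracle_exact <- function(chars, elements) {
  if (length(elements) == 0L) return(length(chars) == 0L)
  e <- elements[[1]]
  for (cnt in e$min:e$max) {
    if (cnt > length(chars)) break
    ok <- TRUE
    for (j in seq_len(cnt)) {
      if (!oracle_residue_ok(chars[j], e)) { ok <- FALSE; break }
    }
    if (ok && oracle_exact(chars[-seq_len(cnt)], elements[-1]))
      return(TRUE)
  }
  FALSE
}

oracle_match <- function(pattern, residues) {
  chars <- strsplit(residues, "")[[1]]
  n <- length(chars)
  starts <- if (pattern$anchored_start) 1L else seq_len(n)
  hits <- data.frame(start = integer(0), end = integer(0))
  for (s in starts) {
    ends <- if (pattern$anchored_end) n else s:n
    ends <- ends[ends >= s]
    for (e in sort(ends)) {
      if (oracle_exact(chars[s:e], pattern$elements)) {
        hits <- rbind(hits, data.frame(start = s, end = e))
        break
      }
    }
  }
  hits
}

# Random small PROSITE pattern drawn as text.
random_pattern_text <- function(max_elements = 4L) {
  n_elem <- sample(1:max_elements, 1)
  elems <- vapply(seq_len(n_elem), function(i) {
    kind <- sample(c("fixed", "set", "exclude", "wild"), 1,
                   prob = c(0.35, 0.2, 0.15, 0.3))
    body <- switch(kind,
                   fixed = sample(std20, 1),
                   set = paste0("[", paste(sample(std20, sample(2:3, 1)),
                                           collapse = ""), "]"),
                   exclude = paste0("{", paste(sample(std20, sample(1:2, 1)),
                                               collapse = ""), "}"),
                   wild = "x")
    rep_suffix <- sample(c("", "(2)", "(1,2)", "(2,3)"), 1,
                         prob = c(0.6, 0.15, 0.15, 0.1))
    paste0(body, rep_suffix)
  }, character(1))
  txt <- paste(elems, collapse = "-")
  if (stats::runif(1) < 0.1) txt <- paste0("<", txt)
  if (stats::runif(1) < 0.1) txt <- paste0(txt, ">")
  txt
}

make_window <- function(residues, position) {
  extract_window(protein_record("t", residues), position)
}
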