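# Local PROSITE-syntax consensus-pattern matching (the dialect used by
# ScanProsite): elements separated by '-', each a fixed residue, an
# alternative set [..], an exclusion set {..} or the wildcard x, with an
# optional repeat (n) or range (n,m); '<'/'>' anchor to the termini and a
# terminal '.' is ignored.

#' Parse a PROSITE-syntax pattern
#'
#' Case-insensitive. Examples: `"C-P"`, `"[HY]-x(3)-C"`, `"C-x(2,4)-{P}"`,
#' `"<A-x-B>"`.
#'
#' @param text Pattern string.
#' @return Object of class `prosite_pattern` with fields `source_text`,
#'   `elements` (list of `list(kind, residues, min, max)` where `kind` is
#'   `fixed`, `set`, `exclude` or `wild`), `anchored_start`, `anchored_end`.
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src <- text
  work <- trimws(text)
  work <- sub("\\.$", "", work)
  anchored_start <- startsWith(work, "<")
  if (anchored_start) work <- substring(work, 2L)
  anchored_end <- endsWith(work, ">")
  if (anchored_end) work <- substring(work, 1L, nchar(work) - 1L)
  if (!nzchar(work)) stop("empty pattern", call. = FALSE)

  parts <- strsplit(work, "-", fixed = TRUE)[[1]]
  if (length(parts) == 0L || any(!nzchar(parts))) {
    stop(sprintf("pattern '%s': empty element", src), call. = FALSE)
  }
  offset <- if (anchored_start) 1L else 0L
  elements <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    elements[[i]] <- parse_element(parts[i], src, offset)
    offset <- offset + nchar(parts[i]) + 1L
  }
  structure(list(source_text = src, elements = elements,
                 anchored_start = anchored_start, anchored_end = anchored_end),
            class = "prosite_pattern")
}

parse_element <- function(part, src, offset) {
  m <- regmatches(part, regexec(
    "^(x|[A-Za-z]|\\[[A-Za-z]+\\]|\\{[A-Za-z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
    part))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("pattern '%s': malformed element '%s' at offset %d",
                 src, part, offset + 1L), call. = FALSE)
  }
  body <- m[2]
  lo <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  hi <- if (nzchar(m[6])) as.integer(m[6]) else lo
  if (lo < 1L || hi < lo) {
    stop(sprintf("pattern '%s': bad repeat '%s' at offset %d (need n >= 1, m >= n)",
                 src, m[3], offset + nchar(body) + 1L), call. = FALSE)
  }
  if (body %in% c("x", "X")) {
    list(kind = "wild", residues = character(0), min = lo, max = hi)
  } else if (startsWith(body, "[")) {
    res <- strsplit(toupper(substr(body, 2L, nchar(body) - 1L)), "")[[1]]
    list(kind = "set", residues = unique(res), min = lo, max = hi)
  } else if (startsWith(body, "{")) {
    res <- strsplit(toupper(substr(body, 2L, nchar(body) - 1L)), "")[[1]]
    list(kind = "exclude", residues = unique(res), min = lo, max = hi)
  } else {
    list(kind = "fixed", residues = toupper(body), min = lo, max = hi)
  }
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(sprintf("<prosite_pattern> %s (%d elements%s%s)\n", x$source_text,
              length(x$elements),
              if (x$anchored_start) ", N-anchored" else "",
              if (x$anchored_end) ", C-anchored" else ""))
  invisible(x)
}

# Does a single residue satisfy a single element? An 'X' in the *sequence*
# satisfies only wildcards: an unknown residue must not be taken as evidence
# for a specific requirement.
element_matches <- function(residue, elem) {
  switch(elem$kind,
         wild = TRUE,
         fixed = residue != "X" && residue == elem$residues,
         set = residue != "X" && residue %in% elem$residues,
         exclude = residue != "X" && !(residue %in% elem$residues))
}

# Smallest end index (or NA) of a match of elements k.. starting at pos.
match_min_end <- function(chars, pos, elements, k, anchored_end) {
  if (k > length(elements)) {
    if (anchored_end && pos != length(chars) + 1L) return(NA_integer_)
    return(pos - 1L)
  }
  e <- elements[[k]]
  best <- NA_integer_
  for (cnt in e$min:e$max) {
    if (pos + cnt - 1L > length(chars)) break
    ok <- cnt == 0L ||
      all(vapply(chars[pos:(pos + cnt - 1L)], element_matches, logical(1),
                 elem = e))
    if (!ok) next
    end <- match_min_end(chars, pos + cnt, elements, k + 1L, anchored_end)
    if (!is.na(end) && (is.na(best) || end < best)) best <- end
  }
  best
}

#' Match a PROSITE pattern against a protein record
#'
#' Reports every start position at which the pattern matches; overlapping
#' matches at distinct starts are all reported, and for ranged repeats the
#' shortest match at each start is returned. Anchors restrict matches to the
#' sequence termini.
#'
#' @param pattern A [parse_pattern()] result (or a pattern string).
#' @param record A [protein_record()].
#' @return Data frame with columns `start`, `end` (1-based, inclusive) and
#'   `match` (the matched subsequence), ascending by start.
#' @export
match_pattern <- function(pattern, record) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"), is_protein_record(record))
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  starts <- if (pattern$anchored_start) 1L else seq_along(chars)
  hits_start <- integer(0)
  hits_end <- integer(0)
  for (s in starts) {
    end <- match_min_end(chars, s, pattern$elements, 1L, pattern$anchored_end)
    if (!is.na(end)) {
      hits_start <- c(hits_start, s)
      hits_end <- c(hits_end, end)
    }
  }
  matches <- if (length(hits_start) == 0L) character(0)
             else substring(record$residues, hits_start, hits_end)
  data.frame(start = hits_start, end = hits_end, match = matches,
             stringsAsFactors = FALSE)
}

#' Scan many records with many patterns
#'
#' @param patterns List of patterns ([parse_pattern()] results or strings).
#' @param records List of [protein_record()] objects.
#' @return Data frame with columns `pattern`, `record_id`, `start`, `end`,
#'   `match`, ordered by record, then start position, then pattern order.
#' @export
scan_database <- function(patterns, records) {
  patterns <- lapply(patterns, function(p) {
    if (is.character(p)) parse_pattern(p) else p
  })
  out <- list()
  for (r in records) {
    per_record <- list()
    for (pi in seq_along(patterns)) {
      hits <- match_pattern(patterns[[pi]], r)
      if (nrow(hits) > 0L) {
        per_record[[length(per_record) + 1L]] <- data.frame(
          pattern = patterns[[pi]]$source_text, record_id = r$identifier,
          start = hits$start, end = hits$end, match = hits$match,
          pattern_order = pi, stringsAsFactors = FALSE)
      }
    }
    if (length(per_record) > 0L) {
      tab <- do.call(rbind, per_record)
      tab <- tab[order(tab$start, tab$pattern_order), , drop = FALSE]
      out[[length(out) + 1L]] <- tab
    }
  }
  if (length(out) == 0L) {
    return(data.frame(pattern = character(0), record_id = character(0),
                      start = integer(0), end = integer(0),
                      match = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$pattern_order <- NULL
  rownames(res) <- NULL
  res
}
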