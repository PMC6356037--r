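# Solvent-accessibility profiles and the exposure filter for coordination
# sites. The original tool delegates exposure prediction to the WESA
# meta-predictor; here a documented hydropathy heuristic and a file import
# stand behind the same interface so external predictions plug in unchanged.

ACCESS_LABELS <- c("exposed", "buried", "unknown")

#' Construct a per-residue accessibility profile
#'
#' @param record_id Identifier of the protein the profile describes.
#' @param labels Character vector over `exposed`/`buried`/`unknown`, one per
#'   residue.
#' @param source Provenance tag, e.g. `"builtin-heuristic"` or
#'   `"file:<name>"`.
#' @return Object of class `accessibility_profile`.
#' @export
accessibility_profile <- function(record_id, labels, source) {
  stopifnot(is.character(record_id), length(record_id) == 1L,
            is.character(labels), all(labels %in% ACCESS_LABELS),
            is.character(source), length(source) == 1L)
  structure(list(record_id = record_id, labels = labels, source = source),
            class = "accessibility_profile")
}

#' @export
print.accessibility_profile <- function(x, ...) {
  cat(sprintf("<accessibility_profile> %s (%d residues, %s): %d exposed / %d buried / %d unknown\n",
              x$record_id, length(x$labels), x$source,
              sum(x$labels == "exposed"), sum(x$labels == "buried"),
              sum(x$labels == "unknown")))
  invisible(x)
}

#' Filter coordination sites by solvent exposure
#'
#' In `default` mode only sites labeled `exposed` survive; `unknown` labels
#' pass with a warning (missing evidence should not suppress a candidate).
#' In `structure` mode no filtering is applied and the site list is returned
#' unchanged — the user is expected to curate against the known structure.
#'
#' @param sites Data frame from [find_coordination_sites()].
#' @param profile An [accessibility_profile()] covering the record.
#' @param mode `"default"` or `"structure"`.
#' @return Order-preserving subset of `sites`.
#' @export
filter_sites <- function(sites, profile, mode = c("default", "structure")) {
  mode <- match.arg(mode)
  if (mode == "structure") return(sites)
  stopifnot(inherits(profile, "accessibility_profile"))
  if (nrow(sites) > 0L && max(sites$position) > length(profile$labels)) {
    stop(sprintf("accessibility profile for '%s' (%d residues) does not cover site position %d",
                 profile$record_id, length(profile$labels),
                 max(sites$position)), call. = FALSE)
  }
  labels <- profile$labels[sites$position]
  if (any(labels == "unknown")) {
    warning(sprintf("record '%s': %d site(s) with unknown exposure retained",
                    profile$record_id, sum(labels == "unknown")), call. = FALSE)
  }
  sites[labels != "buried", , drop = FALSE]
}

# Kyte-Doolittle hydropathy values keyed by one-letter code, taken from
# seqinr's aaindex (entry KYTJ820101).
kyte_doolittle_scale <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("aaindex", package = "seqinr", envir = e)
      idx <- e$aaindex[["KYTJ820101"]]
      vals <- idx$I
      names(vals) <- vapply(names(vals), seqinr::a, character(1))
      # norleucine (J): straight-chain isomer of leucine, same hydropathy
      vals <- c(vals, J = unname(vals[["L"]]))
      cache <<- vals
    }
    cache
  }
})

#' Built-in exposure heuristic (hydropathy sliding window)
#'
#' Labels each residue by the mean Kyte-Doolittle hydropathy of a centered
#' sliding window (truncated at the termini): a mean above `threshold`
#' (hydrophobic environment) is labeled `buried`, otherwise `exposed`.
#' This is a simple deterministic heuristic for the default operating mode.
#' Norleucine (`J`) is scored with leucine's hydropathy (it is leucine's
#' straight-chain isomer); residue codes without a hydropathy value
#' (X, B, Z, U, O) contribute 0 with a warning.
#'
#' @param record A [protein_record()].
#' @param window_size Odd window width >= 3 (default 9).
#' @param threshold Mean-hydropathy cutoff separating buried from exposed
#'   (default 0, the hydrophobic/hydrophilic midpoint of the scale).
#' @return An [accessibility_profile()] with source `"builtin-heuristic"`.
#' @export
builtin_predictor <- function(record, window_size = 9L, threshold = 0) {
  stopifnot(is_protein_record(record),
            window_size >= 3L, window_size %% 2L == 1L)
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  scale <- kyte_doolittle_scale()
  h <- unname(scale[chars])
  if (anyNA(h)) {
    warning(sprintf("record '%s': %d residue(s) without hydropathy value treated as 0",
                    record$identifier, sum(is.na(h))), call. = FALSE)
    h[is.na(h)] <- 0
  }
  n <- length(h)
  half <- (window_size - 1L) %/% 2L
  means <- vapply(seq_len(n), function(i) {
    mean(h[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  labels <- ifelse(means > threshold, "buried", "exposed")
  accessibility_profile(record$identifier, labels, "builtin-heuristic")
}

#' Read a per-residue accessibility file
#'
#' Two-column whitespace/tab-separated text: 1-based residue position, then
#' either a label (`exposed`/`buried`, case-insensitive) or a relative
#' solvent accessibility (RSA) fraction in \[0, 1\], binarized at
#' `rsa_cutoff` (RSA >= cutoff is exposed). Lines starting with `#` and
#' blank lines are skipped. Positions not listed are labeled `unknown`.
#'
#' @param path File path.
#' @param record The [protein_record()] the file describes.
#' @param rsa_cutoff RSA binarization cutoff (default 0.25, the common
#'   surface/buried convention).
#' @return An [accessibility_profile()] with source `"file:<basename>"`.
#' @export
read_accessibility_file <- function(path, record, rsa_cutoff = 0.25) {
  stopifnot(is_protein_record(record), file.exists(path),
            rsa_cutoff >= 0, rsa_cutoff <= 1)
  n <- nchar(record$residues)
  labels <- rep("unknown", n)
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    fields <- strsplit(line, "[\t ]+")[[1]]
    if (length(fields) != 2L) {
      stop(sprintf("%s line %d: expected 2 fields, got %d", path, i,
                   length(fields)), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(fields[1]))
    if (is.na(pos)) {
      stop(sprintf("%s line %d: unparseable position '%s'", path, i,
                   fields[1]), call. = FALSE)
    }
    if (pos < 1L || pos > n) {
      stop(sprintf("%s line %d: position %d outside record '%s' (length %d)",
                   path, i, pos, record$identifier, n), call. = FALSE)
    }
    val <- tolower(fields[2])
    if (val %in% c("exposed", "buried")) {
      labels[pos] <- val
    } else {
      rsa <- suppressWarnings(as.numeric(fields[2]))
      if (is.na(rsa) || rsa < 0 || rsa > 1) {
        stop(sprintf("%s line %d: label must be exposed/buried or RSA in [0,1], got '%s'",
                     path, i, fields[2]), call. = FALSE)
      }
      labels[pos] <- if (rsa >= rsa_cutoff) "exposed" else "buried"
    }
  }
  accessibility_profile(record$identifier, labels,
                        paste0("file:", basename(path)))
}
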