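# FASTA input, TSV report output, and sequence validation.

#' Accepted one-letter amino-acid alphabet
#'
#' The 20 standard residues plus the ambiguity/rare codes X, B, Z, U, O and J.
#' J is used here for norleucine (Nle), which has no standard one-letter code;
#' the scanner never treats J as a coordination site.
#'
#' @return Character vector of accepted residue codes.
#' @export
protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
    "F", "P", "S", "T", "W", "Y", "V", "X", "B", "Z", "U", "O", "J")
}

#' Construct a protein record
#'
#' @param identifier Record identifier (FASTA header token before the first
#'   whitespace).
#' @param residues Residue string, one-letter codes. Lowercase is uppercased;
#'   `*` (stop) characters are stripped with a warning.
#' @param description Remainder of the FASTA header (may be empty).
#' @return An object of class `protein_record` with fields `identifier`,
#'   `description` and `residues`.
#' @export
protein_record <- function(identifier, residues, description = "") {
  stopifnot(is.character(identifier), length(identifier) == 1L, nzchar(identifier),
            is.character(residues), length(residues) == 1L,
            is.character(description), length(description) == 1L)
  residues <- toupper(residues)
  if (grepl("*", residues, fixed = TRUE)) {
    warning(sprintf("record '%s': stripping '*' (stop) character(s)", identifier),
            call. = FALSE)
    residues <- gsub("*", "", residues, fixed = TRUE)
  }
  if (!nzchar(residues)) {
    stop(sprintf("record '%s': empty residue string", identifier), call. = FALSE)
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% protein_alphabet())
  if (length(bad) > 0L) {
    stop(sprintf("record '%s': illegal residue character '%s' at position %d",
                 identifier, chars[bad[1]], bad[1]), call. = FALSE)
  }
  structure(list(identifier = identifier, description = description,
                 residues = residues),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s%s (%d aa)\n%s\n", x$identifier,
              if (nzchar(x$description)) paste0(" ", x$description) else "",
              nchar(x$residues), x$residues))
  invisible(x)
}

is_protein_record <- function(x) inherits(x, "protein_record")

#' Read protein sequences from FASTA
#'
#' Accepts a file path or FASTA-formatted text. Wrapped sequence lines are
#' joined, surrounding whitespace is stripped and lowercase residues are
#' uppercased. Parsing is delegated to [seqinr::read.fasta()]; records are
#' then validated against [protein_alphabet()].
#'
#' @param source Path to a FASTA file, or a character vector of FASTA text
#'   (recognized by a leading `>` or embedded newlines).
#' @return List of [protein_record()] objects, input order preserved.
#' @export
read_fasta <- function(source) {
  stopifnot(is.character(source), length(source) >= 1L)
  is_text <- length(source) > 1L || grepl("[>\n]", source[1])
  path <- if (is_text) {
    tf <- tempfile(fileext = ".fasta")
    writeLines(paste(source, collapse = "\n"), tf)
    tf
  } else {
    if (!file.exists(source)) stop(sprintf("FASTA file not found: %s", source),
                                   call. = FALSE)
    source
  }
  raw_lines <- readLines(path, warn = FALSE)
  nonblank <- raw_lines[nzchar(trimws(raw_lines))]
  if (length(nonblank) == 0L) stop("no records: input is empty", call. = FALSE)
  if (!startsWith(trimws(nonblank[1]), ">")) {
    stop("FASTA format error: sequence data before first '>' header",
         call. = FALSE)
  }
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       whole.header = TRUE),
    error = function(e) stop(sprintf("no records: %s", conditionMessage(e)),
                             call. = FALSE))
  lapply(seqs, function(s) {
    header <- trimws(attr(s, "name"))
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) trimws(sub("^\\S+\\s+", "", header)) else ""
    protein_record(id, gsub("\\s", "", as.character(s)), desc)
  })
}

#' Write protein records to FASTA
#'
#' @param records List of [protein_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(vapply(records, is_protein_record, logical(1))))
  headers <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$identifier, r$description) else r$identifier
  }, character(1))
  seqinr::write.fasta(lapply(records, `[[`, "residues"), names = headers,
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

report_columns <- function() {
  c("record_id", "position", "axial_ligand", "motif", "net_charge",
    "class", "exposure", "comment")
}

#' Write a scan report as TSV
#'
#' One header line, tab-separated, `\n` line endings. The `comments` list
#' column is joined with `"; "`. Row order is preserved.
#'
#' @param rows Scan report data frame as returned by [scan_report()] /
#'   [run_scan()]: columns `record_id`, `position`, `axial_ligand`, `motif`,
#'   `net_charge`, `class`, `exposure` and a list column `comments`.
#' @param path Output file path (or connection).
#' @return `path`, invisibly.
#' @export
write_report <- function(rows, path) {
  out <- data.frame(
    record_id = as.character(rows$record_id),
    position = as.integer(rows$position),
    axial_ligand = as.character(rows$axial_ligand),
    motif = as.character(rows$motif),
    net_charge = as.integer(rows$net_charge),
    class = as.character(rows$class),
    exposure = as.character(rows$exposure),
    comment = vapply(rows$comments, paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a scan report written by [write_report()]
#'
#' @param path Report TSV path.
#' @return Data frame with the report columns; `comment` is split back into
#'   the `comments` list column.
#' @export
read_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", stringsAsFactors = FALSE)
  if (!identical(names(df), report_columns())) {
    stop("malformed report: unexpected column set", call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df$net_charge <- as.integer(df$net_charge)
  df$comments <- lapply(df$comment, function(x) {
    if (!nzchar(x)) character(0) else strsplit(x, "; ", fixed = TRUE)[[1]]
  })
  df$comment <- NULL
  df
}
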