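# Core motif scanning: coordination sites, 9-mer windows, net charge,
# CP dipeptides and ancillary sites.

COORDINATING <- c("C", "H", "Y")

#' Locate candidate heme-coordination sites
#'
#' A coordination site is any Cys, His or Tyr residue; these side chains
#' supply the fifth/sixth axial ligand of the heme iron. Methionine and
#' lysine are reported in the literature as rare ligands and can be enabled
#' explicitly.
#'
#' @param record A [protein_record()].
#' @param ligands Residues treated as coordinating (default `C`, `H`, `Y`).
#' @return Data frame with columns `position` (1-based) and `ligand`,
#'   ascending by position; zero rows if no site is present.
#' @export
find_coordination_sites <- function(record, ligands = COORDINATING) {
  stopifnot(is_protein_record(record))
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  pos <- which(chars %in% ligands)
  data.frame(position = as.integer(pos), ligand = chars[pos],
             stringsAsFactors = FALSE)
}

#' Extract the motif window around a coordination site
#'
#' The window spans up to four residues on each side of the axial ligand
#' (position P0 in the nonapeptide nomenclature), giving a 9-mer in the
#' sequence interior. Near a terminus the window is truncated to the
#' available residues and the corresponding flag is set. The returned window
#' carries the net charge, the CP-dipeptide flag and all ancillary
#' coordination sites within the window.
#'
#' @param record A [protein_record()].
#' @param position 1-based position of the site; the residue there must be a
#'   coordinating one.
#' @param flank Number of residues on each side (default 4).
#' @param ligands Residues accepted as axial ligands at `position`.
#' @return An object of class `motif_window` with fields `record_id`,
#'   `position`, `ligand`, `sequence`, `center_offset` (0-based),
#'   `left_truncated`, `right_truncated`, `net_charge`, `is_cp`,
#'   `ancillary_sites` (data frame of `ligand`, `offset`).
#' @export
extract_window <- function(record, position, flank = 4L, ligands = COORDINATING) {
  stopifnot(is_protein_record(record), length(position) == 1L)
  position <- as.integer(position)
  n <- nchar(record$residues)
  if (position < 1L || position > n) {
    stop(sprintf("site position %d outside record '%s' (length %d)",
                 position, record$identifier, n), call. = FALSE)
  }
  ligand <- substr(record$residues, position, position)
  if (!ligand %in% ligands) {
    stop(sprintf("residue '%s' at position %d of record '%s' is not a coordination site",
                 ligand, position, record$identifier), call. = FALSE)
  }
  lo <- max(1L, position - flank)
  hi <- min(n, position + flank)
  w <- structure(list(
    record_id = record$identifier,
    position = position,
    ligand = ligand,
    sequence = substr(record$residues, lo, hi),
    center_offset = position - lo,
    left_truncated = lo > position - flank,
    right_truncated = hi < position + flank
  ), class = "motif_window")
  w$net_charge <- net_charge(w$sequence)
  w$is_cp <- detect_cp(w)
  w$ancillary_sites <- find_ancillary_sites(w)
  w
}

#' @export
print.motif_window <- function(x, ...) {
  cat(sprintf("<motif_window> %s @%d (%s): %s  charge %+d%s%s\n",
              x$record_id, x$position, x$ligand, x$sequence, x$net_charge,
              if (x$is_cp) "  CP" else "",
              if (nrow(x$ancillary_sites) > 0L)
                paste0("  ancillary: ",
                       paste(sprintf("%s%+d", x$ancillary_sites$ligand,
                                     x$ancillary_sites$offset), collapse = ","))
              else ""))
  invisible(x)
}

#' Net charge of a peptide window
#'
#' Counts Lys and Arg as +1, Asp and Glu as -1; His is neutral at the
#' implied physiological pH and termini contribute nothing because windows
#' are internal protein fragments.
#'
#' @param x A `motif_window` or a residue string.
#' @return Integer net charge.
#' @export
net_charge <- function(x) {
  s <- if (inherits(x, "motif_window")) x$sequence else x
  stopifnot(is.character(s), length(s) == 1L, nzchar(s))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  as.integer(sum(chars %in% c("K", "R")) - sum(chars %in% c("D", "E")))
}

#' Detect a cysteine-proline (CP) dipeptide at the axial ligand
#'
#' TRUE iff the axial ligand is Cys and the residue immediately following it
#' (offset +1) exists and is Pro.
#'
#' @param window A `motif_window`.
#' @return Logical scalar.
#' @export
detect_cp <- function(window) {
  stopifnot(inherits(window, "motif_window"))
  if (window$ligand != "C") return(FALSE)
  nxt <- window$center_offset + 2L  # 1-based index of offset +1
  nxt <= nchar(window$sequence) &&
    substr(window$sequence, nxt, nxt) == "P"
}

#' Ancillary coordination sites within a motif window
#'
#' All Cys/His/Tyr residues in the window other than the axial ligand itself,
#' reported as signed offsets relative to P0 (ascending).
#'
#' @param window A `motif_window`.
#' @return Data frame with columns `ligand` and `offset` (offset != 0).
#' @export
find_ancillary_sites <- function(window) {
  stopifnot(inherits(window, "motif_window"))
  chars <- strsplit(window$sequence, "", fixed = TRUE)[[1]]
  offsets <- seq_along(chars) - 1L - window$center_offset
  keep <- chars %in% COORDINATING & offsets != 0L
  data.frame(ligand = chars[keep], offset = as.integer(offsets[keep]),
             stringsAsFactors = FALSE)
}

#' Scan a protein record for motif windows
#'
#' One fully populated window per coordination site, ascending by position.
#'
#' @param record A [protein_record()].
#' @param ligands Coordinating residues (see [find_coordination_sites()]).
#' @return List of `motif_window` objects (possibly empty).
#' @export
scan_record <- function(record, ligands = COORDINATING) {
  sites <- find_coordination_sites(record, ligands)
  lapply(sites$position, function(p) extract_window(record, p, ligands = ligands))
}
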