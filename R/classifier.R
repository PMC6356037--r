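# HBM classification (eight classes) and report comment generation.

# Class table. The class space is (axial ligand in {C,H,Y}) x (ancillary
# present yes/no), with cysteine split further by the CP dipeptide:
# 2 (C) + 2 (CP) + 2 (H) + 2 (Y) = 8 classes. Coordination and topology are
# metadata hints from peptide-level spectroscopy/NMR, not per-protein
# predictions: penta = {III, IV, V, VII}, hexa = {I, II, VI, VIII};
# sandwich-like complexes for I and VIII, loop/clamp-like for II and VI.
.hbm_class_table <- data.frame(
  label        = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
  axial_ligand = c("C", "C", "C", "C", "H", "H", "Y", "Y"),
  requires_cp  = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
  requires_ancillary = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
  coordination = c("hexa", "hexa", "penta", "penta", "penta", "hexa",
                   "penta", "hexa"),
  topology     = c("sandwich", "loop", "single", "single", "single", "loop",
                   "single", "sandwich"),
  stringsAsFactors = FALSE
)

#' The eight heme-binding-motif classes
#'
#' Enumerates the full classification space: axial ligand (Cys, His, Tyr)
#' crossed with presence/absence of an ancillary coordination site, with
#' cysteine motifs split further by the CP dipeptide. The `coordination` and
#' `topology` columns are expectations from peptide-level spectroscopic and
#' NMR studies (penta-coordination for III, IV, V, VII; hexa for I, II, VI,
#' VIII; sandwich-like complexes for I/VIII and loop/clamp-like for II/VI);
#' they are attached to reports as hints, not predictions.
#'
#' @return Data frame with columns `label`, `axial_ligand`, `requires_cp`,
#'   `requires_ancillary`, `coordination`, `topology` (8 rows).
#' @export
hbm_classes <- function() .hbm_class_table

#' Assign a motif window to its HBM class
#'
#' Deterministic total mapping: Cys without CP maps to I (no ancillary) or
#' II (ancillary); a CP dipeptide dominates the cysteine split and maps to
#' III (no ancillary) or IV (ancillary); His maps to V/VI and Tyr to
#' VII/VIII by the same ancillary criterion. One or more ancillary sites of
#' any coordinating type count as "ancillary present".
#'
#' @param window A `motif_window` (see [extract_window()]).
#' @return One row of [hbm_classes()] as a list of class `hbm_class`.
#' @export
assign_class <- function(window) {
  stopifnot(inherits(window, "motif_window"))
  anc <- nrow(window$ancillary_sites) > 0L
  tab <- .hbm_class_table
  row <- tab[tab$axial_ligand == window$ligand &
               tab$requires_cp == window$is_cp &
               tab$requires_ancillary == anc, , drop = FALSE]
  stopifnot(nrow(row) == 1L)
  structure(as.list(row), class = "hbm_class")
}

#' @export
print.hbm_class <- function(x, ...) {
  cat(sprintf("<hbm_class> %s: %s%s, ancillary %s -> expect %s-coordination (%s)\n",
              x$label, x$axial_ligand, if (x$requires_cp) "P" else "",
              if (x$requires_ancillary) "yes" else "no",
              x$coordination, x$topology))
  invisible(x)
}

#' Generate report comments for a classified window
#'
#' Produces the human-readable hints attached to the scan report: CP-motif
#' identification, the list of ancillary coordination sites, the qualitative
#' net-charge assessment (a negative net charge disfavors heme binding, a
#' positive one favors it), and the class expectation hint.
#'
#' @param window A `motif_window`.
#' @param cls Its class, as returned by [assign_class()]; must agree with
#'   the window.
#' @return Character vector of comments (possibly empty, never NULL).
#' @export
annotate_window <- function(window, cls = assign_class(window)) {
  stopifnot(inherits(window, "motif_window"), inherits(cls, "hbm_class"))
  check <- assign_class(window)
  if (!identical(check$label, cls$label)) {
    stop(sprintf("class '%s' does not match window (expected '%s')",
                 cls$label, check$label), call. = FALSE)
  }
  comments <- character(0)
  if (window$is_cp) comments <- c(comments, "CP motif")
  if (nrow(window$ancillary_sites) > 0L) {
    sites <- sprintf("%s at %+d", window$ancillary_sites$ligand,
                     window$ancillary_sites$offset)
    comments <- c(comments,
                  paste0("additional coordination site(s): ",
                         paste(sites, collapse = ", ")))
  }
  if (window$net_charge < 0L) {
    comments <- c(comments, "negative net charge: heme binding disfavored")
  } else if (window$net_charge > 0L) {
    comments <- c(comments, "positive net charge: heme binding favored")
  }
  comments <- c(comments,
                sprintf("class %s: expect %s-coordination (%s topology)",
                        cls$label, cls$coordination, cls$topology))
  comments
}
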