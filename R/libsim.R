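# Simulator of the combinatorial X4(C/H/Y)X4 nonapeptide library: a fixed
# central coordinating residue with randomized flanks drawn from the 20
# standard residues minus Cys and Met plus norleucine (Nle, written J).
# Used for fixtures, property tests and generator-calibration checks.

#' Default flank alphabet of the combinatorial library
#'
#' The 20 standard residues without Cys (to avoid intramolecular disulfides)
#' and Met (reserved for the peptide elimination chemistry), plus norleucine
#' as `J` — 19 letters.
#'
#' @return Character vector of 19 one-letter codes.
#' @export
library_flank_alphabet <- function() {
  c("A", "R", "N", "D", "Q", "E", "G", "H", "I", "L", "K",
    "F", "P", "S", "T", "W", "Y", "V", "J")
}

#' Specify a combinatorial nonapeptide library
#'
#' Defaults reproduce the screened library design: four randomized flank
#' positions on each side of a central Cys/His/Tyr. The default center
#' weights are the axial-ligand frequencies observed among library *hits*
#' (His ~40%, Tyr ~40%, Cys ~20%); the synthesized library itself is uniform
#' over the three centers, which can be requested with equal weights.
#'
#' @param flank_length Randomized positions per side (default 4).
#' @param center_alphabet Possible axial ligands (default C, H, Y).
#' @param flank_alphabet Flank residues (default [library_flank_alphabet()]).
#' @param center_weights Named numeric sampling weights over
#'   `center_alphabet`, summing to 1 (default H = 0.4, Y = 0.4, C = 0.2).
#' @param seed Integer RNG seed.
#' @return Object of class `library_spec`.
#' @export
library_spec <- function(flank_length = 4L,
                         center_alphabet = c("C", "H", "Y"),
                         flank_alphabet = library_flank_alphabet(),
                         center_weights = c(H = 0.4, Y = 0.4, C = 0.2),
                         seed = 1L) {
  stopifnot(flank_length >= 1L, length(center_alphabet) >= 1L,
            length(flank_alphabet) >= 1L)
  if (is.null(names(center_weights)) ||
      !setequal(names(center_weights), center_alphabet)) {
    stop("center_weights must be named by the center alphabet", call. = FALSE)
  }
  if (any(center_weights < 0) || abs(sum(center_weights) - 1) > 1e-9) {
    stop("center_weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(flank_length = as.integer(flank_length),
                 center_alphabet = center_alphabet,
                 flank_alphabet = flank_alphabet,
                 center_weights = center_weights[center_alphabet],
                 seed = as.integer(seed)),
            class = "library_spec")
}

#' Generate synthetic library peptides
#'
#' Draws `n` peptides of length `2 * flank_length + 1`: the center from
#' `center_alphabet` with `center_weights`, flank positions i.i.d. from
#' `flank_alphabet`. Reproducible for a given `spec$seed`.
#'
#' @param spec A [library_spec()].
#' @param n Number of peptides (>= 1).
#' @return List of [protein_record()] objects named `lib_%06d`, each with a
#'   description recording the center ligand.
#' @export
generate_library <- function(spec, n) {
  stopifnot(inherits(spec, "library_spec"), n >= 1L)
  n <- as.integer(n)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  centers <- sample(spec$center_alphabet, n, replace = TRUE,
                    prob = spec$center_weights)
  k <- spec$flank_length
  flanks <- matrix(sample(spec$flank_alphabet, n * 2L * k, replace = TRUE),
                   nrow = n)
  lapply(seq_len(n), function(i) {
    seq_chars <- c(flanks[i, seq_len(k)], centers[i],
                   flanks[i, k + seq_len(k)])
    protein_record(sprintf("lib_%06d", i), paste(seq_chars, collapse = ""),
                   description = paste0("center=", centers[i]))
  })
}

center_residues <- function(records, flank_length = 4L) {
  pos <- flank_length + 1L
  vapply(records, function(r) substr(r$residues, pos, pos), character(1))
}

#' Empirical axial-ligand fractions of a library
#'
#' @param records Library peptides from [generate_library()].
#' @param flank_length Flank length used to generate them (default 4).
#' @return Named numeric vector of center-residue fractions, summing to 1.
#' @export
ligand_fractions <- function(records, flank_length = 4L) {
  if (length(records) == 0L) stop("empty library", call. = FALSE)
  centers <- center_residues(records, flank_length)
  tab <- table(centers)
  stats::setNames(as.numeric(tab) / length(records), names(tab))
}

#' Fraction of peptides with ancillary His/Tyr in the flanks
#'
#' Among library hits, additional His/Tyr coordination sites in the flanks
#' were observed in more than half the peptides; this computes the empirical
#' fraction of records with at least one H or Y at a flank position. Under
#' uniform sampling from a 19-letter flank alphabet containing H and Y the
#' expectation is `1 - (17/19)^(2 * flank_length)` (about 0.589 for
#' flank_length 4).
#'
#' @inheritParams ligand_fractions
#' @return Fraction in \[0, 1\].
#' @export
ancillary_fraction <- function(records, flank_length = 4L) {
  if (length(records) == 0L) stop("empty library", call. = FALSE)
  k <- flank_length
  has_anc <- vapply(records, function(r) {
    flank <- paste0(substr(r$residues, 1L, k),
                    substr(r$residues, k + 2L, 2L * k + 1L))
    grepl("[HY]", flank)
  }, logical(1))
  mean(has_anc)
}
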