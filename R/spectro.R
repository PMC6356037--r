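# Rule engine for heme-iron coordination-state calls from spectroscopic
# band positions: UV/Vis Soret maxima, resonance-Raman nu3 wavenumbers and
# cwEPR g-values. Inputs are already-extracted band positions; no spectrum
# processing is done here.

#' Default tolerances of the spectroscopic rule base
#'
#' Band positions in the underlying studies are reported as approximate
#' ("~") values; these windows operationalize them. All are user-settable.
#'
#' * `soret_penta_nm` (370) with `soret_penta_tol_nm` (8): Soret maximum of
#'   a penta-coordinated complex.
#' * `soret_hexa_min_nm`/`soret_hexa_max_nm` (415-435): the 420-430 nm band,
#'   which cannot be uniquely assigned to one coordination state.
#' * `nu3_penta_cm1` (1491), `nu3_hexa_cm1` (1505), `nu3_tol_cm1` (5): nu3
#'   marker-band positions for penta- and hexa-coordination.
#' * `g_perp` (6), `g_par` (2), `g_tol` (0.4): high-spin EPR signals of a
#'   penta-coordinated complex.
#' * `g_lowspin_min`/`g_lowspin_max` (1.5-3): range of the three g-values of
#'   a low-spin hexa-coordinated complex.
#'
#' @return Named list of tolerance parameters.
#' @export
spectro_tolerances <- function() {
  list(soret_penta_nm = 370, soret_penta_tol_nm = 8,
       soret_hexa_min_nm = 415, soret_hexa_max_nm = 435,
       nu3_penta_cm1 = 1491, nu3_hexa_cm1 = 1505, nu3_tol_cm1 = 5,
       g_perp = 6, g_par = 2, g_tol = 0.4,
       g_lowspin_min = 1.5, g_lowspin_max = 3)
}

partial_call <- function(technique, verdict, rules, caveats = character(0)) {
  structure(list(technique = technique, verdict = verdict, rules = rules,
                 caveats = caveats),
            class = "partial_coordination_call")
}

#' Interpret UV/Vis Soret maxima
#'
#' A lone Soret maximum near 370 nm indicates a penta-coordinated complex; a
#' lone maximum in the 420-430 nm band cannot be uniquely assigned to one
#' coordination state (verdict `ambiguous`); maxima in both bands indicate a
#' mixture of penta- and hexa-coordinated complexes.
#'
#' @param soret_maxima_nm Numeric vector of Soret maxima (nm), 0-2 entries
#'   used, in 300-800 nm.
#' @param tol Tolerance list, see [spectro_tolerances()].
#' @return A partial coordination call (technique `"UV/Vis"`).
#' @export
infer_from_uv <- function(soret_maxima_nm, tol = spectro_tolerances()) {
  x <- sort(as.numeric(soret_maxima_nm))
  if (any(x <= 0) || any(x < 300 | x > 800)) {
    stop("Soret maxima must lie in 300-800 nm", call. = FALSE)
  }
  in_penta <- any(abs(x - tol$soret_penta_nm) <= tol$soret_penta_tol_nm)
  in_hexa_band <- any(x >= tol$soret_hexa_min_nm & x <= tol$soret_hexa_max_nm)
  if (in_penta && in_hexa_band) {
    partial_call("UV/Vis", "mixed",
                 "maxima in both the ~370 nm and 420-430 nm bands: mixture of penta- and hexa-coordination")
  } else if (in_penta) {
    partial_call("UV/Vis", "penta", "Soret maximum ~370 nm: penta-coordinated complex")
  } else if (in_hexa_band) {
    partial_call("UV/Vis", "ambiguous",
                 "Soret maximum in 420-430 nm band: not uniquely assignable to one coordination state")
  } else {
    partial_call("UV/Vis", "undetermined", character(0))
  }
}

#' Interpret resonance-Raman nu3 band positions
#'
#' A single nu3 band near 1491 cm-1 indicates penta-coordination (with the
#' caveat that free hemin, chloride-ligated, gives the same band); a single
#' band near 1505 cm-1 indicates hexa-coordination; a double band indicates
#' a mixture.
#'
#' @param nu3_wavenumbers_cm1 Numeric vector of nu3 band positions (cm-1),
#'   0-2 entries used, in 1400-1600 cm-1.
#' @param tol Tolerance list, see [spectro_tolerances()].
#' @return A partial coordination call (technique `"rRaman"`).
#' @export
infer_from_rraman <- function(nu3_wavenumbers_cm1, tol = spectro_tolerances()) {
  x <- sort(as.numeric(nu3_wavenumbers_cm1))
  if (any(x < 1400 | x > 1600)) {
    stop("nu3 wavenumbers must lie in 1400-1600 cm-1", call. = FALSE)
  }
  near_penta <- any(abs(x - tol$nu3_penta_cm1) <= tol$nu3_tol_cm1)
  near_hexa <- any(abs(x - tol$nu3_hexa_cm1) <= tol$nu3_tol_cm1)
  if (near_penta && near_hexa) {
    partial_call("rRaman", "mixed",
                 "nu3 double band ~1491 + ~1505 cm-1: mixture of penta- and hexa-coordination")
  } else if (near_penta) {
    partial_call("rRaman", "penta", "nu3 band ~1491 cm-1: penta-coordinated complex",
                 caveats = "~1491 cm-1 is indistinguishable from free hemin (chloride as ligand)")
  } else if (near_hexa) {
    partial_call("rRaman", "hexa", "nu3 band ~1505 cm-1: hexa-coordinated complex")
  } else {
    partial_call("rRaman", "undetermined", character(0))
  }
}

#' Interpret cwEPR g-values
#'
#' The high-spin signal pair g_perp ~6 and g_par ~2 indicates a
#' penta-coordinated complex; three g-values (gx, gy, gz) all within
#' ~1.5-3 indicate a low-spin hexa-coordinated complex.
#'
#' @param epr_g_values Numeric vector of g-values, 0-3 entries used, in
#'   0.5-10.
#' @param tol Tolerance list, see [spectro_tolerances()].
#' @return A partial coordination call (technique `"cwEPR"`).
#' @export
infer_from_epr <- function(epr_g_values, tol = spectro_tolerances()) {
  x <- sort(as.numeric(epr_g_values))
  if (any(x < 0.5 | x > 10)) {
    stop("EPR g-values must lie in 0.5-10", call. = FALSE)
  }
  high_spin <- any(abs(x - tol$g_perp) <= tol$g_tol) &&
    any(abs(x - tol$g_par) <= tol$g_tol)
  low_spin <- length(x) == 3L &&
    all(x >= tol$g_lowspin_min & x <= tol$g_lowspin_max)
  if (high_spin && low_spin) {
    partial_call("cwEPR", "mixed", "both high-spin and low-spin g-value patterns present")
  } else if (high_spin) {
    partial_call("cwEPR", "penta",
                 "g_perp ~6 and g_par ~2 (high-spin): penta-coordinated complex")
  } else if (low_spin) {
    partial_call("cwEPR", "hexa",
                 "three g-values within ~1.5-3 (low-spin): hexa-coordinated complex")
  } else {
    partial_call("cwEPR", "undetermined", character(0))
  }
}

#' Combine spectroscopic evidence into one coordination call
#'
#' Unanimous decisive verdicts pass through; any `mixed` partial makes the
#' overall verdict `mixed`; a penta/hexa conflict between techniques yields
#' `mixed` with a conflict flag in the evidence; an `ambiguous` UV verdict
#' is resolved by any decisive technique; with no decisive partial the
#' verdict falls back to `ambiguous` or `undetermined`.
#'
#' The UV-group label (I: ~370 nm only; II: 420-430 nm only; III: both;
#' IV: neither) is an interpretation of a grouping the underlying studies
#' name but do not define, and is reported as such.
#'
#' @param partials List of partial calls from the `infer_from_*` functions.
#' @return Object of class `coordination_call` with fields `verdict` (one of
#'   penta/hexa/mixed/ambiguous/undetermined), `evidence` (data frame:
#'   `technique`, `rule`, `verdict`), `uv_group` (I-IV or `"none"`).
#' @export
combine_evidence <- function(partials) {
  if (length(partials) == 0L) stop("no partial calls to combine", call. = FALSE)
  stopifnot(all(vapply(partials, inherits, logical(1),
                       "partial_coordination_call")))
  # order-independent: sort by technique name
  partials <- partials[order(vapply(partials, `[[`, character(1), "technique"))]

  evidence <- do.call(rbind, lapply(partials, function(p) {
    rule <- if (length(p$rules) > 0L) paste(p$rules, collapse = "; ") else "no rule matched"
    rule <- paste(c(rule, p$caveats), collapse = " [caveat: ")
    if (length(p$caveats) > 0L) rule <- paste0(rule, "]")
    data.frame(technique = p$technique, rule = rule, verdict = p$verdict,
               stringsAsFactors = FALSE)
  }))

  verdicts <- vapply(partials, `[[`, character(1), "verdict")
  decisive <- verdicts[verdicts %in% c("penta", "hexa")]
  verdict <- if (any(verdicts == "mixed")) {
    "mixed"
  } else if (length(unique(decisive)) == 2L) {
    evidence <- rbind(evidence, data.frame(
      technique = "combined", verdict = "mixed",
      rule = "conflict: penta- and hexa-coordination indicated by different techniques",
      stringsAsFactors = FALSE))
    "mixed"
  } else if (length(decisive) > 0L) {
    decisive[1]
  } else if (any(verdicts == "ambiguous")) {
    "ambiguous"
  } else {
    "undetermined"
  }

  uv <- Filter(function(p) p$technique == "UV/Vis", partials)
  uv_group <- if (length(uv) == 0L) {
    "none"
  } else {
    switch(uv[[1]]$verdict,
           penta = "I", ambiguous = "II", mixed = "III", undetermined = "IV")
  }

  structure(list(verdict = verdict, evidence = evidence, uv_group = uv_group),
            class = "coordination_call")
}

#' @export
print.coordination_call <- function(x, ...) {
  cat(sprintf("<coordination_call> verdict: %s (UV-group %s, an interpretive label)\n",
              x$verdict, x$uv_group))
  for (i in seq_len(nrow(x$evidence))) {
    cat(sprintf("  %-8s %-6s %s\n", x$evidence$technique[i],
                x$evidence$verdict[i], x$evidence$rule[i]))
  }
  invisible(x)
}

#' One-step coordination call from raw readouts
#'
#' Convenience wrapper running each applicable `infer_from_*` rule set and
#' combining the partial calls.
#'
#' @param soret_maxima_nm,nu3_wavenumbers_cm1,epr_g_values Numeric vectors
#'   (possibly empty); a technique with no values supplied is skipped
#'   entirely, one with an empty vector contributes `undetermined`.
#' @param tol Tolerance list, see [spectro_tolerances()].
#' @return A `coordination_call`, see [combine_evidence()].
#' @export
coordination_call <- function(soret_maxima_nm = NULL, nu3_wavenumbers_cm1 = NULL,
                              epr_g_values = NULL, tol = spectro_tolerances()) {
  partials <- list()
  if (!is.null(soret_maxima_nm)) {
    partials <- c(partials, list(infer_from_uv(soret_maxima_nm, tol)))
  }
  if (!is.null(nu3_wavenumbers_cm1)) {
    partials <- c(partials, list(infer_from_rraman(nu3_wavenumbers_cm1, tol)))
  }
  if (!is.null(epr_g_values)) {
    partials <- c(partials, list(infer_from_epr(epr_g_values, tol)))
  }
  if (length(partials) == 0L) {
    stop("at least one technique's readout must be supplied", call. = FALSE)
  }
  combine_evidence(partials)
}
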