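# End-to-end scan pipeline: FASTA -> site finding -> exposure filtering ->
# window extraction -> classification -> annotated TSV report; plus the
# key-value configuration loader. The exec/hemescan script is a thin
# wrapper over these functions.

default_config <- function() {
  list(mode = "default",
       rsa_cutoff = 0.25,
       hydropathy_window = 9L,
       hydropathy_threshold = 0,
       scan_met_lys = FALSE,
       tolerances = spectro_tolerances())
}

#' Load a YAML configuration file
#'
#' Recognized keys: `mode` (`default`/`structure`), `rsa_cutoff` (RSA
#' binarization cutoff in \[0,1\]), `hydropathy_window` (odd integer >= 3),
#' `hydropathy_threshold` (numeric), `scan_met_lys` (logical; also treat Met
#' and Lys as coordination sites — rare ligands, off by default), and
#' `tolerances` (a mapping overriding entries of [spectro_tolerances()]).
#' Unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of validated configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (key in names(user)) {
    val <- user[[key]]
    switch(key,
      mode = {
        if (!is.character(val) || !val %in% c("default", "structure"))
          stop("config key 'mode': must be 'default' or 'structure'", call. = FALSE)
        cfg$mode <- val
      },
      rsa_cutoff = {
        if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
            val < 0 || val > 1)
          stop("config key 'rsa_cutoff': must be a number in [0,1]", call. = FALSE)
        cfg$rsa_cutoff <- as.numeric(val)
      },
      hydropathy_window = {
        if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
            val < 3 || val %% 2 != 1)
          stop("config key 'hydropathy_window': must be an odd integer >= 3",
               call. = FALSE)
        cfg$hydropathy_window <- as.integer(val)
      },
      hydropathy_threshold = {
        if (!is.numeric(val) || length(val) != 1L || is.na(val))
          stop("config key 'hydropathy_threshold': must be a number", call. = FALSE)
        cfg$hydropathy_threshold <- as.numeric(val)
      },
      scan_met_lys = {
        if (!is.logical(val) || length(val) != 1L || is.na(val))
          stop("config key 'scan_met_lys': must be true or false", call. = FALSE)
        cfg$scan_met_lys <- val
      },
      tolerances = {
        if (!is.list(val))
          stop("config key 'tolerances': must be a mapping", call. = FALSE)
        bad <- setdiff(names(val), names(cfg$tolerances))
        if (length(bad) > 0L)
          stop(sprintf("config key 'tolerances': unknown entries %s",
                       paste(bad, collapse = ", ")), call. = FALSE)
        for (tk in names(val)) {
          tv <- val[[tk]]
          if (!is.numeric(tv) || length(tv) != 1L || is.na(tv))
            stop(sprintf("config key 'tolerances.%s': must be a number", tk),
                 call. = FALSE)
          cfg$tolerances[[tk]] <- as.numeric(tv)
        }
      })
  }
  cfg
}

#' Build the scan report for one record
#'
#' @param record A [protein_record()].
#' @param mode `"default"` (exposure filtering) or `"structure"` (report
#'   every site; the user curates against the known structure).
#' @param profile Optional [accessibility_profile()]; in default mode a
#'   missing profile falls back to [builtin_predictor()].
#' @param config Configuration list, see [load_config()].
#' @return Data frame of report rows (see [write_report()]); also used by
#'   [run_scan()].
#' @export
scan_report <- function(record, mode = c("default", "structure"),
                        profile = NULL, config = load_config()) {
  mode <- match.arg(mode)
  ligands <- if (isTRUE(config$scan_met_lys)) c(COORDINATING, "M", "K")
             else COORDINATING
  sites <- find_coordination_sites(record, ligands)
  if (mode == "default" && is.null(profile)) {
    message(sprintf("record '%s': no accessibility data supplied; using the builtin hydropathy heuristic (a stand-in for a real exposure predictor such as WESA)",
                    record$identifier))
    profile <- builtin_predictor(record, config$hydropathy_window,
                                 config$hydropathy_threshold)
  }
  kept <- filter_sites(sites, profile, mode)
  windows <- lapply(kept$position, function(p) {
    extract_window(record, p, ligands = ligands)
  })
  rows <- lapply(windows, function(w) {
    classifiable <- w$ligand %in% COORDINATING
    data.frame(record_id = record$identifier, position = w$position,
               axial_ligand = w$ligand, motif = w$sequence,
               net_charge = w$net_charge,
               class = if (classifiable) assign_class(w)$label else "unclassified",
               exposure = if (is.null(profile)) "unknown"
                          else profile$labels[w$position],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) == 0L) {
    data.frame(record_id = character(0), position = integer(0),
               axial_ligand = character(0), motif = character(0),
               net_charge = integer(0), class = character(0),
               exposure = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, rows)
  }
  out$comments <- lapply(windows, function(w) {
    if (w$ligand %in% COORDINATING) annotate_window(w)
    else "rare axial ligand (Met/Lys): unclassified"
  })
  attr(out, "stage_counts") <- c(sites_found = nrow(sites),
                                 sites_kept = nrow(kept))
  out
}

#' Run the full scan pipeline over a FASTA file
#'
#' Reads the FASTA input, finds candidate coordination sites per record,
#' filters them by solvent exposure (default mode), extracts and classifies
#' the motif windows and assembles the annotated report. Per-stage counts
#' (records, sites found, sites surviving the exposure filter, rows written)
#' are emitted as messages.
#'
#' @param fasta FASTA path or text (see [read_fasta()]).
#' @param mode `"default"` or `"structure"`.
#' @param accessibility Optional accessibility file path (see
#'   [read_accessibility_file()]); only valid for single-record input.
#' @param config Path to a YAML config file, or a list from [load_config()].
#' @param out Optional output TSV path; written via [write_report()].
#' @return The report data frame, invisibly.
#' @export
run_scan <- function(fasta, mode = c("default", "structure"),
                     accessibility = NULL, config = NULL, out = NULL) {
  mode <- match.arg(mode)
  cfg <- if (is.null(config)) load_config()
         else if (is.character(config)) load_config(config)
         else config
  records <- read_fasta(fasta)
  if (!is.null(accessibility) && length(records) != 1L) {
    stop("an accessibility file applies to exactly one record; got multi-record input",
         call. = FALSE)
  }
  reports <- lapply(records, function(rec) {
    profile <- if (!is.null(accessibility)) {
      read_accessibility_file(accessibility, rec, cfg$rsa_cutoff)
    } else NULL
    rep <- scan_report(rec, mode, profile, cfg)
    counts <- attr(rep, "stage_counts")
    message(sprintf("record '%s': %d site(s) found, %d after exposure filter",
                    rec$identifier, counts["sites_found"], counts["sites_kept"]))
    rep
  })
  report <- do.call(rbind, c(reports, list(make.row.names = FALSE)))
  message(sprintf("%d record(s) scanned, %d report row(s)",
                  length(records), nrow(report)))
  if (!is.null(out)) write_report(report, out)
  invisible(report)
}
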