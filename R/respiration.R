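OCR_PHASES <- c("baseline", "oligomycin", "FCCP", "antimycin_rotenone")

#' Summarize an OCR trace into one value per injection phase
#'
#' The flux protocol takes three repeated OCR measurements per phase; the
#' default summary is their mean (median and last-measurement summaries are
#' available, since the source protocol does not state its summary
#' statistic). A phase with fewer or more than 3 measurements is summarized
#' anyway and flagged.
#'
#' @param trace data frame for one subject with columns `phase` and
#'   `ocr_pmol_min` (pMol/min).
#' @param summary_rule `"mean"`, `"median"` or `"last"`.
#' @return named numeric vector over the four phases, with attribute
#'   `flags`.
#' @export
#' @examples
#' tr <- data.frame(phase = rep(c("baseline", "oligomycin", "FCCP",
#'                                "antimycin_rotenone"), each = 3),
#'                  ocr_pmol_min = rep(c(100, 40, 160, 10), each = 3))
#' phase_summaries(tr)
phase_summaries <- function(trace, summary_rule = c("mean", "median",
                                                    "last")) {
  summary_rule <- match.arg(summary_rule)
  assert_columns(trace, c("phase", "ocr_pmol_min"))
  missing <- setdiff(OCR_PHASES, trace$phase)
  if (length(missing)) {
    stop_serumir("OCR trace is missing phase(s): %s",
                 paste(missing, collapse = ", "),
                 class = "serumir_trace_error")
  }
  flags <- character()
  out <- vapply(OCR_PHASES, function(ph) {
    x <- trace$ocr_pmol_min[trace$phase == ph]
    if (length(x) != 3L) {
      flags <<- c(flags, sprintf("replicate_count_%s_%d", ph, length(x)))
    }
    switch(summary_rule,
           mean = mean(x), median = stats::median(x), last = x[length(x)])
  }, numeric(1))
  attr(out, "flags") <- flags
  out
}

#' Derive bioenergetic parameters from phase-level OCR values
#'
#' Definitions (all pMol/min): non-mitochondrial respiration is the OCR
#' remaining after antimycin A + rotenone; basal = baseline - non-mito;
#' ATP-linked respiration ALR = baseline - oligomycin; proton-leak
#' respiration PLR = oligomycin - non-mito; maximal respiratory capacity
#' MRC = FCCP - non-mito; reserve capacity RC = MRC - basal. Efficiency
#' ratios ALR/PLR and MRC/PLR are undefined (NA, flagged) when PLR <= 0.
#' By construction basal = ALR + PLR and RC = MRC - basal exactly. Negative
#' derived values are returned with QC flags, never clipped.
#'
#' @param phase_values named numeric vector over the four phases (as from
#'   [phase_summaries()]).
#' @return list of class `respiration_params` with elements `non_mito`,
#'   `basal`, `ALR`, `PLR`, `MRC`, `RC`, `alr_over_plr`, `mrc_over_plr`,
#'   `qc_flags`.
#' @export
#' @examples
#' derive_parameters(c(baseline = 100, oligomycin = 40, FCCP = 160,
#'                     antimycin_rotenone = 10))
derive_parameters <- function(phase_values) {
  missing <- setdiff(OCR_PHASES, names(phase_values))
  if (length(missing)) {
    stop_serumir("phase value(s) missing: %s",
                 paste(missing, collapse = ", "),
                 class = "serumir_trace_error")
  }
  b <- phase_values[["baseline"]]; o <- phase_values[["oligomycin"]]
  f <- phase_values[["FCCP"]]; a <- phase_values[["antimycin_rotenone"]]
  non_mito <- a
  ALR <- b - o
  PLR <- o - a
  basal <- ALR + PLR    # algebraically baseline - non_mito; exact identity
  MRC <- f - a
  RC <- MRC - basal
  flags <- character()
  if (basal < 0) flags <- c(flags, "negative_basal")
  if (ALR < 0) flags <- c(flags, "negative_ALR")
  if (PLR < 0) flags <- c(flags, "negative_PLR")
  if (RC < 0) flags <- c(flags, "negative_RC")
  if (PLR <= 0) {
    flags <- c(flags, "ratios_undefined")
    alr_over_plr <- NA_real_; mrc_over_plr <- NA_real_
  } else {
    alr_over_plr <- ALR / PLR; mrc_over_plr <- MRC / PLR
  }
  structure(list(non_mito = non_mito, basal = basal, ALR = ALR, PLR = PLR,
                 MRC = MRC, RC = RC, alr_over_plr = alr_over_plr,
                 mrc_over_plr = mrc_over_plr, qc_flags = flags),
            class = "respiration_params")
}

#' @export
print.respiration_params <- function(x, ...) {
  cat(sprintf(paste0("respiration (pMol/min): basal %.1f, ALR %.1f, ",
                     "PLR %.1f, MRC %.1f, RC %.1f, non-mito %.1f\n"),
              x$basal, x$ALR, x$PLR, x$MRC, x$RC, x$non_mito))
  if (length(x$qc_flags)) cat("  flags:", paste(x$qc_flags, collapse = ", "),
                              "\n")
  invisible(x)
}

#' Quality-control report for an OCR trace
#'
#' Flags wrong replicate counts, a non-responding injection (phase means
#' that violate the expected ordering: oligomycin and antimycin should fall
#' below baseline, FCCP should rise above it), negative raw readings, and
#' noisy phases (within-phase coefficient of variation above
#' `cv_threshold`).
#'
#' @param trace one subject's trace (columns `phase`, `ocr_pmol_min`).
#' @param cv_threshold within-phase CV above which a phase is flagged.
#' @return character vector of flags (empty when well formed).
#' @export
qc_trace <- function(trace, cv_threshold = 0.25) {
  assert_columns(trace, c("phase", "ocr_pmol_min"))
  flags <- character()
  means <- vapply(OCR_PHASES, function(ph) {
    x <- trace$ocr_pmol_min[trace$phase == ph]
    if (length(x) != 3L) {
      flags <<- c(flags, sprintf("replicate_count_%s_%d", ph, length(x)))
    }
    if (length(x) > 1L && mean(x) != 0 &&
        abs(stats::sd(x) / mean(x)) > cv_threshold) {
      flags <<- c(flags, sprintf("noisy_phase_%s", ph))
    }
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  if (any(trace$ocr_pmol_min < 0)) flags <- c(flags, "negative_raw_ocr")
  if (!anyNA(means)) {
    if (means[["oligomycin"]] > means[["baseline"]]) {
      flags <- c(flags, "no_oligomycin_response")
    }
    if (means[["antimycin_rotenone"]] > means[["oligomycin"]]) {
      flags <- c(flags, "no_antimycin_response")
    }
    if (means[["FCCP"]] < means[["baseline"]]) {
      flags <- c(flags, "no_fccp_response")
    }
  }
  unique(flags)
}

#' Bioenergetic parameters for every subject in an OCR table
#'
#' Applies [phase_summaries()], [derive_parameters()] and [qc_trace()] per
#' subject.
#'
#' @param ocr long OCR table (columns `subject_id`, `phase`,
#'   `ocr_pmol_min`).
#' @inheritParams phase_summaries
#' @inheritParams qc_trace
#' @return data frame with one row per subject: `subject_id`, `non_mito`,
#'   `basal`, `ALR`, `PLR`, `MRC`, `RC`, `alr_over_plr`, `mrc_over_plr`,
#'   `qc_flags` (semicolon-joined).
#' @export
respiration_table <- function(ocr, summary_rule = "mean",
                              cv_threshold = 0.25) {
  assert_columns(ocr, c("subject_id", "phase", "ocr_pmol_min"))
  per <- split(ocr, ocr$subject_id)
  out <- do.call(rbind, lapply(names(per), function(sid) {
    tr <- per[[sid]]
    pv <- phase_summaries(tr, summary_rule)
    p <- derive_parameters(pv)
    flags <- unique(c(attr(pv, "flags"), p$qc_flags,
                      qc_trace(tr, cv_threshold)))
    data.frame(subject_id = sid, non_mito = p$non_mito, basal = p$basal,
               ALR = p$ALR, PLR = p$PLR, MRC = p$MRC, RC = p$RC,
               alr_over_plr = p$alr_over_plr,
               mrc_over_plr = p$mrc_over_plr,
               qc_flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[match(unique(ocr$subject_id), out$subject_id), , drop = FALSE]
}
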