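#' Curated human whole-blood candidate biomarker panel
#'
#' The 15-transcript chronic-neuropathic-back-pain (CNBP) candidate panel
#' from the human whole-blood screen that this workflow operationalizes:
#' per gene, the two-group ANOVA p-value, the signed fold change in CNBP
#' relative to healthy controls, and the external-evidence flags
#' (\code{ca}: present in the prior-correlation analysis output;
#' \code{literature}: published association with pain pathways). These
#' printed values are consumed as inputs — e.g. to exercise the
#' refinement gate or as the human side of the cross-species concordance
#' report — not re-derived.
#'
#' @return data.frame with columns \code{gene}, \code{p}, \code{direction},
#'   \code{fc}, \code{ca}, \code{literature}.
#' @seealso [refinePanel()], [ratValidationResults()], [concordance()]
#' @export
humanCandidatePanel <- function() {
  data.frame(
    gene = c("CASP5", "CLU", "DPP3", "ELF3", "FAM99A", "ICOSLG",
             "LIN28A", "MC1R", "NLRC4", "ORM2", "ARHGAP11B", "RNF185",
             "RNU6-76P", "TIMP1", "TLR5"),
    p = c(0.0449, 0.0489, 0.0028, 0.0095, 0.0017, 0.0007,
          0.0183, 0.0005, 0.0437, 0.0225, 0.0025, 0.0032,
          0.0049, 0.0049, 0.0428),
    direction = c("up", "up", "up", "up", "up", "up",
                  "down", "up", "up", "up", "up", "down",
                  "down", "up", "up"),
    fc = c(2.23, 1.85, 1.50, 1.62, 1.64, 1.20,
           1.50, 1.40, 1.99, 1.97, 1.57, 1.68,
           1.54, 1.50, 1.75),
    ca = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
           FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
           FALSE, TRUE, FALSE),
    literature = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                   TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                   FALSE, TRUE, TRUE))
}

#' Curated rat dorsal-horn validation results
#'
#' Sham vs L5 spinal-nerve-ligation (SNL) expression changes of the rat
#' orthologs of the human candidate panel, measured in ipsilateral dorsal
#' horn by qPCR (multi-reference normalized relative quantities) or ddPCR
#' (normalized absolute copies), each with an unpaired t-test p-value and
#' the SNL/sham fold change (magnitude >= 1 with direction; a fold change
#' of exactly 1.00 keeps the upward tie-break).
#'
#' @return data.frame with columns \code{gene}, \code{p}, \code{direction},
#'   \code{fc}, \code{method} ("qpcr" or "ddpcr").
#' @seealso [concordance()], [humanRatOrthologs()]
#' @export
ratValidationResults <- function() {
  data.frame(
    gene = c("Casp4", "Clu", "Dpp3", "Icoslg", "Lin28a", "Mc1r",
             "Nlrc4", "Arhgap11a", "Rnf185", "Timp1", "Tlr5"),
    p = c(0.1951, 0.9990, 0.4670, 0.7920, 0.7860, 0.0847,
          0.5242, 0.8516, 0.3900, 0.0058, 0.6820),
    direction = c("up", "up", "down", "down", "up", "up",
                  "up", "down", "down", "up", "up"),
    fc = c(1.22, 1.00, 1.16, 1.16, 1.30, 2.72,
           1.15, 1.03, 2.18, 2.19, 1.51),
    method = c("ddpcr", "qpcr", "qpcr", "qpcr", "qpcr", "ddpcr",
               "ddpcr", "ddpcr", "qpcr", "qpcr", "qpcr"))
}

#' Curated human-to-rat ortholog map for the candidate panel
#'
#' Hand-picked ortholog (or closest high-similarity) comparisons used for
#' the cross-species concordance report, e.g. CASP5 to Casp4 and
#' ARHGAP11B to Arhgap11a. Panel genes with no usable rat counterpart
#' (no apparent ortholog, or not reliably detectable) are absent from the
#' map and come out as "untestable" in the concordance report.
#'
#' @return data.frame with columns \code{human}, \code{rat}.
#' @seealso [concordance()]
#' @export
humanRatOrthologs <- function() {
  data.frame(
    human = c("CASP5", "CLU", "DPP3", "ICOSLG", "LIN28A", "MC1R",
              "NLRC4", "ARHGAP11B", "RNF185", "TIMP1", "TLR5"),
    rat = c("Casp4", "Clu", "Dpp3", "Icoslg", "Lin28a", "Mc1r",
            "Nlrc4", "Arhgap11a", "Rnf185", "Timp1", "Tlr5"))
}
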