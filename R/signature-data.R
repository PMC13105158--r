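#' The published 11-gene perturbation-network signature
#'
#' Returns the published gene interaction perturbation network index gene
#' list: SPRR2A, SPRR2B, SPRR2E, SEC11A, PPFIA1, CROT, RAP1B, HPRT1, MRPL41,
#' S100A7 and SNRPD2. The numeric coefficients were published only as a bar
#' plot and are therefore shipped as NA: retrain them on your own cohort with
#' \code{\link{fit_signature}} before calling \code{\link{score_samples}}.
#'
#' @return a \code{SignatureModel} with 11 genes and NA coefficients.
#' @export
gipni_signature <- function() {
  genes <- c("SPRR2A", "SPRR2B", "SPRR2E", "SEC11A", "PPFIA1", "CROT",
             "RAP1B", "HPRT1", "MRPL41", "S100A7", "SNRPD2")
  signature_model(genes, rep(NA_real_, length(genes)),
                  training_cohort = "published")
}

#' Packaged synthetic 28-panel immune gene-set fixture
#'
#' Path to a small GMT file with 28 immune cell-type panels whose marker
#' genes are synthetic placeholders (IMM* identifiers), shipped so the
#' enrichment stage can be exercised without downloads. Real marker panels
#' are user-supplied GMT files.
#'
#' @return path to the packaged GMT file.
#' @export
immune_panel_fixture <- function() {
  system.file("extdata", "immune28_panels_synthetic.gmt", package = "gipni",
              mustWork = TRUE)
}
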