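#' Worked example: the five-factor murine secretome panel
#'
#' Encodes, as an [evidence_matrix()], the assay outcomes of the canonical
#' EMT6 PTIS factors (CCL2, IL1RN, IL6, LCN2, NOS2): bulk RNA-seq
#' transcript up in the resistant line, cytokine-array protein up in the
#' resistant line and down after IFNAR1 knockdown, western blot
#' confirmation for LCN2 and NOS2, ELISA confirmation for LCN2, IL6 and
#' CCL2, and qRT-PCR confirmation for all five (up in `PTR_vs_P`, down in
#' `KD_vs_PTR`).  All records are significant calls.  The preliminary
#' candidate list contains the same five genes — each is a secreted,
#' type-I IFN-regulated transcript upregulated with resistance.
#'
#' Running [derive_signature()] on this panel with the default
#' [rule_config()] reproduces the five-gene signature; the README walks
#' through it.
#'
#' @param magnitude Log2 magnitude used for the "up" records (the "down"
#'   records get its negative); the integration rule is set-logical, so
#'   any value at or above the default effect floor gives the same result.
#' @return List with `prelim` (character vector of candidates) and
#'   `evidence` (an [evidence_matrix()]).
#' @export
#' @examples
#' wx <- ptis_worked_example()
#' derive_signature(wx$evidence, wx$prelim)
ptis_worked_example <- function(magnitude = 2) {
  factors <- c("CCL2", "IL1RN", "IL6", "LCN2", "NOS2")
  rec <- function(genes, assay, comparison, direction)
    data.frame(gene = genes, assay = assay, comparison = comparison,
               direction = direction,
               magnitude = if (direction == "up") magnitude else -magnitude,
               significant = TRUE, stringsAsFactors = FALSE)
  ev <- evidence_matrix(rbind(
    rec(factors, "rnaseq", "PTR_vs_P", "up"),
    rec(factors, "array", "PTR_vs_P", "up"),
    rec(factors, "array", "KD_vs_PTR", "down"),
    rec(c("LCN2", "NOS2"), "western", "PTR_vs_P", "up"),
    rec(c("LCN2", "NOS2"), "western", "KD_vs_PTR", "down"),
    rec(c("CCL2", "IL6", "LCN2"), "elisa", "PTR_vs_P", "up"),
    rec(c("CCL2", "IL6", "LCN2"), "elisa", "KD_vs_PTR", "down"),
    rec(factors, "qrtpcr", "PTR_vs_P", "up"),
    rec(factors, "qrtpcr", "KD_vs_PTR", "down")
  ))
  list(prelim = factors, evidence = ev)
}
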