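#' Example extracted triplets from an asthma guideline
#'
#' Sixteen triplets extracted from the GINA (Global Initiative for Asthma)
#' guideline text, shipped as a small worked example of the
#' `Source,Edge,Target` interchange format: multi-word entity phrases
#' ("acute care Patients", "cell eosinophils"), prepositional relations
#' ("binds to"), a modal-only relation ("may"), and near-duplicate relation
#' surfaces ("include" vs "included") that frequency tallies must keep
#' apart.
#'
#' @return an `mlr_triplets` table of 16 complete rows.
#' @export
#' @examples
#' tab <- example_triplets()
#' top_relations(tab, k = 5)
example_triplets <- function() {
  path <- system.file("extdata", "gina_example_triplets.csv",
                      package = "mlrkg")
  read_table(path)
}
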