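#' Normalise an entity or relation label
#'
#' Lower-cases, collapses internal whitespace to single spaces, and strips
#' leading/trailing punctuation and whitespace. This is the key used for
#' duplicate elimination, graph node identity, and prediction/ground-truth
#' alignment throughout the package.
#'
#' @param x character vector of labels.
#' @return character vector of normalised labels.
#' @export
#' @examples
#' normalize_label("  Severe   Asthma. ")
normalize_label <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  x <- gsub("^[[:space:][:punct:]]+|[[:space:][:punct:]]+$", "", x)
  x
}

#' Round half away from zero
#'
#' Base [round()] rounds half to even; reported ranking metrics use the
#' conventional half-up rule so that e.g. 0.00825 prints as 0.0083 at four
#' decimal places.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (half away from zero for negatives).
#' @export
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# normalised (source, edge, target) key for one table row
triplet_key <- function(source, edge, target) {
  paste(normalize_label(source), normalize_label(edge), normalize_label(target),
        sep = "\x1f")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
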