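#' Controlled organ vocabulary
#'
#' The pipeline uses a small controlled vocabulary of organ names.  The
#' vocabulary is open: names outside it are passed through (lower-cased,
#' whitespace normalised) and flagged as custom sources rather than rejected,
#' so user-defined regions such as a tumor sub-volume or salivary gland can
#' flow through every stage.  `whole_body` is reserved: the residual-body
#' allocation stage requires it.
#'
#' @format Character vector of canonical organ names.
#' @export
ORGAN_VOCABULARY <- c(
  "blood", "heart", "liver", "lungs", "spleen", "kidneys", "intestine",
  "pancreas", "stomach", "bone", "marrow", "muscle", "tumor", "whole_body"
)

# alias table: normalised input -> canonical name
.organ_aliases <- c(
  "kidney"      = "kidneys",
  "lung"        = "lungs",
  "gut"         = "intestine",
  "intestines"  = "intestine",
  "bone_marrow" = "marrow",
  "red_marrow"  = "marrow",
  "wb"          = "whole_body",
  "body"        = "whole_body",
  "total_body"  = "whole_body",
  "tumour"      = "tumor",
  "skeleton"    = "bone"
)

#' Canonicalise organ names
#'
#' Lower-cases, trims, converts separators to underscores and resolves common
#' aliases (`"Liver"` -> `"liver"`, `"whole body"` -> `"whole_body"`,
#' `"bone marrow"` -> `"marrow"`).  Unknown names pass through normalised and
#' are flagged as custom in the `"custom"` attribute; they are never rejected.
#'
#' @param name Character vector of organ names.
#' @return Character vector of canonical names with a logical attribute
#'   `"custom"` marking entries outside the controlled vocabulary.
#' @examples
#' canonical_organ(c("Liver", "whole body", "salivary_gland"))
#' @export
canonical_organ <- function(name) {
  stopifnot(is.character(name))
  x <- tolower(trimws(name))
  x <- gsub("[[:space:]\\-]+", "_", x)
  hit <- x %in% names(.organ_aliases)
  x[hit] <- .organ_aliases[x[hit]]
  structure(x, custom = !(x %in% ORGAN_VOCABULARY))
}
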