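#' Reference phantom: organ masses and body mass
#'
#' A `phantom` holds the named organ masses (grams) and total body mass of
#' the reference animal used to extrapolate concentration curves (%IA/g) to
#' whole-organ activity (%IA) and to allocate the residual (remainder) body.
#' Organs absent from the mass map are implicitly part of the remainder.
#'
#' @param organ_masses_g Named numeric vector, grams per organ; all positive.
#' @param body_mass_g Total body mass, grams; must be at least the sum of the
#'   listed organ masses.
#' @return An object of class `phantom`.
#' @examples
#' phantom(c(liver = 1.37, kidneys = 0.34), body_mass_g = 25)
#' @export
phantom <- function(organ_masses_g, body_mass_g) {
  stopifnot(is.numeric(organ_masses_g), !is.null(names(organ_masses_g)))
  names(organ_masses_g) <- as.character(canonical_organ(names(organ_masses_g)))
  if (any(!is.finite(organ_masses_g)) || any(organ_masses_g <= 0))
    stop("all organ masses must be positive and finite", call. = FALSE)
  if (anyDuplicated(names(organ_masses_g)))
    stop("duplicated organ names in mass map", call. = FALSE)
  body_mass_g <- as.numeric(body_mass_g)
  if (length(body_mass_g) != 1L || !is.finite(body_mass_g) || body_mass_g <= 0)
    stop("'body_mass_g' must be a single positive number", call. = FALSE)
  if (sum(organ_masses_g) > body_mass_g + 1e-9)
    stop("sum of organ masses exceeds body mass", call. = FALSE)
  structure(list(organ_masses_g = organ_masses_g, body_mass_g = body_mass_g),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> body mass %g g, %d organs (%g g listed, %g g remainder)\n",
              x$body_mass_g, length(x$organ_masses_g),
              sum(x$organ_masses_g),
              x$body_mass_g - sum(x$organ_masses_g)))
  print(x$organ_masses_g)
  invisible(x)
}

#' Organ mass lookup
#'
#' @param x A [phantom()].
#' @param organ Organ names.
#' @param extra_masses_g Named numeric vector of user-supplied masses for
#'   regions outside the phantom (typically `c(tumor = ...)`).
#' @return Numeric vector of masses in grams; errors on organs that are
#'   neither in the phantom nor in `extra_masses_g`.
#' @export
organ_mass <- function(x, organ, extra_masses_g = NULL) {
  stopifnot(inherits(x, "phantom"))
  organ <- as.character(canonical_organ(organ))
  pool <- x$organ_masses_g
  if (!is.null(extra_masses_g)) {
    names(extra_masses_g) <- as.character(canonical_organ(names(extra_masses_g)))
    pool[names(extra_masses_g)] <- extra_masses_g
  }
  miss <- setdiff(organ, names(pool))
  if (length(miss))
    stop(sprintf("no mass for organ(s): %s (supply via 'extra_masses_g')",
                 paste(miss, collapse = ", ")), call. = FALSE)
  unname(pool[organ])
}

#' Default 25-g mouse phantom
#'
#' Representative organ masses for a 25 g adult mouse, the scale of the
#' standardised phantoms used for murine dosimetry.  Values are nominal
#' reference masses, not a reproduction of any published Monte Carlo model.
#'
#' @return A [phantom()].
#' @export
mouse_phantom <- function() {
  phantom(
    organ_masses_g = c(
      blood = 1.70, heart = 0.15, liver = 1.37, lungs = 0.15,
      spleen = 0.10, kidneys = 0.34, intestine = 2.00, pancreas = 0.30,
      stomach = 0.25, bone = 2.50, marrow = 0.25, muscle = 9.00
    ),
    body_mass_g = 25
  )
}

#' Read / write a phantom definition file
#'
#' JSON with fields `body_mass_g` and `organs` (name -> grams), e.g.
#' `{"body_mass_g": 25, "organs": {"liver": 1.37}}`.
#'
#' @param path File location.
#' @return `read_phantom()` returns a [phantom()]; `write_phantom()` returns
#'   `path` invisibly.
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$body_mass_g) || is.null(obj$organs))
    stop("phantom file must contain 'body_mass_g' and 'organs'", call. = FALSE)
  phantom(unlist(obj$organs), obj$body_mass_g)
}

#' @rdname read_phantom
#' @param x A [phantom()].
#' @export
write_phantom <- function(x, path) {
  stopifnot(inherits(x, "phantom"))
  jsonlite::write_json(
    list(body_mass_g = x$body_mass_g, organs = as.list(x$organ_masses_g)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
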