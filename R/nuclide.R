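#' Radionuclide physical constants
#'
#' A `nuclide` bundles the physical constants the pipeline needs: the
#' physical half-life (hours) and, for the toy S-value generator only, the
#' mean energy emitted per decay (MeV).  The decay constant
#' \eqn{\lambda = \ln 2 / T_{1/2}} is always derived from the half-life,
#' never stored separately.
#'
#' @param name Character identifier, e.g. `"Lu-177"`.
#' @param half_life_h Physical half-life in hours; must be positive and finite.
#' @param mean_energy_mev Mean energy emitted per decay in MeV (locally
#'   absorbed emissions).  Only consulted by [generate_svalues()]; may be `NA`
#'   for nuclides used purely for decay bookkeeping.
#'
#' @return An object of class `nuclide` (a named list).
#' @examples
#' lu <- nuclide("Lu-177", half_life_h = 159.5, mean_energy_mev = 0.1473)
#' decay_constant(lu)           # ln(2)/159.5 per hour
#' @seealso [lu177()], [y86()], [decay_constant()]
#' @export
nuclide <- function(name, half_life_h, mean_energy_mev = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  half_life_h <- as.numeric(half_life_h)
  if (length(half_life_h) != 1L || !is.finite(half_life_h) || half_life_h <= 0)
    stop("'half_life_h' must be a single positive finite number", call. = FALSE)
  mean_energy_mev <- as.numeric(mean_energy_mev)
  if (length(mean_energy_mev) != 1L ||
      (!is.na(mean_energy_mev) && mean_energy_mev < 0))
    stop("'mean_energy_mev' must be a single nonnegative number or NA",
         call. = FALSE)
  structure(
    list(name = name, half_life_h = half_life_h,
         mean_energy_mev = mean_energy_mev),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s: T1/2 = %g h (lambda = %.6g /h)",
              x$name, x$half_life_h, decay_constant(x)))
  if (!is.na(x$mean_energy_mev))
    cat(sprintf(", mean energy = %g MeV/decay", x$mean_energy_mev))
  cat("\n")
  invisible(x)
}

#' Decay constant of a nuclide
#'
#' @param x A [nuclide()].
#' @return \eqn{\lambda = \ln 2 / T_{1/2}} in 1/hour.
#' @export
decay_constant <- function(x) {
  stopifnot(inherits(x, "nuclide"))
  log(2) / x$half_life_h
}

#' Built-in nuclides for the Lu-177 / Y-86 theranostic pair
#'
#' `lu177()` is the beta-emitting therapeutic nuclide (half-life 159.5 h,
#' mean locally absorbed energy 0.1473 MeV per decay, dominated by the beta
#' spectrum).  `y86()` is the positron-emitting imaging surrogate
#' (half-life 14.74 h); its emitted energy is irrelevant to the dose engine
#' because measured curves are decay-corrected before use.
#'
#' @return A [nuclide()].
#' @examples
#' lu177()$half_life_h    # 159.5
#' @export
lu177 <- function() nuclide("Lu-177", half_life_h = 159.5,
                            mean_energy_mev = 0.1473)

#' @rdname lu177
#' @export
y86 <- function() nuclide("Y-86", half_life_h = 14.74)

# resolve a nuclide given either a nuclide object or a known name
as_nuclide <- function(x) {
  if (inherits(x, "nuclide")) return(x)
  if (is.character(x) && length(x) == 1L) {
    key <- toupper(gsub("[^A-Za-z0-9]", "", x))
    if (key %in% c("LU177", "177LU")) return(lu177())
    if (key %in% c("Y86", "86Y")) return(y86())
    stop(sprintf("unknown nuclide '%s'; pass a nuclide() object", x),
         call. = FALSE)
  }
  stop("expected a nuclide object or a known nuclide name", call. = FALSE)
}
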