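#' Source-organ activity curves (%IA versus time)
#'
#' A `source_curves` object holds whole-organ activity, percent of injected
#' activity (%IA), per source organ over time.  It records where each curve
#' came from (`provenance`: `"delineated"` for imaged organs, `"residual"`
#' for mass-allocated remainder organs) and which physical decay, if any, is
#' embedded in the values: `physical_decay = NA` means the curve is purely
#' biological (decay-corrected to injection).
#'
#' @param organ,time_h,pct_ia,provenance Column vectors.
#' @param physical_decay Name of the nuclide whose physical decay is embedded
#'   in `pct_ia`, or `NA` for a biological (decay-corrected) curve.
#' @return Data frame of class `source_curves`.
#' @keywords internal
source_curves <- function(organ, time_h, pct_ia,
                          provenance = "delineated",
                          physical_decay = NA_character_) {
  organ <- as.character(canonical_organ(as.character(organ)))
  out <- data.frame(organ = organ, time_h = as.numeric(time_h),
                    pct_ia = as.numeric(pct_ia),
                    provenance = rep_len(provenance, length(organ)),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$pct_ia)) || any(out$pct_ia < 0))
    stop("whole-organ activity must be finite and >= 0", call. = FALSE)
  out <- out[order(out$organ, out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, physical_decay = physical_decay,
            class = c("source_curves", "data.frame"))
}

#' @export
print.source_curves <- function(x, ...) {
  pd <- attr(x, "physical_decay")
  cat(sprintf("<source_curves> %d organ(s); physical decay: %s\n",
              length(unique(x$organ)),
              if (is.na(pd)) "none (biological)" else pd))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Concentration to whole-organ activity
#'
#' Extrapolates %IA/g concentration curves to whole-organ %IA using the
#' phantom's organ masses: `%IA(t) = %IA/g(t) * mass_src`.  The reserved
#' `whole_body` organ is converted with the total body mass, giving the
#' body-level %IA curve required by [allocate_residual()].  Regions without
#' a phantom mass (typically the tumor) take theirs from `extra_masses_g`.
#'
#' @param tac A [tac_table()]; must be decay-corrected to injection so the
#'   curves are biological.
#' @param phantom A [phantom()].
#' @param extra_masses_g Named masses for organs absent from the phantom,
#'   e.g. `c(tumor = 0.4)`.
#' @return A [source_curves()] object with provenance `"delineated"` and no
#'   physical decay embedded.
#' @export
to_whole_organ <- function(tac, phantom, extra_masses_g = NULL) {
  stopifnot(inherits(tac, "tac_table"), inherits(phantom, "phantom"))
  if (attr(tac, "decay_corrected_to") != "injection")
    stop("time-activity table is not decay-corrected to injection; ",
         "remove the measured nuclide's decay first", call. = FALSE)
  organs <- unique(tac$organ)
  extra <- extra_masses_g
  if ("whole_body" %in% organs)
    extra <- c(extra, c(whole_body = phantom$body_mass_g))
  mass <- organ_mass(phantom, tac$organ, extra)
  source_curves(tac$organ, tac$time_h, tac$pct_ia_per_g * mass,
                provenance = "delineated")
}

#' Resample curves to a common time grid
#'
#' Linear interpolation in time on %IA; outside the sampled range the first
#' or last value is held constant.
#'
#' @param curves A [source_curves()] object.
#' @param times Target time grid, hours.
#' @return A [source_curves()] on the new grid.
#' @export
resample_curves <- function(curves, times) {
  stopifnot(inherits(curves, "source_curves"))
  times <- sort(unique(as.numeric(times)))
  pieces <- lapply(split(as.data.frame(curves), curves$organ), function(d) {
    y <- if (nrow(d) == 1L) rep(d$pct_ia, length(times))
         else stats::approx(d$time_h, d$pct_ia, xout = times, rule = 2)$y
    data.frame(organ = d$organ[1L], time_h = times, pct_ia = y,
               provenance = d$provenance[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  source_curves(out$organ, out$time_h, out$pct_ia, out$provenance,
                physical_decay = attr(curves, "physical_decay"))
}

#' Allocate residual whole-body activity to non-delineated organs
#'
#' Activity not assigned to the delineated source organs is distributed over
#' the remaining tissues in proportion to their masses.  Two modes:
#'
#' * `"conserve"` (default): each non-delineated organ receives
#'   `(%IA_WB(t) - sum of delineated %IA(t)) * mass_src / (mass_body - sum of
#'   delineated masses)`.  The part of the remainder mass not covered by
#'   listed organs is emitted as a `remainder` pseudo-organ, so that the
#'   source set conserves activity exactly: the sum of all source curves
#'   equals the whole-body curve at every sampled time.
#' * `"strict_paper"`: the literal mass-fraction rule
#'   `%IA_src(t) = %IA_WB(t) * mass_src / mass_body`, with no subtraction of
#'   delineated organs.  This can double-count activity (the delineated
#'   organs' share is not removed) and is provided for comparability.
#'
#' If the delineated organs exceed the whole-body activity at some time the
#' default is a hard error; `clamp = TRUE` instead clamps the residual to
#' zero there with a warning.
#'
#' @param curves Delineated [source_curves()] including a `whole_body` curve
#'   (all biological, no physical decay embedded).  Curves on different
#'   grids are first resampled to the union of sampled times.
#' @param phantom A [phantom()].
#' @param mode `"conserve"` or `"strict_paper"`.
#' @param extra_masses_g Masses for delineated organs outside the phantom.
#' @param clamp Clamp-and-warn instead of erroring on conservation violation.
#' @return A [source_curves()] object: the delineated organs unchanged plus
#'   residual curves (provenance `"residual"`) for the non-delineated
#'   phantom organs (and `remainder`).
#' @export
allocate_residual <- function(curves, phantom,
                              mode = c("conserve", "strict_paper"),
                              extra_masses_g = NULL, clamp = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(curves, "source_curves"), inherits(phantom, "phantom"))
  if (!is.na(attr(curves, "physical_decay")))
    stop("allocate on biological curves, before applying physical decay",
         call. = FALSE)
  if (!"whole_body" %in% curves$organ)
    stop("a 'whole_body' curve is required for residual allocation",
         call. = FALSE)
  times <- sort(unique(curves$time_h))
  same_grid <- all(vapply(split(curves$time_h, curves$organ),
                          function(t) identical(sort(t), times), logical(1)))
  if (!same_grid) curves <- resample_curves(curves, times)

  delineated <- setdiff(unique(curves$organ), "whole_body")
  wb <- curves$pct_ia[curves$organ == "whole_body"]
  delin_mat <- vapply(delineated, function(o)
    curves$pct_ia[curves$organ == o], numeric(length(times)))
  delin_sum <- if (length(delineated))
    rowSums(matrix(delin_mat, nrow = length(times))) else
    numeric(length(times))
  delin_mass <- if (length(delineated))
    sum(organ_mass(phantom, delineated, extra_masses_g)) else 0

  residual_organs <- setdiff(names(phantom$organ_masses_g), delineated)
  res_mass <- phantom$organ_masses_g[residual_organs]
  carcass <- phantom$body_mass_g - delin_mass - sum(res_mass)
  if (carcass > 1e-9) res_mass <- c(res_mass, remainder = carcass)

  if (mode == "conserve") {
    deficit <- wb - delin_sum
    if (any(deficit < -1e-9 * pmax(wb, 1))) {
      if (!clamp)
        stop("delineated organs exceed whole-body activity: conservation ",
             "violated (set clamp = TRUE to clamp the residual to zero)",
             call. = FALSE)
      warning("delineated organs exceed whole-body activity; residual clamped to zero")
    }
    deficit <- pmax(deficit, 0)
    denom <- phantom$body_mass_g - delin_mass
    if (denom <= 0)
      stop("delineated masses exhaust the body mass; nothing to allocate",
           call. = FALSE)
    res <- lapply(names(res_mass), function(o)
      data.frame(organ = o, time_h = times,
                 pct_ia = deficit * res_mass[[o]] / denom,
                 provenance = "residual", stringsAsFactors = FALSE))
  } else {
    res <- lapply(names(res_mass), function(o)
      data.frame(organ = o, time_h = times,
                 pct_ia = wb * res_mass[[o]] / phantom$body_mass_g,
                 provenance = "residual", stringsAsFactors = FALSE))
  }
  keep <- as.data.frame(curves)[curves$organ != "whole_body",
                                c("organ", "time_h", "pct_ia", "provenance")]
  out <- rbind(keep, do.call(rbind, res))
  source_curves(out$organ, out$time_h, out$pct_ia, out$provenance)
}

#' Transpose biological kinetics onto another nuclide's physical decay
#'
#' In surrogate-imaging dosimetry the biodistribution is measured with an
#' imaging nuclide and, after decay correction, treated as the shared
#' biological kinetics of the labelled compound.  The therapy nuclide's
#' physical decay is then imposed:
#' `activity(t) = biological %IA(t) * exp(-lambda_therapeutic * t)`.
#'
#' In `reverse` mode the function removes an embedded physical decay
#' (multiplies by `exp(+lambda * t)`), recovering the biological curve; a
#' reverse-then-forward round trip with the same nuclide is the identity.
#'
#' @param curves A [source_curves()] object.  Forward mode requires a
#'   biological curve (no physical decay embedded); reverse mode requires
#'   the decay of `nuclide` to be embedded.
#' @param nuclide The [nuclide()] whose decay to apply (forward) or remove
#'   (reverse).
#' @param reverse Remove instead of apply.
#' @return A [source_curves()] with the `physical_decay` attribute updated.
#' @export
transpose_isotope <- function(curves, nuclide, reverse = FALSE) {
  stopifnot(inherits(curves, "source_curves"))
  nuclide <- as_nuclide(nuclide)
  lam <- decay_constant(nuclide)
  embedded <- attr(curves, "physical_decay")
  if (!reverse) {
    if (!is.na(embedded))
      stop(sprintf("curves already carry %s physical decay; remove it first ",
                   embedded),
           "with transpose_isotope(..., reverse = TRUE)", call. = FALSE)
    fac <- exp(-lam * curves$time_h)
    pd <- nuclide$name
  } else {
    if (is.na(embedded) || embedded != nuclide$name)
      stop(sprintf("curves do not carry %s physical decay", nuclide$name),
           call. = FALSE)
    fac <- exp(lam * curves$time_h)
    pd <- NA_character_
  }
  source_curves(curves$organ, curves$time_h, curves$pct_ia * fac,
                curves$provenance, physical_decay = pd)
}
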