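#' End-to-end image-derived dosimetry
#'
#' Convenience wrapper running the full organ-level dosimetry chain on a
#' decay-corrected time-activity table:
#'
#' 1. [cohort_mean()] if the table carries cohort replicates;
#' 2. [to_whole_organ()] — %IA/g to whole-organ %IA on the phantom;
#' 3. [allocate_residual()] — residual-body activity to non-delineated
#'    organs (requires a `whole_body` curve);
#' 4. [transpose_isotope()] — impose the therapeutic nuclide's physical
#'    decay on the biological kinetics;
#' 5. [integrate_tac()] — cumulated activity with the chosen head and tail
#'    models;
#' 6. [absorbed_dose()] — MIRD convolution with the S-value matrix.
#'
#' @param tac A [tac_table()] (decay-corrected to injection).
#' @param phantom A [phantom()].
#' @param svalues An [svalue_matrix()].
#' @param therapeutic Therapeutic [nuclide()] (default [lu177()]).
#' @param tumor_mass_g Tumor mass in grams (default 0.4 g, a ~400 mm^3
#'   graft); extend `extra_masses_g` instead for additional custom regions.
#' @param extra_masses_g Named masses for further non-phantom regions.
#' @param allocation_mode,clamp Passed to [allocate_residual()].
#' @param tail,head_model Passed to [integrate_tac()].
#' @return A [absorbed_dose()] report (`dose_report`).
#' @examples
#' coh <- generate_cohort(cohort_preset("4T07", cv = 0), n = 1, seed = 1)
#' sv <- generate_svalues(mouse_phantom(), lu177(),
#'                        extra_masses_g = c(tumor = 0.4, remainder = 7.79))
#' rep <- estimate_dosimetry(coh$tac, mouse_phantom(), sv)
#' @export
estimate_dosimetry <- function(tac, phantom, svalues,
                               therapeutic = lu177(),
                               tumor_mass_g = 0.4, extra_masses_g = NULL,
                               allocation_mode = c("conserve", "strict_paper"),
                               clamp = FALSE,
                               tail = c("physical_decay", "fitted_terminal",
                                        "none"),
                               head_model = c("constant", "linear_zero")) {
  allocation_mode <- match.arg(allocation_mode)
  tail <- match.arg(tail)
  head_model <- match.arg(head_model)
  stopifnot(inherits(tac, "tac_table"))
  if (!is.null(tac$animal)) tac <- cohort_mean(tac)
  masses <- extra_masses_g
  if ("tumor" %in% tac$organ && !"tumor" %in% names(masses %||% character()) &&
      !"tumor" %in% names(phantom$organ_masses_g))
    masses <- c(masses, c(tumor = tumor_mass_g))
  curves <- to_whole_organ(tac, phantom, extra_masses_g = masses)
  if ("whole_body" %in% curves$organ)
    curves <- allocate_residual(curves, phantom, mode = allocation_mode,
                                extra_masses_g = masses, clamp = clamp)
  decayed <- transpose_isotope(curves, therapeutic)
  cum <- integrate_tac(decayed, tail = tail, nuclide = therapeutic,
                       head_model = head_model)
  absorbed_dose(cum, svalues)
}

#' Remainder-carcass mass of a phantom for a delineated organ set
#'
#' When residual allocation emits a `remainder` pseudo-organ (see
#' [allocate_residual()]), the S-value matrix needs a mass for it.  This
#' helper returns `body mass - listed organ masses - extra masses`, i.e. the
#' carcass mass the pseudo-organ represents.
#'
#' @param phantom A [phantom()].
#' @param extra_masses_g Named masses of regions outside the phantom that
#'   hold activity (e.g. the tumor).
#' @return Mass in grams.
#' @export
remainder_mass <- function(phantom, extra_masses_g = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  m <- phantom$body_mass_g - sum(phantom$organ_masses_g) -
    sum(extra_masses_g %||% 0)
  if (m < 0) stop("listed masses exceed body mass", call. = FALSE)
  m
}
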