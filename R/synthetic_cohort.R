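#' Organ kinetic models for the synthetic cohort generator
#'
#' Noise-free organ kinetics are represented as sums of exponentials,
#' \eqn{A(t) = \sum_i c_i e^{-r_i t}}, which covers the three shapes the
#' generator offers and keeps every time-integral available in closed form
#' (the ground truth oracles emitted by [generate_cohort()]):
#'
#' * `km_washout(value0, half_life_h)` — monoexponential washout from
#'   `value0` at injection (blood-pool clearance);
#' * `km_uptake_washout(peak, peak_time_h, washout_half_life_h)` — the
#'   uptake-washout difference of exponentials
#'   \eqn{A(t) \propto e^{-\lambda_w t} - e^{-\lambda_u t}} normalised so the
#'   maximum equals `peak` at `peak_time_h`; requires
#'   \eqn{\lambda_w < \lambda_u} (washout slower than uptake), which bounds
#'   the admissible peak time below \eqn{1/\lambda_w};
#' * `km_plateau(peak, peak_time_h, decline_half_life_h)` — rise to a
#'   plateau with slow terminal decline (sustained tumor retention); the
#'   same difference form with a long washout half-life.
#'
#' @param value0 Value at t = 0, %IA/g (washout model).
#' @param half_life_h Washout half-life, hours.
#' @param peak Peak value, %IA/g.
#' @param peak_time_h Time of the peak, hours.
#' @param washout_half_life_h,decline_half_life_h Terminal half-life, hours.
#' @return An `organ_kinetics` object (coefficients, rates, kind).
#' @export
km_washout <- function(value0, half_life_h) {
  stopifnot(value0 > 0, half_life_h > 0)
  structure(list(coef = value0, rate = log(2) / half_life_h,
                 kind = "washout", peak_time_h = 0,
                 peak = value0),
            class = "organ_kinetics")
}

#' @rdname km_washout
#' @export
km_uptake_washout <- function(peak, peak_time_h, washout_half_life_h) {
  stopifnot(peak > 0, peak_time_h > 0, washout_half_life_h > 0)
  lw <- log(2) / washout_half_life_h
  if (peak_time_h >= 1 / lw)
    stop("peak_time_h is too late for this washout half-life: ",
         "uptake would have to be slower than washout (lambda_w >= lambda_u)",
         call. = FALSE)
  # solve ln(lu/lw) = (lu - lw) * tp for the uptake rate lu > lw
  f <- function(lu) log(lu / lw) - (lu - lw) * peak_time_h
  hi <- lw * 2
  while (f(hi) > 0) hi <- hi * 2
  lu <- stats::uniroot(f, c(lw * (1 + 1e-9), hi), tol = 1e-14)$root
  norm <- exp(-lw * peak_time_h) - exp(-lu * peak_time_h)
  structure(list(coef = peak / norm * c(1, -1), rate = c(lw, lu),
                 kind = "uptake_washout", peak_time_h = peak_time_h,
                 peak = peak),
            class = "organ_kinetics")
}

#' @rdname km_washout
#' @export
km_plateau <- function(peak, peak_time_h, decline_half_life_h) {
  k <- km_uptake_washout(peak, peak_time_h, decline_half_life_h)
  k$kind <- "plateau"
  k
}

#' Evaluate a noise-free organ kinetic curve
#'
#' @param model An `organ_kinetics` object or a [kinetic_spec()] (then
#'   `organ` selects the model).
#' @param t Times, hours.
#' @param organ Organ name when `model` is a spec.
#' @return %IA/g values.
#' @export
kinetic_value <- function(model, t, organ = NULL) {
  if (inherits(model, "kinetic_spec")) model <- .spec_model(model, organ)
  stopifnot(inherits(model, "organ_kinetics"))
  vapply(t, function(ti) sum(model$coef * exp(-model$rate * ti)), numeric(1))
}

#' Closed-form time integral of a kinetic curve
#'
#' \eqn{\int_0^\infty A(t) e^{-\lambda t} dt = \sum_i c_i / (r_i + \lambda)};
#' `lambda = 0` gives the biological integral, a positive `lambda` the
#' integral under additional physical decay.  Used as the analytic ground
#' truth against which numerical integration is checked.
#'
#' @inheritParams kinetic_value
#' @param lambda Additional decay constant, 1/h (default 0).
#' @return Integral in %IA/g h (or %IA h if the curve is whole-organ).
#' @export
kinetic_integral <- function(model, lambda = 0, organ = NULL) {
  if (inherits(model, "kinetic_spec")) model <- .spec_model(model, organ)
  stopifnot(inherits(model, "organ_kinetics"), lambda >= 0)
  sum(model$coef / (model$rate + lambda))
}

.spec_model <- function(spec, organ) {
  stopifnot(inherits(spec, "kinetic_spec"), !is.null(organ))
  organ <- as.character(canonical_organ(organ))
  m <- spec$organs[[organ]]
  if (is.null(m))
    stop(sprintf("no kinetic model for organ '%s' in this spec", organ),
         call. = FALSE)
  m
}

#' Cohort kinetic specification
#'
#' Bundles per-organ kinetic models with the noise structure of a synthetic
#' cohort.  Noise is multiplicative lognormal: an optional per-animal
#' amplitude factor (`cv_animal`, shared across an animal's time points —
#' inter-animal variation in uptake level, not in rates) and a
#' per-observation factor (`cv`, measurement scatter).  Both factors have
#' mean 1, so cohort means stay calibrated to the noise-free curves.
#'
#' @param organs Named list of `organ_kinetics` models (names are organ
#'   names).
#' @param cv Per-observation coefficient of variation (default 0.12, the
#'   scale of printed mean-to-SD ratios in small-animal ROI data).
#' @param cv_animal Per-animal amplitude coefficient of variation
#'   (default 0).
#' @return Object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(organs, cv = 0.12, cv_animal = 0) {
  stopifnot(is.list(organs), length(organs) > 0, !is.null(names(organs)))
  names(organs) <- as.character(canonical_organ(names(organs)))
  ok <- vapply(organs, inherits, logical(1), what = "organ_kinetics")
  if (!all(ok)) stop("all organ models must be organ_kinetics objects",
                     call. = FALSE)
  stopifnot(cv >= 0, cv_animal >= 0)
  structure(list(organs = organs, cv = cv, cv_animal = cv_animal),
            class = "kinetic_spec")
}

#' Built-in cohort presets for the two tumor models
#'
#' Returns a [kinetic_spec()] whose noise-free curves are calibrated to the
#' published summary kinetics of the alkylphosphocholine agent in the two
#' syngeneic TNBC graft models:
#'
#' * tumor: sustained accretion peaking at 12.9 %IA/g (`"4T07"`) or
#'   11.0 %IA/g (`"4T1"`) at 72 h, with slow terminal decline (prolonged
#'   retention);
#' * liver (hepatobiliary clearance route): peak at 24 h of 9.3 (`"4T07"`)
#'   or 11.3 (`"4T1"`) %IA/g, then gradual decline;
#' * blood: monoexponential clearance with a 20.4 h half-life;
#' * kidneys, spleen, bone, muscle (and the other normal organs): below
#'   6 %IA/g at all sampled times;
#' * `whole_body`: body-level retention (100 %IA at injection over a 25 g
#'   body) with slow biological elimination, so residual-body allocation is
#'   exercisable end to end.
#'
#' @param model `"4T07"` (nonmetastatic graft) or `"4T1"` (metastatic).
#' @param cv,cv_animal Noise structure, see [kinetic_spec()].
#' @return A [kinetic_spec()].
#' @examples
#' sp <- cohort_preset("4T07")
#' kinetic_value(sp, 72, organ = "tumor")   # 12.9
#' @export
cohort_preset <- function(model = c("4T07", "4T1"), cv = 0.12,
                          cv_animal = 0) {
  if (!is.character(model) || !model[1L] %in% c("4T07", "4T1"))
    stop("unknown preset '", model[1L], "'; available presets: 4T07, 4T1",
         call. = FALSE)
  model <- match.arg(model)
  tumor_peak <- if (model == "4T07") 12.9 else 11.0
  liver_peak <- if (model == "4T07") 9.3 else 11.3
  kinetic_spec(
    organs = list(
      blood      = km_washout(15, half_life_h = 20.4),
      heart      = km_uptake_washout(5.0, peak_time_h = 4,
                                     washout_half_life_h = 24),
      lungs      = km_uptake_washout(3.0, peak_time_h = 4,
                                     washout_half_life_h = 30),
      liver      = km_uptake_washout(liver_peak, peak_time_h = 24,
                                     washout_half_life_h = 48),
      spleen     = km_uptake_washout(3.0, peak_time_h = 24,
                                     washout_half_life_h = 60),
      kidneys    = km_uptake_washout(4.5, peak_time_h = 4,
                                     washout_half_life_h = 36),
      intestine  = km_uptake_washout(5.0, peak_time_h = 24,
                                     washout_half_life_h = 30),
      bone       = km_uptake_washout(2.0, peak_time_h = 24,
                                     washout_half_life_h = 96),
      muscle     = km_uptake_washout(0.8, peak_time_h = 24,
                                     washout_half_life_h = 96),
      tumor      = km_plateau(tumor_peak, peak_time_h = 72,
                              decline_half_life_h = 300),
      whole_body = km_washout(100 / 25, half_life_h = 60)
    ),
    cv = cv, cv_animal = cv_animal
  )
}

#' Generate a synthetic multi-animal cohort
#'
#' Samples each organ's noise-free kinetic curve at the requested times for
#' `n` animals, applying the spec's multiplicative lognormal noise.  With
#' `cv = cv_animal = 0` every replicate equals the noise-free curve.  The
#' returned ground truth carries the noise-free table and the closed-form
#' biological integrals, so downstream numerical stages can be checked
#' against analytic oracles.
#'
#' @param spec A [kinetic_spec()].
#' @param times Sampling times, hours; non-empty, within \[0, 400\].
#'   Default 4/24/48/72 h, the standard longitudinal small-animal PET grid.
#' @param n Cohort size (animals).
#' @param seed Integer seed; mandatory so cohorts are reproducible.
#' @return List with elements
#'   `tac` — a [tac_table()] with an `animal` column;
#'   `truth` — list with `noise_free` (a `tac_table` at `times`),
#'   `integral_pct_ia_h` (named vector of analytic biological integrals,
#'   %IA/g h) and `spec`.
#' @export
generate_cohort <- function(spec, times = c(4, 24, 48, 72), n = 10, seed) {
  stopifnot(inherits(spec, "kinetic_spec"))
  times <- as.numeric(times)
  if (!length(times) || any(!is.finite(times)) ||
      any(times < 0) || any(times > 400))
    stop("'times' must be non-empty and within [0, 400] hours", call. = FALSE)
  times <- sort(unique(times))
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (missing(seed) || is.null(seed))
    stop("a seed is mandatory for cohort generation", call. = FALSE)

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(as.integer(seed))

  organs <- names(spec$organs)
  clean <- lapply(spec$organs, kinetic_value, t = times)
  sdlog_obs <- sqrt(log(1 + spec$cv^2))
  sdlog_ani <- sqrt(log(1 + spec$cv_animal^2))

  rows <- vector("list", n)
  for (a in seq_len(n)) {
    amp <- if (spec$cv_animal > 0)
      stats::rlnorm(length(organs), -sdlog_ani^2 / 2, sdlog_ani) else
      rep(1, length(organs))
    names(amp) <- organs
    obs <- lapply(organs, function(o) {
      eps <- if (spec$cv > 0)
        stats::rlnorm(length(times), -sdlog_obs^2 / 2, sdlog_obs) else
        rep(1, length(times))
      clean[[o]] * amp[[o]] * eps
    })
    rows[[a]] <- data.frame(
      animal = sprintf("animal_%03d", a),
      organ = rep(organs, each = length(times)),
      time_h = rep(times, length(organs)),
      pct_ia_per_g = unlist(obs), stringsAsFactors = FALSE)
  }
  all_rows <- do.call(rbind, rows)
  tac <- tac_table(all_rows$organ, all_rows$time_h, all_rows$pct_ia_per_g,
                   animal = all_rows$animal,
                   decay_corrected_to = "injection", nuclide = "Y-86")
  noise_free <- tac_table(rep(organs, each = length(times)),
                          rep(times, length(organs)),
                          unlist(clean, use.names = FALSE),
                          decay_corrected_to = "injection", nuclide = "Y-86")
  truth <- list(
    noise_free = noise_free,
    integral_pct_ia_h = vapply(spec$organs, kinetic_integral, numeric(1)),
    spec = spec
  )
  list(tac = tac, truth = truth)
}

#' Cohort mean time-activity table
#'
#' Averages a cohort table (with an `animal` column) across animals,
#' producing the mean +/- SD, n per organ and time — the form in which ROI
#' summaries enter the dosimetry pipeline.
#'
#' @param tac A [tac_table()] with an `animal` column.
#' @return A [tac_table()] without `animal`, with `sd` and `n` filled in.
#' @export
cohort_mean <- function(tac) {
  stopifnot(inherits(tac, "tac_table"))
  if (is.null(tac$animal)) stop("table has no 'animal' column", call. = FALSE)
  key <- interaction(tac$organ, tac$time_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(as.data.frame(tac), key), function(d)
    data.frame(organ = d$organ[1L], time_h = d$time_h[1L],
               pct_ia_per_g = mean(d$pct_ia_per_g),
               sd = stats::sd(d$pct_ia_per_g), n = nrow(d),
               stringsAsFactors = FALSE)))
  tac_table(agg$organ, agg$time_h, agg$pct_ia_per_g, sd = agg$sd, n = agg$n,
            decay_corrected_to = attr(tac, "decay_corrected_to"),
            nuclide = attr(tac, "nuclide"))
}
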