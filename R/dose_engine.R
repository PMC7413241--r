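#' Cumulated activity by piecewise time integration
#'
#' Integrates a decayed source-organ activity curve to cumulated activity
#' per unit injected activity (MBq h per MBq injected; numerically
#' `integral of %IA(t) dt / 100`).  The integral is assembled piecewise:
#'
#' * head, `[0, t1]`: constant back-extrapolation at the first measured
#'   value (`head_model = "constant"`, default) or a linear ramp from zero
#'   (`"linear_zero"`);
#' * body, `[t1, t_last]`: trapezoid rule on the sampled, decayed curve;
#' * tail, `[t_last, Inf)`: `"physical_decay"` (default) assumes the
#'   biological retention stays constant after the last sample, so the tail
#'   is `A(t_last) / lambda` with lambda the therapeutic nuclide's decay
#'   constant — the conservative standard when terminal kinetics are
#'   unresolved; `"fitted_terminal"` instead decays the tail with the
#'   effective rate fitted to the last points of the curve itself (at least
#'   `fit_points`, default 2); `"none"` truncates at the last sample.
#'
#' @param curves A [source_curves()] object with physical decay applied
#'   (see [transpose_isotope()]).
#' @param tail `"physical_decay"`, `"fitted_terminal"` or `"none"`.
#' @param nuclide The therapeutic [nuclide()] for the physical tail;
#'   defaults to the nuclide whose decay is embedded in `curves`.
#' @param head_model `"constant"` or `"linear_zero"`.
#' @param fit_points Number of terminal points for the fitted tail.
#' @return Data frame of class `cumulated_activity` with columns `organ`,
#'   `a_tilde_mbq_h` and `tail_model`, plus grid metadata attributes.
#' @examples
#' cur <- source_curves("liver", c(0, 10), c(10, 10),
#'                      physical_decay = "Lu-177")
#' integrate_tac(cur, tail = "none")  # rectangle: 10% * 10 h / 100 = 1 MBq h
#' @export
integrate_tac <- function(curves,
                          tail = c("physical_decay", "fitted_terminal", "none"),
                          nuclide = NULL,
                          head_model = c("constant", "linear_zero"),
                          fit_points = 2L) {
  tail <- match.arg(tail)
  head_model <- match.arg(head_model)
  stopifnot(inherits(curves, "source_curves"))
  embedded <- attr(curves, "physical_decay")
  if (is.na(embedded))
    stop("curves carry no physical decay; apply transpose_isotope() first ",
         "(a purely biological curve has a divergent physical tail)",
         call. = FALSE)
  if (tail == "physical_decay") {
    nuc <- if (is.null(nuclide)) as_nuclide(embedded) else as_nuclide(nuclide)
    lam <- decay_constant(nuc)
  }

  res <- lapply(split(as.data.frame(curves), curves$organ), function(d) {
    t <- d$time_h; a <- d$pct_ia
    head_area <- if (t[1L] > 0) {
      if (head_model == "constant") t[1L] * a[1L] else t[1L] * a[1L] / 2
    } else 0
    body_area <- if (length(t) > 1L)
      sum(diff(t) * (utils::head(a, -1L) + utils::tail(a, -1L)) / 2) else 0
    tail_area <- switch(tail,
      none = 0,
      physical_decay = {
        if (a[length(a)] > 0 && lam <= 0)
          stop("zero decay constant with nonzero terminal activity: ",
               "divergent integral", call. = FALSE)
        a[length(a)] / lam
      },
      fitted_terminal = {
        k <- length(t)
        if (a[k] <= 0) 0 else {
          np <- max(2L, min(as.integer(fit_points), k))
          idx <- seq.int(k - np + 1L, k)
          if (any(a[idx] <= 0))
            stop("fitted_terminal tail needs positive terminal samples",
                 call. = FALSE)
          f <- fit_exponential(t[idx], a[idx], terms = 1L)
          a[k] / f$rates[1L]
        }
      })
    data.frame(organ = d$organ[1L],
               a_tilde_mbq_h = (head_area + body_area + tail_area) / 100,
               tail_model = tail, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out,
            physical_decay = embedded, head_model = head_model,
            units = "MBq_h_per_MBq",
            class = c("cumulated_activity", "data.frame"))
}

#' Absorbed dose per injected activity (MIRD convolution)
#'
#' Sums dose contributions from every source organ, including the target
#' itself: \deqn{\tilde D_{target} = \sum_{src} \tilde A_{src} \cdot
#' S(target \leftarrow src)} giving the dose coefficient in Gy per MBq
#' injected.  Every source with cumulated activity must appear among the
#' S-matrix sources (hard error otherwise); targets missing some S-matrix
#' source column simply receive no contribution from it.
#'
#' @param cumulated A `cumulated_activity` data frame from
#'   [integrate_tac()].
#' @param s An [svalue_matrix()] declared in Gy/(MBq h).
#' @return Object of class `dose_report`: data frame with columns `target`
#'   and `gy_per_mbq`, with provenance metadata attributes.
#' @export
absorbed_dose <- function(cumulated, s) {
  stopifnot(inherits(cumulated, "cumulated_activity"),
            inherits(s, "svalue_matrix"))
  if (s$units_label != "Gy_per_MBq_h")
    stop(sprintf("S-matrix units '%s' do not match cumulated-activity units MBq h: expected 'Gy_per_MBq_h'",
                 s$units_label), call. = FALSE)
  miss <- setdiff(cumulated$organ, colnames(s$values))
  if (length(miss))
    stop(sprintf("source organ(s) missing from S-matrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  a <- stats::setNames(cumulated$a_tilde_mbq_h, cumulated$organ)
  src <- intersect(colnames(s$values), names(a))
  if (length(src) < ncol(s$values))
    warning(sprintf("no cumulated activity for S-matrix source(s): %s (contributing zero)",
                    paste(setdiff(colnames(s$values), src), collapse = ", ")))
  dose <- as.numeric(s$values[, src, drop = FALSE] %*% a[src])
  out <- data.frame(target = rownames(s$values), gy_per_mbq = dose,
                    stringsAsFactors = FALSE)
  structure(out,
            tail_model = unique(cumulated$tail_model),
            head_model = attr(cumulated, "head_model"),
            nuclide = s$nuclide,
            physical_decay = attr(cumulated, "physical_decay"),
            class = c("dose_report", "data.frame"))
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("<dose_report> nuclide %s, tail %s, head %s\n",
              attr(x, "nuclide"), paste(attr(x, "tail_model"), collapse = "/"),
              attr(x, "head_model")))
  df <- as.data.frame(x)
  df$gy_per_mbq <- round(df$gy_per_mbq, 2)   # report precision 0.01 Gy/MBq
  print(df, ...)
  invisible(x)
}

#' Dose coefficient lookup
#' @param report A [absorbed_dose()] report.
#' @param target Target organ name.
#' @return Gy/MBq.
#' @export
dose_coefficient <- function(report, target) {
  stopifnot(inherits(report, "dose_report"))
  target <- as.character(canonical_organ(target))
  i <- match(target, report$target)
  if (anyNA(i))
    stop(sprintf("no dose coefficient for target '%s'",
                 target[which(is.na(i))[1L]]), call. = FALSE)
  report$gy_per_mbq[i]
}

#' Tumor-to-organ (or any) dose-coefficient ratio
#'
#' @param report A [absorbed_dose()] report, or a named numeric vector of
#'   coefficients (Gy/MBq) for desk calculations from published values.
#' @param numerator,denominator Target organ names.
#' @return Dimensionless coefficient ratio (summaries conventionally quote
#'   it at one decimal).
#' @examples
#' dose_ratio(c(tumor = 2.04, liver = 1.12), "tumor", "liver")  # 1.82
#' @export
dose_ratio <- function(report, numerator, denominator) {
  get1 <- function(organ) {
    if (inherits(report, "dose_report")) dose_coefficient(report, organ)
    else {
      organ <- as.character(canonical_organ(organ))
      if (!organ %in% names(report))
        stop(sprintf("no coefficient named '%s'", organ), call. = FALSE)
      unname(report[[organ]])
    }
  }
  den <- get1(denominator)
  if (!is.finite(den) || den <= 0)
    stop("denominator coefficient must be positive: ratio undefined",
         call. = FALSE)
  get1(numerator) / den
}
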