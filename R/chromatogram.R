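#' Chromatogram peak set
#'
#' Integrated peak areas from a radio-chromatogram (HPLC or TLC), with one
#' peak designated as the main product peak.  Used for radiochemical purity
#' quality control.
#'
#' @param areas Nonnegative, finite peak areas (at least one).
#' @param retention_time_min Optional retention-time labels, minutes.
#' @param main Index of the main product peak (default first).
#' @return Object of class `chromatogram_peaks`.
#' @export
chromatogram_peaks <- function(areas, retention_time_min = NULL, main = 1L) {
  areas <- as.numeric(areas)
  if (!length(areas)) stop("at least one peak is required", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("peak areas must be finite and nonnegative", call. = FALSE)
  main <- as.integer(main)
  if (main < 1L || main > length(areas))
    stop("'main' must index one of the peaks", call. = FALSE)
  if (!is.null(retention_time_min))
    stopifnot(length(retention_time_min) == length(areas))
  structure(list(areas = areas, retention_time_min = retention_time_min,
                 main = main),
            class = "chromatogram_peaks")
}

#' Radiochemical purity from integrated peak areas
#'
#' Purity (%) is the area of the designated main radiopeak divided by the
#' total integrated area of all visible peaks, times 100.  The result is
#' scale-invariant and always lies in \[0, 100\].
#'
#' @param peaks A [chromatogram_peaks()].
#' @return Purity in percent.
#' @examples
#' # a secondary peak at 6% of the main peak's area
#' peak_purity(chromatogram_peaks(c(100, 6)))   # 94.34
#' @export
peak_purity <- function(peaks) {
  stopifnot(inherits(peaks, "chromatogram_peaks"))
  total <- sum(peaks$areas)
  if (total <= 0)
    stop("total integrated area is zero: purity undefined", call. = FALSE)
  100 * peaks$areas[peaks$main] / total
}
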