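#' S-value matrix (dose kernel)
#'
#' An `svalue_matrix` stores the dose-kernel lookup S(target <- source): the
#' absorbed dose in a target region per unit cumulated activity in a source
#' region.  The internal unit convention is Gy per (MBq h); the units label
#' is mandatory and checked by the dose engine before convolution.
#'
#' @param values Numeric matrix, targets in rows, sources in columns, with
#'   dimnames; all entries nonnegative.
#' @param units_label Units string; the dose engine requires
#'   `"Gy_per_MBq_h"`.
#' @param nuclide Name of the nuclide the kernel was computed for
#'   (informational).
#' @return An object of class `svalue_matrix`.
#' @export
svalue_matrix <- function(values, units_label = "Gy_per_MBq_h",
                          nuclide = NA_character_) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("S-value matrix needs target row names and source column names",
         call. = FALSE)
  rownames(values) <- as.character(canonical_organ(rownames(values)))
  colnames(values) <- as.character(canonical_organ(colnames(values)))
  if (any(!is.finite(values)) || any(values < 0))
    stop("S-values must be finite and nonnegative", call. = FALSE)
  if (!is.character(units_label) || length(units_label) != 1L ||
      !nzchar(units_label))
    stop("a units label is mandatory", call. = FALSE)
  structure(list(values = values, units_label = units_label,
                 nuclide = nuclide),
            class = "svalue_matrix")
}

#' @export
print.svalue_matrix <- function(x, ...) {
  cat(sprintf("<svalue_matrix> %d targets x %d sources, units %s, nuclide %s\n",
              nrow(x$values), ncol(x$values), x$units_label, x$nuclide))
  print(signif(x$values, 4))
  invisible(x)
}

#' Read / write an S-value matrix file
#'
#' Delimited text: metadata lines `# units=...` and `# nuclide=...`, then a
#' header row of source names (first cell `target`) and one row per target.
#'
#' @param path File location.
#' @return `read_svalues()` returns an [svalue_matrix()].
#' @export
read_svalues <- function(path) {
  lines <- readLines(path)
  meta <- .parse_meta(grep("^[[:space:]]*#", lines, value = TRUE))
  body <- grep("^[[:space:]]*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (tolower(names(df)[1L]) != "target")
    stop("first column of an S-matrix file must be 'target'", call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (is.null(meta[["units"]]))
    stop("S-matrix file must declare '# units=...'", call. = FALSE)
  svalue_matrix(m, units_label = meta[["units"]],
                nuclide = meta[["nuclide"]] %||% NA_character_)
}

#' @rdname read_svalues
#' @param x An [svalue_matrix()].
#' @export
write_svalues <- function(x, path) {
  stopifnot(inherits(x, "svalue_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# units=%s", x$units_label),
               if (!is.na(x$nuclide)) sprintf("# nuclide=%s", x$nuclide)), con)
  df <- data.frame(target = rownames(x$values),
                   formatC(x$values, digits = 15, format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("target", colnames(x$values))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# MeV/(g decay) -> Gy/(MBq h): J per MeV, per-gram to per-kg, decays per MBq h
.MEV_PER_G_TO_GY <- 1.602176634e-13 * 1000
.DECAYS_PER_MBQ_H <- 1e6 * 3600

#' Analytic toy S-value generator
#'
#' Builds an organ-level S-value matrix from first-principles energy
#' bookkeeping, as an exercisable stand-in for Monte Carlo transport-derived
#' rodent dose kernels (which are consumed as input files when available).
#' Each decay emits `mean_energy_mev`; a fraction `self_fraction` (the
#' absorbed fraction phi) is deposited in the source organ itself and a
#' fraction `cross_fraction` leaks out, shared among the other organs in
#' proportion to their masses (equivalently: a uniform dose to the rest of
#' the listed tissue).  Then
#' \deqn{S(self \leftarrow self) = k \Delta \phi / m_{self}}
#' with \eqn{k} the conversion from MeV/(g decay) to Gy/(MBq h).
#' For a soft beta emitter whose range (< 1 mm) is small compared to organ
#' dimensions, `self_fraction = 1` and `cross_fraction = 0` is the sensible
#' default; reduce `self_fraction` for millimetre-scale organs or tumors.
#'
#' @param phantom A [phantom()] providing organ masses.
#' @param nuclide A [nuclide()] with `mean_energy_mev` set.
#' @param organs Organs to include; defaults to all phantom organs.
#' @param self_fraction Absorbed fraction phi in (0, 1].
#' @param cross_fraction Leaked fraction in \[0, 1); `self_fraction +
#'   cross_fraction` must not exceed 1 (energy conservation).
#' @param extra_masses_g Masses for organs outside the phantom (e.g. tumor).
#' @return An [svalue_matrix()] in Gy/(MBq h).
#' @examples
#' sv <- generate_svalues(mouse_phantom(), lu177(), organs = c("liver"))
#' @export
generate_svalues <- function(phantom, nuclide, organs = NULL,
                             self_fraction = 1, cross_fraction = 0,
                             extra_masses_g = NULL) {
  stopifnot(inherits(phantom, "phantom"))
  nuclide <- as_nuclide(nuclide)
  if (is.na(nuclide$mean_energy_mev))
    stop("nuclide must carry 'mean_energy_mev' to generate S-values",
         call. = FALSE)
  if (self_fraction <= 0 || self_fraction > 1)
    stop("'self_fraction' must be in (0, 1]", call. = FALSE)
  if (cross_fraction < 0 || cross_fraction >= 1)
    stop("'cross_fraction' must be in [0, 1)", call. = FALSE)
  if (self_fraction + cross_fraction > 1)
    stop("'self_fraction' + 'cross_fraction' exceeds 1: energy is not conserved",
         call. = FALSE)
  if (is.null(organs))
    organs <- union(names(phantom$organ_masses_g),
                    names(extra_masses_g %||% character()))
  organs <- as.character(canonical_organ(organs))
  m <- organ_mass(phantom, organs, extra_masses_g)
  names(m) <- organs
  k <- .MEV_PER_G_TO_GY * .DECAYS_PER_MBQ_H
  delta <- nuclide$mean_energy_mev
  S <- matrix(0, length(organs), length(organs),
              dimnames = list(organs, organs))
  for (src in organs) {
    S[src, src] <- k * delta * self_fraction / m[src]
    if (cross_fraction > 0 && length(organs) > 1L) {
      rest <- sum(m[setdiff(organs, src)])
      # mass-weighted energy share => equal dose to every non-self target
      S[setdiff(organs, src), src] <- k * delta * cross_fraction / rest
    }
  }
  svalue_matrix(S, units_label = "Gy_per_MBq_h", nuclide = nuclide$name)
}
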