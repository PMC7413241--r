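#' Time-activity tables (%IA/g versus time)
#'
#' A `tac_table` is the pipeline's primary input: sampled activity
#' concentration curves, one or more organs, expressed as percent injected
#' activity per gram of tissue (%IA/g) against time post-injection in hours.
#' Time zero is injection.  Every table carries an explicit decay-correction
#' flag (`decay_corrected_to`): `"injection"` means physical decay of the
#' measured nuclide has been removed, so the curve reflects biological
#' kinetics only; `"none"` means raw measured activity.
#'
#' @param organ Character vector of organ names (canonicalised with
#'   [canonical_organ()]).
#' @param time_h Numeric vector, hours post-injection; per organ the times
#'   must be unique (they are sorted ascending).
#' @param pct_ia_per_g Numeric vector of concentrations, %IA/g, nonnegative.
#' @param sd Optional numeric dispersion (%IA/g) per row.
#' @param n Optional integer replicate count per row.
#' @param animal Optional identifier when the table holds cohort replicates.
#' @param decay_corrected_to `"injection"` (default) or `"none"`.
#' @param nuclide Name of the measured nuclide, informational.
#'
#' @return A data frame of class `tac_table` with columns `organ`, `time_h`,
#'   `pct_ia_per_g`, `sd`, `n` (and `animal` if given) and attributes
#'   `decay_corrected_to` and `nuclide`.  Rows are sorted by organ (and
#'   animal) then time.
#' @examples
#' tac_table(organ = c("tumor", "tumor"), time_h = c(24, 4),
#'           pct_ia_per_g = c(12.9, 7.5))
#' @export
tac_table <- function(organ, time_h, pct_ia_per_g, sd = NA_real_,
                      n = NA_integer_, animal = NULL,
                      decay_corrected_to = c("injection", "none"),
                      nuclide = NA_character_) {
  decay_corrected_to <- match.arg(decay_corrected_to)
  organ <- as.character(canonical_organ(as.character(organ)))
  time_h <- as.numeric(time_h)
  pct_ia_per_g <- as.numeric(pct_ia_per_g)
  k <- length(organ)
  stopifnot(length(time_h) == k, length(pct_ia_per_g) == k)
  if (any(!is.finite(time_h)) || any(time_h < 0))
    stop("'time_h' must be finite and >= 0", call. = FALSE)
  bad <- which(!is.finite(pct_ia_per_g) | pct_ia_per_g < 0)
  if (length(bad))
    stop(sprintf("negative or non-finite concentration at row %d",
                 bad[1L]), call. = FALSE)
  out <- data.frame(
    organ = organ, time_h = time_h, pct_ia_per_g = pct_ia_per_g,
    sd = rep_len(as.numeric(sd), k), n = rep_len(as.integer(n), k),
    stringsAsFactors = FALSE
  )
  if (!is.null(animal)) out$animal <- rep_len(animal, k)
  key <- if (is.null(animal)) list(out$organ, out$time_h)
         else list(out$animal, out$organ, out$time_h)
  out <- out[do.call(order, key), , drop = FALSE]
  rownames(out) <- NULL
  grp <- if (is.null(animal)) out$organ else paste(out$animal, out$organ)
  dup <- unlist(tapply(out$time_h, grp, function(t) duplicated(t)))
  if (any(dup))
    stop("duplicate time points within an organ; times must be strictly increasing",
         call. = FALSE)
  structure(out, decay_corrected_to = decay_corrected_to, nuclide = nuclide,
            class = c("tac_table", "data.frame"))
}

#' Read a time-activity table file
#'
#' The file is comma-delimited with header columns
#' `organ,time_h,pct_ia_per_g[,sd,n]` and optional metadata lines prefixed
#' `#` of the form `# key=value`; recognised keys are `decay_corrected_to`
#' (value `injection` or `none`) and `nuclide`.  Time must be supplied in
#' hours and declared as such by the `time_h` column name; any other time
#' column name (e.g. `time_d`) is a hard error, so day/hour mix-ups fail
#' loudly instead of silently scaling doses by 24.
#'
#' @param path File to read.
#' @param decay_corrected_to Override for files without the metadata line;
#'   default follows standard surrogate-imaging practice (`"injection"`).
#' @return A [tac_table()] with times sorted ascending within organ.
#' @export
read_tac <- function(path, decay_corrected_to = NULL) {
  lines <- readLines(path)
  meta_lines <- grep("^[[:space:]]*#", lines, value = TRUE)
  meta <- .parse_meta(meta_lines)
  body <- grep("^[[:space:]]*#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty time-activity file", call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(trimws(names(df)))
  tcol <- grep("^time", names(df), value = TRUE)
  if (length(tcol) == 1L && tcol != "time_h")
    stop(sprintf("time column '%s' found; times must be in hours in a column named 'time_h'",
                 tcol), call. = FALSE)
  for (col in c("organ", "time_h", "pct_ia_per_g"))
    if (!col %in% names(df))
      stop(sprintf("missing required column '%s'", col), call. = FALSE)
  df$pct_ia_per_g <- as.numeric(df$pct_ia_per_g)
  bad <- which(!is.finite(df$pct_ia_per_g) | df$pct_ia_per_g < 0)
  if (length(bad))
    stop(sprintf("negative or non-finite concentration at data row %d",
                 bad[1L]), call. = FALSE)
  dc <- decay_corrected_to %||% meta[["decay_corrected_to"]] %||% "injection"
  tac_table(
    organ = df$organ, time_h = df$time_h, pct_ia_per_g = df$pct_ia_per_g,
    sd = if ("sd" %in% names(df)) df$sd else NA_real_,
    n = if ("n" %in% names(df)) df$n else NA_integer_,
    animal = if ("animal" %in% names(df)) df$animal else NULL,
    decay_corrected_to = dc,
    nuclide = meta[["nuclide"]] %||% NA_character_
  )
}

#' Write a time-activity table file
#'
#' Inverse of [read_tac()]: metadata lines first, then the delimited body.
#' Numeric values are written with 15 significant digits so a write/read
#' round trip reproduces the table to the declared precision.
#'
#' @param x A [tac_table()].
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_tac <- function(x, path) {
  stopifnot(inherits(x, "tac_table"))
  meta <- c(
    sprintf("# decay_corrected_to=%s", attr(x, "decay_corrected_to")),
    if (!is.na(attr(x, "nuclide"))) sprintf("# nuclide=%s", attr(x, "nuclide"))
  )
  df <- as.data.frame(x)
  for (col in c("time_h", "pct_ia_per_g", "sd"))
    df[[col]] <- formatC(df[[col]], digits = 15, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# "# key=value" metadata lines -> named list
.parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    ln <- sub("^[[:space:]]*#[[:space:]]*", "", ln)
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(key)) out[[key]] <- val
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tac_table <- function(x, ...) {
  cat(sprintf("<tac_table> %d rows, %d organ(s); decay_corrected_to=%s, nuclide=%s\n",
              nrow(x), length(unique(x$organ)),
              attr(x, "decay_corrected_to"),
              attr(x, "nuclide")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Split a multi-organ table into per-organ curves
#'
#' @param x A [tac_table()].
#' @return Named list of `tac_table`s, one per organ.
#' @export
split_organs <- function(x) {
  stopifnot(inherits(x, "tac_table"))
  lapply(split(as.data.frame(x), x$organ), function(d)
    tac_table(d$organ, d$time_h, d$pct_ia_per_g, d$sd, d$n,
              animal = d$animal,
              decay_corrected_to = attr(x, "decay_corrected_to"),
              nuclide = attr(x, "nuclide")))
}
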