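#' Polar coordinates from two-channel signals
#'
#' Converts raw two-channel fluorescence intensities to the polar
#' coordinates used throughout array genotyping: `theta`, the relative
#' contribution of the second channel scaled to `[0, 1]`, and `R`, the
#' total signal.
#'
#' @param x,y Non-negative signal intensities for the two fluorophore
#'   channels (matrices or vectors of equal shape).
#' @return A list with components `theta = (2/pi) * atan2(y, x)` and
#'   `r = x + y`.
#' @export
theta_r_from_xy <- function(x, y) {
  if (any(x < 0, na.rm = TRUE) || any(y < 0, na.rm = TRUE))
    stop_fmt("signal intensities must be non-negative")
  list(theta = (2 / pi) * atan2(y, x), r = x + y)
}

#' Construct an intensity table
#'
#' A marker-by-sample container for two-channel array intensities.
#' Either raw channel signals (`x`, `y`) or polar coordinates
#' (`theta`, `r`) must be supplied; polar coordinates are derived from
#' the raw signals when absent. Missing cells are `NA`.
#'
#' @param markers,samples Character vectors of unique ids.
#' @param x,y Optional marker-by-sample matrices of raw signals.
#' @param theta,r Optional marker-by-sample matrices of polar
#'   coordinates (`theta` in `[0, 1]`).
#' @return An object of class `intensity_table`.
#' @export
intensity_table <- function(markers, samples, x = NULL, y = NULL,
                            theta = NULL, r = NULL) {
  markers <- as.character(markers)
  samples <- as.character(samples)
  if (anyDuplicated(markers)) stop_fmt("duplicate marker ids")
  if (anyDuplicated(samples)) stop_fmt("duplicate sample ids")
  dims <- c(length(markers), length(samples))
  shape <- function(m, nm) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (!all(dim(m) == dims))
      stop_fmt("%s must be a %d x %d matrix", nm, dims[1], dims[2])
    dimnames(m) <- list(markers, samples)
    storage.mode(m) <- "double"
    m
  }
  x <- shape(x, "x"); y <- shape(y, "y")
  theta <- shape(theta, "theta"); r <- shape(r, "r")
  if (is.null(theta)) {
    if (is.null(x) || is.null(y))
      stop_fmt("either (x, y) or (theta, r) must be supplied")
    tr <- theta_r_from_xy(x, y)
    theta <- tr$theta
    r <- tr$r
  }
  if (is.null(r)) stop_fmt("r is required when theta is supplied")
  if (any(theta < -1e-9 | theta > 1 + 1e-9, na.rm = TRUE))
    stop_fmt("theta must lie in [0, 1]")
  structure(list(markers = markers, samples = samples,
                 x = x, y = y, theta = theta, r = r),
            class = "intensity_table")
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("intensity_table: %d markers x %d samples (%s)\n",
              length(x$markers), length(x$samples),
              if (is.null(x$x)) "theta/R only" else "X/Y + theta/R"))
  invisible(x)
}

parse_allele_calls <- function(a1, a2) {
  g <- paste0(a1, a2)
  g[a1 %in% c("-", "", "N") | a2 %in% c("-", "", "N")] <- "NC"
  g[g == "BA"] <- "AB"
  assert_calls(g, "allele calls")
  g
}

#' Read a GenomeStudio-style final report
#'
#' Parses the tab-delimited long-format export convention of array
#' genotyping software: an optional bracketed `[Header]` block followed
#' by a `[Data]` section with one row per (marker, sample) and columns
#' `SNP Name`, `Sample ID`, plus either raw channel signals (`X`, `Y`)
#' or polar coordinates (`Theta`, `R`), and optionally allele calls
#' (`Allele1`, `Allele2`).
#'
#' @param path Path to the report file.
#' @return A list with `intensity` (an [intensity_table]) and `calls`
#'   (marker-by-sample character matrix of `AA/AB/BB/NC`; all `NC` when
#'   the file carries no call columns).
#' @export
read_final_report <- function(path) {
  lines <- readLines(path)
  dstart <- 1L
  hdr <- grep("^\\[", lines)
  if (length(hdr)) {
    data_tag <- grep("^\\[Data\\]", lines, ignore.case = TRUE)
    if (length(data_tag)) dstart <- data_tag[1] + 1L
    else dstart <- max(hdr) + 1L
  }
  if (dstart > length(lines))
    stop_fmt("final report has no data section")
  con <- textConnection(lines[dstart:length(lines)])
  on.exit(close(con))
  df <- utils::read.delim(con, check.names = FALSE,
                          colClasses = "character", blank.lines.skip = TRUE)
  req <- c("SNP Name", "Sample ID")
  for (column in req)
    if (!column %in% names(df))
      stop_fmt("final report is missing mandatory column '%s'", column)
  has_xy <- all(c("X", "Y") %in% names(df))
  has_tr <- all(c("Theta", "R") %in% names(df))
  if (!has_xy && !has_tr)
    stop_fmt("final report is missing mandatory column 'X/Y' or 'Theta/R'")
  markers <- unique(df[["SNP Name"]])
  samples <- unique(df[["Sample ID"]])
  if (anyDuplicated(paste(df[["SNP Name"]], df[["Sample ID"]], sep = "\r")))
    stop_fmt("duplicate (marker, sample) rows in final report")
  if (nrow(df) == 0) {
    return(list(
      intensity = intensity_table(character(), character(),
                                  theta = matrix(numeric(), 0, 0),
                                  r = matrix(numeric(), 0, 0)),
      calls = matrix(character(), 0, 0)))
  }
  i <- match(df[["SNP Name"]], markers)
  j <- match(df[["Sample ID"]], samples)
  grab <- function(column) {
    v <- suppressWarnings(as.numeric(df[[column]]))
    bad <- is.na(v) & !(df[[column]] %in% c("NA", "", "NaN"))
    if (any(bad))
      stop_fmt("non-numeric value '%s' in column '%s'",
               df[[column]][which(bad)[1]], column)
    m <- matrix(NA_real_, length(markers), length(samples),
                dimnames = list(markers, samples))
    m[cbind(i, j)] <- v
    m
  }
  it <- if (has_xy)
    intensity_table(markers, samples, x = grab("X"), y = grab("Y"))
  else
    intensity_table(markers, samples, theta = grab("Theta"), r = grab("R"))
  calls <- matrix("NC", length(markers), length(samples),
                  dimnames = list(markers, samples))
  if (all(c("Allele1", "Allele2") %in% names(df)))
    calls[cbind(i, j)] <- parse_allele_calls(df[["Allele1"]], df[["Allele2"]])
  list(intensity = it, calls = calls)
}

#' Write a final report
#'
#' Inverse of [read_final_report()]; emits a bracketed header and the
#' long-format data section.
#'
#' @param intensity An [intensity_table].
#' @param calls Optional marker-by-sample call matrix (`AA/AB/BB/NC`).
#' @param path Output path.
#' @export
write_final_report <- function(intensity, path, calls = NULL) {
  stopifnot(inherits(intensity, "intensity_table"))
  mk <- intensity$markers; sm <- intensity$samples
  grid <- expand.grid(i = seq_along(mk), j = seq_along(sm))
  df <- data.frame(`SNP Name` = mk[grid$i], `Sample ID` = sm[grid$j],
                   check.names = FALSE)
  for (field in c("x", "y")) {
    if (!is.null(intensity[[field]]))
      df[[toupper(field)]] <- intensity[[field]][cbind(grid$i, grid$j)]
  }
  df[["Theta"]] <- intensity$theta[cbind(grid$i, grid$j)]
  df[["R"]] <- intensity$r[cbind(grid$i, grid$j)]
  if (!is.null(calls)) {
    g <- calls[cbind(grid$i, grid$j)]
    df[["Allele1"]] <- ifelse(g == "NC", "-", substr(g, 1, 1))
    df[["Allele2"]] <- ifelse(g == "NC", "-", substr(g, 2, 2))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[Header]", "Content\tpolymap final report", "[Data]"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
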