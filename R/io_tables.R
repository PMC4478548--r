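# Writers/readers for the pipeline's flat tables: cluster models, ABH
# matrices, marker positions and genetic maps. All TSV; missing values
# are "NA" except ABH where "-" is the missing code.

#' Write fitted cluster models to an open TSV dialect
#'
#' One row per marker: id, status, pattern, call frequency, separation
#' score, number of components, then per-component blocks (mean theta,
#' sd theta, mean R, sd R, weight, genotype label) in ascending order of
#' mean theta. Numeric fields are serialized to 6 decimals.
#'
#' @param models A list of per-marker records, each a list with
#'   `model` (a [cluster_model]) and `classification`
#'   (from [classify_marker()]).
#' @param path Output path.
#' @export
write_cluster_file <- function(models, path) {
  kmax <- max(1L, vapply(models, function(m) m$model$k, integer(1)))
  rows <- lapply(models, function(rec) {
    m <- rec$model; cl <- rec$classification
    row <- list(marker = m$marker, status = cl$status,
                pattern = as.character(cl$pattern),
                call_frequency = round(cl$call_frequency, 6),
                separation = round(cl$separation, 6),
                n_components = m$k)
    for (c_i in seq_len(kmax)) {
      pre <- sprintf("comp%d_", c_i)
      if (c_i <= m$k) {
        row[[paste0(pre, "mean_theta")]] <- round(m$mean_theta[c_i], 6)
        row[[paste0(pre, "sd_theta")]] <- round(m$sd_theta[c_i], 6)
        row[[paste0(pre, "mean_r")]] <- round(m$mean_r[c_i], 6)
        row[[paste0(pre, "sd_r")]] <- round(m$sd_r[c_i], 6)
        row[[paste0(pre, "weight")]] <- round(m$weight[c_i], 6)
        row[[paste0(pre, "label")]] <- m$label[c_i]
      } else {
        for (f in c("mean_theta", "sd_theta", "mean_r", "sd_r", "weight",
                    "label"))
          row[[paste0(pre, f)]] <- NA
      }
    }
    as.data.frame(row, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a cluster TSV written by [write_cluster_file()]
#' @param path Path to the cluster TSV.
#' @return A list of records with `model` and `classification` entries.
#' @export
read_cluster_file <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    k <- df$n_components[i]
    idx <- seq_len(k)
    col <- function(f) unlist(df[i, sprintf("comp%d_%s", idx, f)],
                              use.names = FALSE)
    model <- cluster_model(
      marker = df$marker[i], k = k,
      mean_theta = as.numeric(col("mean_theta")),
      sd_theta = as.numeric(col("sd_theta")),
      mean_r = as.numeric(col("mean_r")),
      sd_r = as.numeric(col("sd_r")),
      weight = as.numeric(col("weight")),
      label = as.character(col("label")))
    classification <- list(status = df$status[i],
                           pattern = df$pattern[i],
                           call_frequency = df$call_frequency[i],
                           separation = df$separation[i])
    list(model = model, classification = classification)
  })
}

#' Write an ABH matrix
#'
#' @param abh Marker-by-individual character matrix with codes
#'   `A`, `H`, `B` and `-` for missing.
#' @param path Output path.
#' @param dialect `"tsv"` (markers as rows, individuals as columns) or
#'   `"joinmap_loc"` (an F2 `.loc` file with lowercase codes).
#' @export
write_abh <- function(abh, path, dialect = c("tsv", "joinmap_loc")) {
  dialect <- match.arg(dialect)
  bad <- which(!(abh %in% ABH_CODES))
  if (length(bad)) {
    at <- arrayInd(bad[1], dim(abh))
    stop_fmt("illegal ABH code '%s' at marker %s, individual %s",
             abh[at], rownames(abh)[at[1]] %||% at[1],
             colnames(abh)[at[2]] %||% at[2])
  }
  if (dialect == "tsv") {
    df <- data.frame(marker = rownames(abh), abh, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    lines <- c("name = polymap", "popt = F2",
               sprintf("nloc = %d", nrow(abh)),
               sprintf("nind = %d", ncol(abh)))
    if (nrow(abh))
      lines <- c(lines, paste(rownames(abh),
                              apply(abh, 1, function(z)
                                paste(tolower(z), collapse = " "))))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a TSV ABH matrix written by [write_abh()]
#' @param path Path to the ABH TSV.
#' @return Marker-by-individual character matrix.
#' @export
read_abh <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bad <- unique(m[!(m %in% ABH_CODES)])
  if (length(bad))
    stop_fmt("illegal ABH code(s): %s", paste(bad, collapse = ", "))
  m
}

#' Read a marker alignment-position table
#'
#' TSV with columns `marker`, `chrom`, `bp` (1-based). Markers with a
#' missing chromosome or position are kept and flagged unmapped rather
#' than dropped.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns marker, chrom, bp, mapped.
#' @export
read_position_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  for (column in c("marker", "chrom", "bp"))
    if (!column %in% names(df))
      stop_fmt("position table is missing column '%s'", column)
  if (anyDuplicated(df$marker))
    stop_fmt("duplicate marker rows in position table: %s",
             df$marker[anyDuplicated(df$marker)])
  bp_missing <- is.na(df$bp) | df$bp %in% c("", "NA")
  bp <- suppressWarnings(as.numeric(df$bp))
  bad <- is.na(bp) & !bp_missing
  if (any(bad))
    stop_fmt("non-numeric bp '%s' on line %d", df$bp[which(bad)[1]],
             which(bad)[1] + 1L)
  if (any(bp < 1, na.rm = TRUE))
    stop_fmt("bp positions must be >= 1")
  chrom_missing <- is.na(df$chrom) | df$chrom %in% c("", "NA")
  data.frame(marker = df$marker,
             chrom = ifelse(chrom_missing, NA, df$chrom),
             bp = bp,
             mapped = !(is.na(bp) | chrom_missing),
             stringsAsFactors = FALSE)
}

#' @rdname read_position_table
#' @param positions A position data.frame as returned by
#'   [read_position_table()].
#' @export
write_position_table <- function(positions, path) {
  utils::write.table(positions[c("marker", "chrom", "bp")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read/write a genetic map table (marker, linkage group, Kosambi cM)
#'
#' Map positions are serialized to 1 decimal place of a centimorgan.
#'
#' @param path Path to the map TSV.
#' @return data.frame with columns marker, group, cm.
#' @export
read_map <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  for (column in c("marker", "group", "cm"))
    if (!column %in% names(df))
      stop_fmt("map table is missing column '%s'", column)
  genetic_map(df$marker, df$group, df$cm)
}

#' @rdname read_map
#' @param map A genetic map data.frame (marker, group, cm).
#' @export
write_map <- function(map, path) {
  out <- data.frame(marker = map$marker, group = map$group,
                    cm = round(map$cm, 1))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct a genetic map container
#'
#' @param marker,group,cm Equal-length vectors: marker ids, linkage
#'   group labels and cumulative Kosambi positions (cM, non-decreasing
#'   within a group).
#' @return data.frame of class `genetic_map`, sorted by (group, cm).
#' @export
genetic_map <- function(marker, group, cm) {
  df <- data.frame(marker = as.character(marker),
                   group = as.character(group), cm = as.numeric(cm),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$marker)) stop_fmt("duplicate markers in map")
  df <- df[order(df$group, df$cm, df$marker), ]
  rownames(df) <- NULL
  class(df) <- c("genetic_map", "data.frame")
  df
}
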