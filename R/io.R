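# Plain-text readers/writers for the pipeline's on-disk formats.
# Intervals are written BED-style (0-based half-open).

write_tsv <- function(x, path, rownames_col = NULL) {
  if (!is.null(rownames_col)) {
    x <- cbind(stats::setNames(data.frame(rownames(x),
                                          stringsAsFactors = FALSE),
                               rownames_col),
               as.data.frame(x, check.names = FALSE))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a beta or intensity matrix as TSV
#'
#' Probes are rows, samples are columns; the first column holds probe
#' ids, and sample groups travel in a `# groups:` comment line.
#'
#' @param beta `beta_matrix`.
#' @param path output file.
#' @return the path (write) or a `beta_matrix` (read).
#' @export
write_beta_tsv <- function(beta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# groups: ",
                    paste(beta$groups, collapse = ",")), con)
  utils::write.table(
    cbind(data.frame(probe_id = rownames(beta$values),
                     stringsAsFactors = FALSE),
          as.data.frame(beta$values, check.names = FALSE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beta_tsv
#' @export
read_beta_tsv <- function(path) {
  first <- readLines(path, n = 1)
  groups <- NULL
  if (startsWith(first, "# groups:"))
    groups <- strsplit(trimws(sub("# groups:", "", first)), ",")[[1]]
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  if (is.null(groups)) groups <- rep("tumor", ncol(m))
  beta_matrix(m, groups)
}

#' Write intervals as a BED file (0-based half-open)
#'
#' @param intervals data.frame with chrom, start, end and optionally a
#'   name column.
#' @param path output file.
#' @param name_col column holding interval names (NULL for none).
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  bed <- intervals[, c("chrom", "start", "end")]
  if (!is.null(name_col)) bed$name <- intervals[[name_col]]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
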