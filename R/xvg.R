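# GROMACS xvg column files: '#' comment lines, '@' metadata (title, axis
# labels, 's<k> legend "..."'), then whitespace-separated numeric columns
# with time in the first column.

xvg_legend_map <- c(
  "Pressure" = "P", "Pres-XX" = "Pxx", "Pres-YY" = "Pyy", "Pres-ZZ" = "Pzz",
  "Pres-XY" = "Pxy", "Pres-XZ" = "Pxz", "Pres-YZ" = "Pyz",
  "Box-X" = "Lx", "Box-Y" = "Ly", "Box-Z" = "Lz")

#' Read a GROMACS xvg file
#'
#' Parses the plain-text xvg format written by GROMACS energy tools:
#' `#` comment lines, `@` metadata lines (title, axis labels, per-set
#' legends) and whitespace-separated numeric data columns, the first being
#' time.  Known legends are mapped to canonical component names
#' (`"Pressure"` to `P`, `"Pres-XX"` to `Pxx`, `"Box-X"` to `Lx`, ...);
#' files without legends get positional column names.
#'
#' @param path Path to the file.
#' @return A tibble with a `time` column and one column per data set;
#'   attributes `title` and `legends` carry the metadata.
#' @export
read_xvg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("empty xvg file: %s", path))
  is_comment <- grepl("^\\s*#", lines)
  is_meta <- grepl("^\\s*@", lines)
  title <- NA_character_
  legends <- character()
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("@\\s*title\\s+\"([^\"]*)\"", ln))[[1]]
    if (length(m) == 2) title <- m[2]
    m <- regmatches(ln, regexec("@\\s*s(\\d+)\\s+legend\\s+\"([^\"]*)\"", ln))[[1]]
    if (length(m) == 3) legends[as.integer(m[2]) + 1L] <- m[3]
  }
  data_idx <- which(!is_comment & !is_meta & nzchar(trimws(lines)))
  if (length(data_idx) == 0) abort(sprintf("no data rows in xvg file: %s", path))
  rows <- strsplit(trimws(lines[data_idx]), "\\s+")
  ncols <- length(rows[[1]])
  vals <- suppressWarnings(lapply(rows, as.numeric))
  for (i in seq_along(vals)) {
    if (length(vals[[i]]) != ncols || anyNA(vals[[i]])) {
      abort(sprintf("non-numeric or ragged data at line %d of %s",
                    data_idx[i], path))
    }
  }
  m <- do.call(rbind, vals)
  nms <- c("time", paste0("V", seq_len(ncols - 1L)))
  if (length(legends)) {
    for (k in seq_along(legends)) {
      if (!is.na(legends[k]) && k + 1L <= ncols) {
        mapped <- xvg_legend_map[legends[k]]
        nms[k + 1L] <- if (!is.na(mapped)) mapped else make.names(legends[k])
      }
    }
  }
  colnames(m) <- nms
  out <- as_tibble(m)
  attr(out, "title") <- title
  attr(out, "legends") <- legends
  out
}

#' Write a GROMACS-style xvg file
#'
#' @param data Data frame whose first column is time; remaining columns
#'   become data sets with their names as legends (canonical names are
#'   mapped back to GROMACS legends).
#' @param path Output path.
#' @param title Plot title metadata.
#' @param xlabel,ylabel Axis label metadata.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(data, path, title = "verletdiag output",
                      xlabel = "Time (ps)", ylabel = "") {
  data <- as.data.frame(data)
  if (ncol(data) < 2) abort("need a time column and at least one data column")
  rev_map <- stats::setNames(names(xvg_legend_map), xvg_legend_map)
  legends <- names(data)[-1]
  legends <- ifelse(legends %in% names(rev_map), rev_map[legends], legends)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# written by verletdiag"),
               sprintf("@    title \"%s\"", title),
               sprintf("@    xaxis  label \"%s\"", xlabel),
               sprintf("@    yaxis  label \"%s\"", ylabel)), con)
  writeLines(sprintf("@ s%d legend \"%s\"", seq_along(legends) - 1L, legends),
             con)
  body <- apply(data, 1, function(r) paste(formatC(r, format = "g", digits = 15),
                                           collapse = "  "))
  writeLines(body, con)
  invisible(path)
}
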