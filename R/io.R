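#' Read a delimited numeric table (CSV/TSV/XVG)
#'
#' Shared reader for the tabular inputs of the pipeline: comma- or
#' tab/whitespace-separated tables and GROMACS-style XVG files. Lines
#' starting with `#` or `@` are preserved as metadata (XVG `@` directives
#' included), a leading non-numeric row is taken as the header, and the data
#' must form a complete numeric rectangle: ragged rows and NaN cells are
#' reported with their position rather than silently dropped. Decimal points
#' only (no locale commas).
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"csv"`, `"tsv"` or `"xvg"`.
#' @return A tibble of numeric columns with attributes `comments` (metadata
#'   lines) and `header` (original column names, if any).
#' @export
read_table <- function(path, dialect = c("auto", "csv", "tsv", "xvg")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_domain(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, csv = "csv", xvg = "xvg", "tsv")
  }

  is_comment <- grepl("^\\s*[#@]", lines)
  comments <- lines[is_comment]
  data_lines <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(data_lines) == 0) {
    stop_domain(sprintf("No data rows in %s", path))
  }
  line_no <- which(!is_comment & nzchar(trimws(lines)))

  split_row <- function(s) {
    if (dialect == "csv") {
      trimws(strsplit(s, ",", fixed = TRUE)[[1]])
    } else {
      strsplit(trimws(s), "\\s+|\t")[[1]]
    }
  }
  rows <- lapply(data_lines, split_row)

  header <- NULL
  first <- suppressWarnings(as.numeric(rows[[1]]))
  if (anyNA(first)) {
    header <- rows[[1]]
    rows <- rows[-1]
    line_no <- line_no[-1]
    if (length(rows) == 0) {
      out <- as_tibble(setNames(rep(list(numeric(0)), length(header)), header))
      attr(out, "comments") <- comments
      attr(out, "header") <- header
      return(out)
    }
  }

  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    stop_domain(sprintf(
      "Ragged table in %s: line %d has %d fields, expected %d.",
      path, line_no[bad], ncols[bad], ncols[1]
    ))
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
  )
  nan_like <- is.na(mat) | is.nan(mat)
  if (any(nan_like)) {
    idx <- which(nan_like, arr.ind = TRUE)[1, ]
    stop_domain(sprintf(
      "Non-numeric or NaN cell in %s at data row %d (line %d), column %d.",
      path, idx[1], line_no[idx[1]], idx[2]
    ))
  }
  cols <- header %||% paste0("V", seq_len(ncol(mat)))
  out <- as_tibble(setNames(as.data.frame(mat), cols))
  attr(out, "comments") <- comments
  attr(out, "header") <- header
  out
}

#' Read a pressure–distance curve file
#'
#' Two-column delimited text or GROMACS-style XVG: first column separation
#' (nm), second interaction pressure (bar).
#'
#' @inheritParams read_table
#' @param D_contact Optional contact separation, nm.
#' @return A [pd_curve()].
#' @export
read_pd_curve <- function(path, dialect = "auto", D_contact = NULL) {
  tbl <- read_table(path, dialect)
  if (ncol(tbl) < 2) stop_domain("Pressure-distance file needs two columns (D, P).")
  pd_curve(tbl[[1]], tbl[[2]], D_contact = D_contact)
}

#' Write / read a droplet density grid as plain text
#'
#' The grid format is a plain-text matrix (rows = `z` ascending from the
#' substrate, columns = `y`) preceded by `#` header lines carrying the bin
#' widths and metadata: `dy=`, `dz=`, `z0=`, `rho_bulk=` and optionally
#' `y0=`, all in the units of [density_field()].
#'
#' @param field A [density_field()].
#' @param path Output / input file path.
#' @return `write_density_grid()` returns `path` invisibly;
#'   `read_density_grid()` returns a [density_field()].
#' @export
write_density_grid <- function(field, path) {
  stopifnot(inherits(field, "density_field"))
  hdr <- sprintf("# dy=%.10g dz=%.10g z0=%.10g rho_bulk=%.10g y0=%.10g",
                 field$dy, field$dz, field$z0, field$rho_bulk, field$y0)
  body <- apply(field$grid, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_density_grid
#' @export
read_density_grid <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[grepl("^\\s*#", lines)]
  meta <- list()
  for (key in c("dy", "dz", "z0", "rho_bulk", "y0")) {
    m <- regmatches(hdr, regexpr(sprintf("%s=\\S+", key), hdr))
    m <- unlist(m)
    if (length(m)) meta[[key]] <- as.numeric(sub(".*=", "", m[1]))
  }
  for (key in c("dy", "dz", "rho_bulk")) {
    if (is.null(meta[[key]])) {
      stop_domain(sprintf("Density grid header is missing `%s=` in %s", key, path))
    }
  }
  data_lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  rows <- lapply(data_lines, function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  if (length(unique(lengths(rows))) != 1) {
    stop_domain(sprintf("Ragged density grid in %s", path))
  }
  grid <- do.call(rbind, rows)
  density_field(grid, dy = meta$dy, dz = meta$dz,
                z0 = meta$z0 %||% 0, rho_bulk = meta$rho_bulk,
                y0 = meta$y0 %||% (meta$dy / 2))
}

#' Write an analysis result to CSV or JSON
#'
#' Writes any tabular result (free-energy breakdowns, per-composition
#' profiles, angle estimates, ...) with full double precision so that a
#' write/read round trip reproduces every value to within 1e-12 relative.
#' Empty results produce a header-only file.
#'
#' @param results A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(results)) stop_domain("`results` must be a data frame.")
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(results, path)
    } else {
      jsonlite::write_json(results, path, dataframe = "columns",
                           digits = NA, auto_unbox = TRUE, pretty = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_domain(sprintf("Could not write report to %s: %s", path,
                        conditionMessage(ok)))
  }
  invisible(path)
}
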