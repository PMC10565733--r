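# Chunk file formats.
#
# Tabular dialect: UTF-8 TSV with '#' comment lines and a header row
#   h k l intensity sigma [frame]
#
# XDS-ASCII dialect (minimal): '!'-prefixed header lines, of which
#   !UNIT_CELL_CONSTANTS= a b c alpha beta gamma
#   !SPACE_GROUP_NUMBER= n
#   !END_OF_DATA
# are recognised; data records are whitespace-separated "h k l I sigma"
# rows (trailing columns ignored).

#' Read one reflection chunk from a file
#'
#' @param path Path to a chunk file.
#' @param dialect `"tabular"` for the TSV format, `"xds_ascii"` for the
#'   minimal XDS-ASCII dialect, or `"auto"` (default) to detect from the
#'   first non-blank line (`!` starts an XDS-ASCII header).
#' @param chunk_id Identifier; defaults to the file name without extension.
#' @param cell Unit cell attached to the chunk; for `xds_ascii` the cell is
#'   read from the header and this argument must be `NULL`.
#' @param ... Further arguments passed to [reflection_chunk()]
#'   (`crystal_id`, `rotation_start_deg`, `label`, `ops`, ...).
#' @return A [reflection_chunk()]. Duplicate (h,k,l) rows are merged by
#'   sigma-weighted mean intensity.
#' @seealso [write_chunk_table()], [write_xds_ascii()]
#' @export
read_chunk_table <- function(path, dialect = c("auto", "tabular", "xds_ascii"),
                             chunk_id = NULL, cell = NULL, ...) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_data(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  if (is.null(chunk_id)) chunk_id <- sub("\\.[^.]*$", "", basename(path))
  if (dialect == "auto") {
    first <- lines[nzchar(trimws(lines))][1]
    dialect <- if (!is.na(first) && startsWith(trimws(first), "!")) "xds_ascii" else "tabular"
  }
  if (dialect == "tabular") {
    parse_tabular_chunk(lines, path, chunk_id = chunk_id, cell = cell, ...)
  } else {
    if (!is.null(cell)) abort_config("for xds_ascii the cell is read from the header")
    parse_xds_chunk(lines, path, chunk_id = chunk_id, ...)
  }
}

parse_tabular_chunk <- function(lines, path, chunk_id, cell, ...) {
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  body <- lines[keep]
  if (length(body) < 2) abort_data(paste0(path, ": no data rows"))
  header <- strsplit(trimws(body[1]), "[ \t]+")[[1]]
  required <- c("h", "k", "l", "intensity", "sigma")
  if (!all(required %in% header)) {
    abort_data(paste0(path, ": header must contain columns ",
                      paste(required, collapse = ", ")))
  }
  fields <- strsplit(trimws(body[-1]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1]
    abort_data(sprintf("%s: malformed row at line %d (%d fields, expected %d)",
                       path, lineno[-1][bad], nf[bad], length(header)))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = length(header), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    abort_data(sprintf("%s: non-numeric value at line %d", path, lineno[-1][bad]))
  }
  colnames(m) <- header
  records <- as_tibble(m)[, intersect(c(required, "frame"), header)]
  reflection_chunk(records, chunk_id = chunk_id, cell = cell, ...)
}

parse_xds_chunk <- function(lines, path, chunk_id, ...) {
  trimmed <- trimws(lines)
  is_header <- startsWith(trimmed, "!")
  cell_line <- grep("^!UNIT_CELL_CONSTANTS=", trimmed, value = TRUE)
  if (length(cell_line) == 0) {
    abort_data(paste0(path, ": missing !UNIT_CELL_CONSTANTS= header"))
  }
  cell_vals <- as.numeric(strsplit(trimws(sub("^!UNIT_CELL_CONSTANTS=", "",
                                              cell_line[1])), "[ \t]+")[[1]])
  if (length(cell_vals) != 6 || anyNA(cell_vals)) {
    abort_data(paste0(path, ": malformed !UNIT_CELL_CONSTANTS= header"))
  }
  cell <- unit_cell(cell_vals[1], cell_vals[2], cell_vals[3],
                    cell_vals[4], cell_vals[5], cell_vals[6])
  sg_line <- grep("^!SPACE_GROUP_NUMBER=", trimmed, value = TRUE)
  sg <- if (length(sg_line) > 0) {
    as.integer(trimws(sub("^!SPACE_GROUP_NUMBER=", "", sg_line[1])))
  } else {
    NA_integer_
  }
  end <- match("!END_OF_DATA", trimmed)
  data_idx <- which(!is_header & nzchar(trimmed))
  if (!is.na(end)) data_idx <- data_idx[data_idx < end]
  if (length(data_idx) == 0) abort_data(paste0(path, ": no data records"))
  fields <- strsplit(trimmed[data_idx], "[ \t]+")
  if (any(lengths(fields) < 5)) {
    bad <- which(lengths(fields) < 5)[1]
    abort_data(sprintf("%s: malformed record at line %d", path, data_idx[bad]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(
    lapply(fields, `[`, 1:5)
  ))), ncol = 5, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(m, 1, anyNA))[1]
    abort_data(sprintf("%s: non-numeric value at line %d", path, data_idx[bad]))
  }
  colnames(m) <- c("h", "k", "l", "intensity", "sigma")
  ch <- reflection_chunk(as_tibble(m), chunk_id = chunk_id, cell = cell, ...)
  ch$space_group_number <- sg
  ch
}

#' Write a chunk in the tabular TSV format
#'
#' @param chunk A [reflection_chunk()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_chunk_table <- function(chunk, path) {
  rec <- chunk$records
  has_frame <- "frame" %in% names(rec)
  cols <- c("h", "k", "l", "intensity", "sigma", if (has_frame) "frame")
  body <- if (has_frame) {
    sprintf("%d\t%d\t%d\t%.9g\t%.9g\t%d",
            as.integer(rec$h), as.integer(rec$k), as.integer(rec$l),
            rec$intensity, rec$sigma, as.integer(rec$frame))
  } else {
    sprintf("%d\t%d\t%d\t%.9g\t%.9g",
            as.integer(rec$h), as.integer(rec$k), as.integer(rec$l),
            rec$intensity, rec$sigma)
  }
  writeLines(c(
    sprintf("# chunk_id=%s crystal_id=%s rotation=%.6g:%.6g",
            chunk$chunk_id, chunk$crystal_id,
            chunk$rotation_start_deg, chunk$rotation_end_deg),
    paste(cols, collapse = "\t"),
    body
  ), path)
  invisible(path)
}

#' Write a chunk in the minimal XDS-ASCII dialect
#'
#' The writer emits a fixed header (unit cell, space-group number) followed by
#' "h k l I sigma" records and `!END_OF_DATA`; [read_chunk_table()] parses
#' its own output back bit-identically.
#'
#' @param chunk A [reflection_chunk()] carrying a unit cell.
#' @param path Output file.
#' @param space_group_number Space-group number written to the header.
#' @return `path`, invisibly.
#' @export
write_xds_ascii <- function(chunk, path, space_group_number = NULL) {
  if (is.null(chunk$cell)) {
    abort_config("write_xds_ascii requires a chunk with a unit cell")
  }
  sg <- space_group_number %||% chunk$space_group_number %||% 1L
  rec <- chunk$records
  writeLines(c(
    "!FORMAT=XDS_ASCII    MERGE=FALSE    FRIEDEL'S_LAW=TRUE",
    sprintf("!SPACE_GROUP_NUMBER= %d", as.integer(sg)),
    sprintf("!UNIT_CELL_CONSTANTS= %.6f %.6f %.6f %.6f %.6f %.6f",
            chunk$cell$a, chunk$cell$b, chunk$cell$c,
            chunk$cell$alpha, chunk$cell$beta, chunk$cell$gamma),
    "!END_OF_HEADER",
    sprintf("%6d %6d %6d %15.7e %15.7e",
            rec$h, rec$k, rec$l, rec$intensity, rec$sigma),
    "!END_OF_DATA"
  ), path)
  invisible(path)
}
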