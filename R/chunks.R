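#' Create a reflection chunk
#'
#' A chunk is one angular slice of a rotation data set, held as a tibble of
#' unique reflections. Duplicate (h,k,l) rows in `records` (and, when `ops`
#' carries more than the identity, symmetry-equivalent rows) are merged by
#' the inverse-variance (sigma-weighted) mean of their intensities.
#'
#' @param records Data frame with integer columns `h`, `k`, `l`, numeric
#'   `intensity` (may be negative, as in integrated data) and `sigma`
#'   (>= 0), optionally `frame` (>= 1).
#' @param chunk_id,crystal_id Identifiers; `crystal_id` defaults to
#'   `chunk_id`.
#' @param cell The [unit_cell()] of the crystal.
#' @param rotation_start_deg,rotation_end_deg Rotation range covered by the
#'   chunk; the end must exceed the start.
#' @param label Optional ground-truth group label (used by synthetic data
#'   and scoring).
#' @param ops Point-group operators used to reduce indices before merging;
#'   defaults to identity (inputs assumed pre-reduced).
#' @return An object of class `reflection_chunk`: a list with the merged
#'   `records` tibble and the metadata above.
#' @export
reflection_chunk <- function(records, chunk_id, crystal_id = chunk_id,
                             cell = NULL,
                             rotation_start_deg = 0, rotation_end_deg = 30,
                             label = NULL, ops = point_group_ops("1")) {
  records <- as_tibble(records)
  needed <- c("h", "k", "l", "intensity", "sigma")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort_data(paste0("chunk records lack columns: ",
                      paste(missing_cols, collapse = ", ")))
  }
  if (nrow(records) == 0) abort_data("chunk has no reflections")
  if (any(records$sigma < 0)) abort_data("sigma must be non-negative")
  if (any(records$h == 0 & records$k == 0 & records$l == 0)) {
    abort_data("(0,0,0) is not a valid reflection index")
  }
  if ("frame" %in% names(records) && any(records$frame < 1)) {
    abort_data("frame numbers must be >= 1")
  }
  if (!(rotation_end_deg > rotation_start_deg)) {
    abort_config("rotation_end_deg must exceed rotation_start_deg")
  }
  if (!is.null(cell) && !is_unit_cell(cell)) {
    abort_config("`cell` must be a unit_cell or NULL")
  }

  records <- merge_equivalents(records, ops)

  structure(
    list(
      chunk_id = as.character(chunk_id),
      crystal_id = as.character(crystal_id),
      records = records,
      cell = cell,
      rotation_start_deg = rotation_start_deg,
      rotation_end_deg = rotation_end_deg,
      label = label
    ),
    class = "reflection_chunk"
  )
}

#' @export
print.reflection_chunk <- function(x, ...) {
  cat(sprintf("<reflection_chunk> %s (%s): %d unique reflections, %.6g-%.6g deg%s\n",
              x$chunk_id, x$crystal_id, nrow(x$records),
              x$rotation_start_deg, x$rotation_end_deg,
              if (is.null(x$label)) "" else paste0(", label=", x$label)))
  invisible(x)
}

# Reduce indices to the asymmetric unit and merge duplicate observations by
# sigma-weighted mean. Frame numbers are dropped on merge (a merged record no
# longer belongs to a single frame).
merge_equivalents <- function(records, ops = point_group_ops("1")) {
  asu <- map_to_asu(as.matrix(records[, c("h", "k", "l")]), ops)
  records$h <- asu[, "h"]
  records$k <- asu[, "k"]
  records$l <- asu[, "l"]
  keep_cols <- intersect(c("h", "k", "l", "intensity", "sigma", "frame"),
                         names(records))
  if (!anyDuplicated(records[, c("h", "k", "l")])) {
    return(as_tibble(records[, keep_cols]))
  }
  grp <- paste(records$h, records$k, records$l)
  split_idx <- split(seq_len(nrow(records)), grp)
  merged <- purrr::map(split_idx, function(ii) {
    wm <- weighted_merge(records$intensity[ii], records$sigma[ii])
    tibble(h = records$h[ii[1]], k = records$k[ii[1]], l = records$l[ii[1]],
           intensity = wm[["intensity"]], sigma = wm[["sigma"]])
  })
  out <- dplyr::bind_rows(merged)
  dplyr::arrange(out, .data$h, .data$k, .data$l)
}

#' Bundle chunks into a collection
#'
#' @param chunks List of [reflection_chunk()] objects with unique
#'   `chunk_id`s.
#' @param provenance Optional tibble recording where each chunk came from
#'   (source file, discarded-partial-chunk flags, ...).
#' @return An object of class `chunk_collection`.
#' @export
chunk_collection <- function(chunks, provenance = NULL) {
  ids <- vapply(chunks, function(ch) ch$chunk_id, character(1))
  if (anyDuplicated(ids)) abort_data("chunk_ids must be unique in a collection")
  structure(
    list(chunks = chunks, provenance = provenance),
    class = "chunk_collection"
  )
}

#' @export
print.chunk_collection <- function(x, ...) {
  cat(sprintf("<chunk_collection> %d chunks\n", length(x$chunks)))
  invisible(x)
}

#' @export
length.chunk_collection <- function(x) length(x$chunks)

chunk_ids <- function(collection) {
  vapply(collection$chunks, function(ch) ch$chunk_id, character(1))
}

#' Split a frame-tagged reflection stream into angular chunks
#'
#' Frames are mapped to rotation angle via `frame_width_deg` (frame f covers
#' `[(f-1), f) * frame_width_deg`) and grouped into consecutive chunks of
#' `chunk_deg`. Within each chunk, equivalent observations are merged by
#' sigma-weighted mean. A trailing partial chunk shorter than half the chunk
#' width is discarded and flagged in the collection's provenance.
#'
#' @param records Data frame with columns `h`, `k`, `l`, `intensity`,
#'   `sigma`, `frame` (every record must carry a frame number).
#' @param frame_width_deg Oscillation width of one frame in degrees.
#' @param chunk_deg Chunk width in degrees; must be a positive multiple of
#'   `frame_width_deg`.
#' @param cell Optional [unit_cell()] attached to every chunk.
#' @param crystal_id Identifier used to derive chunk ids
#'   (`<crystal_id>_chunk<i>`).
#' @param label Optional ground-truth label attached to every chunk.
#' @param ops Point-group operators for within-chunk merging.
#' @return A [chunk_collection()].
#' @examples
#' rec <- tibble::tibble(h = 1, k = 2, l = 3, intensity = 10, sigma = 1,
#'                       frame = 1:300)
#' length(split_into_chunks(rec, 0.1, 30))  # 300 frames x 0.1 deg -> 1 chunk
#' @export
split_into_chunks <- function(records, frame_width_deg, chunk_deg = 30,
                              cell = NULL, crystal_id = "xtal", label = NULL,
                              ops = point_group_ops("1")) {
  records <- as_tibble(records)
  if (!"frame" %in% names(records) || anyNA(records$frame)) {
    abort_data("split_into_chunks requires a frame number on every record")
  }
  if (!is_scalar_number(frame_width_deg) || frame_width_deg <= 0) {
    abort_config("frame_width_deg must be a positive number")
  }
  frames_per_chunk <- chunk_deg / frame_width_deg
  if (!is_scalar_number(chunk_deg) || chunk_deg <= 0 ||
      abs(frames_per_chunk - round(frames_per_chunk)) > 1e-9) {
    abort_config("chunk_deg must be a positive multiple of frame_width_deg")
  }
  frames_per_chunk <- round(frames_per_chunk)

  idx <- (records$frame - 1) %/% frames_per_chunk
  n_frames_total <- max(records$frame)
  n_full <- n_frames_total %/% frames_per_chunk
  trailing_frames <- n_frames_total - n_full * frames_per_chunk

  keep_trailing <- trailing_frames >= frames_per_chunk / 2 && trailing_frames > 0
  discarded <- NULL
  if (trailing_frames > 0 && !keep_trailing) {
    drop <- idx == n_full
    discarded <- tibble(
      chunk_id = sprintf("%s_chunk%02d", crystal_id, n_full + 1),
      reason = sprintf("trailing partial chunk (%.6g deg < %.6g deg) discarded",
                       trailing_frames * frame_width_deg, chunk_deg / 2),
      n_records = sum(drop)
    )
    records <- records[!drop, , drop = FALSE]
    idx <- idx[!drop]
  }

  chunks <- purrr::map(sort(unique(idx)), function(i) {
    sel <- idx == i
    reflection_chunk(
      records[sel, , drop = FALSE],
      chunk_id = sprintf("%s_chunk%02d", crystal_id, i + 1),
      crystal_id = crystal_id,
      cell = cell,
      rotation_start_deg = i * chunk_deg,
      rotation_end_deg = i * chunk_deg +
        if (keep_trailing && i == n_full) trailing_frames * frame_width_deg else chunk_deg,
      label = label,
      ops = ops
    )
  })
  chunk_collection(chunks, provenance = discarded)
}
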