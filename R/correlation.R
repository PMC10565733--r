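#' Transform a correlation coefficient into a clustering distance
#'
#' Three transforms are in common use for intensity-correlation clustering:
#' `1 - CC`, `sqrt(1 - CC)` and `sqrt(1 - CC^2)`. The last, written d_CC,
#' is the package default throughout: it maps `[-1, 1]` onto `[0, 1]` and is
#' strictly decreasing in `|CC|`.
#'
#' @param cc Numeric vector of correlation coefficients in `[-1, 1]`.
#' @param metric One of `"sqrt_one_minus_cc2"` (default, d_CC),
#'   `"one_minus_cc"`, `"sqrt_one_minus_cc"`.
#' @return Numeric vector of distances.
#' @examples
#' cc_to_distance(0.97)   # 0.2431...
#' cc_to_distance(1)      # 0
#' @export
cc_to_distance <- function(cc, metric = c("sqrt_one_minus_cc2", "one_minus_cc",
                                          "sqrt_one_minus_cc")) {
  metric <- match.arg(metric)
  if (any(abs(cc) > 1 + 1e-12, na.rm = TRUE)) {
    abort_config("correlation coefficients must lie in [-1, 1]")
  }
  cc <- pmin(pmax(cc, -1), 1)
  switch(metric,
    one_minus_cc = 1 - cc,
    sqrt_one_minus_cc = sqrt(1 - cc),
    sqrt_one_minus_cc2 = sqrt(1 - cc^2)
  )
}

#' Pearson correlation of common reflections between two chunks
#'
#' Intersects the canonical (h,k,l) keys of the two chunks, after filtering
#' each chunk's reflections to `d >= d_min` using that chunk's own unit cell,
#' and computes the Pearson correlation of the paired raw intensities. The
#' pair is only `valid` when at least `min_common` reflections are shared and
#' neither paired intensity vector is constant.
#'
#' @param x,y [reflection_chunk()] objects.
#' @param d_min Resolution cutoff in angstrom (0 disables the cutoff or when
#'   a chunk carries no cell).
#' @param min_common Minimum number of common reflections for a valid CC
#'   (default 3).
#' @param ops Point-group operators used to canonicalise indices before
#'   intersecting.
#' @return One-row tibble with columns `cc`, `n_common`, `valid`, `reason`
#'   (`NA`, `"too_few_common"` or `"degenerate"`).
#' @export
pearson_cc <- function(x, y, d_min = 0, min_common = 3,
                       ops = point_group_ops("1")) {
  if (min_common < 2) abort_config("min_common must be at least 2")
  a <- filtered_keyed_records(x, d_min, ops)
  b <- filtered_keyed_records(y, d_min, ops)
  m <- dplyr::inner_join(a, b, by = "key", suffix = c("_x", "_y"))
  n <- nrow(m)
  if (n < min_common) {
    return(tibble(cc = NA_real_, n_common = n, valid = FALSE,
                  reason = "too_few_common"))
  }
  if (sd(m$intensity_x) == 0 || sd(m$intensity_y) == 0) {
    return(tibble(cc = NA_real_, n_common = n, valid = FALSE,
                  reason = "degenerate"))
  }
  tibble(cc = cor(m$intensity_x, m$intensity_y), n_common = n,
         valid = TRUE, reason = NA_character_)
}

filtered_keyed_records <- function(chunk, d_min, ops) {
  rec <- chunk$records
  asu <- map_to_asu(as.matrix(rec[, c("h", "k", "l")]), ops)
  rec <- tibble(key = paste(asu[, 1], asu[, 2], asu[, 3]),
                intensity = rec$intensity)
  if (d_min > 0 && !is.null(chunk$cell)) {
    d <- d_spacing(chunk$cell, asu[, 1], asu[, 2], asu[, 3])
    rec <- rec[d >= d_min, , drop = FALSE]
  }
  rec
}

#' Pairwise intensity-correlation distance matrix over a chunk collection
#'
#' Computes the full matrix of pairwise CCs over common reflections (see
#' [pearson_cc()]) and transforms it with [cc_to_distance()]. Chunk pairs
#' sharing fewer than `min_common` reflections (or with constant paired
#' intensities) are invalid; while any invalid pair remains, the chunk
#' involved in the most invalid pairs is dropped (ties broken towards the
#' lexicographically smallest `chunk_id`) and recorded in `excluded`, so the
#' returned matrix is complete over the survivors.
#'
#' @param chunks A [chunk_collection()] or list of chunks (>= 3).
#' @param d_min Resolution cutoff in angstrom applied per chunk with its own
#'   cell (0 disables).
#' @param min_common Minimum common reflections for a valid pair (default 3).
#' @param metric Distance transform, see [cc_to_distance()].
#' @param ops Point-group operators for index canonicalisation.
#' @return An object of class `iso_dist`: list with `labels`, `values`
#'   (symmetric distance matrix, zero diagonal), `cc` and `n_common`
#'   matrices over the retained chunks, `excluded`
#'   (tibble `chunk_id`, `reason`) and `metric`.
#' @export
build_distance_matrix <- function(chunks, d_min = 0, min_common = 3,
                                  metric = "sqrt_one_minus_cc2",
                                  ops = point_group_ops("1")) {
  if (inherits(chunks, "chunk_collection")) chunks <- chunks$chunks
  if (length(chunks) < 3) abort_data("need at least 3 chunks")
  ids <- vapply(chunks, function(ch) ch$chunk_id, character(1))
  if (anyDuplicated(ids)) abort_data("chunk_ids must be unique")

  keyed <- purrr::map(chunks, filtered_keyed_records, d_min = d_min, ops = ops)
  all_keys <- unique(unlist(purrr::map(keyed, "key")))
  M <- matrix(NA_real_, nrow = length(all_keys), ncol = length(chunks),
              dimnames = list(NULL, ids))
  for (j in seq_along(keyed)) {
    M[match(keyed[[j]]$key, all_keys), j] <- keyed[[j]]$intensity
  }

  suppressWarnings(C <- cor(M, use = "pairwise.complete.obs"))
  obs <- !is.na(M)
  N <- crossprod(obs)
  diag(C) <- 1

  invalid <- (N < min_common) | !is.finite(C)
  diag(invalid) <- FALSE

  excluded <- tibble(chunk_id = character(), reason = character())
  keep <- rep(TRUE, length(ids))
  while (any(invalid[keep, keep])) {
    n_bad <- rowSums(invalid[keep, keep, drop = FALSE])
    worst <- which(n_bad == max(n_bad))
    # ties -> lexicographically smallest chunk_id
    drop_id <- sort(ids[keep][worst])[1]
    excluded <- dplyr::bind_rows(excluded, tibble(
      chunk_id = drop_id,
      reason = sprintf("invalid CC with %d retained chunks (< %d common reflections or degenerate)",
                       n_bad[match(drop_id, ids[keep])], min_common)
    ))
    keep[match(drop_id, ids)] <- FALSE
  }
  if (sum(keep) < 3) {
    abort_data("insufficient mutually comparable chunks (fewer than 3 survive)")
  }

  C <- C[keep, keep, drop = FALSE]
  N <- N[keep, keep, drop = FALSE]
  D <- cc_to_distance(C, metric)
  diag(D) <- 0
  new_iso_dist(labels = ids[keep], values = D, metric = metric,
               cc = C, n_common = N, excluded = excluded)
}

new_iso_dist <- function(labels, values, metric, cc = NULL, n_common = NULL,
                         excluded = tibble(chunk_id = character(),
                                           reason = character())) {
  dimnames(values) <- list(labels, labels)
  structure(
    list(labels = labels, values = values, cc = cc, n_common = n_common,
         excluded = excluded, metric = metric),
    class = "iso_dist"
  )
}

#' @export
print.iso_dist <- function(x, ...) {
  cat(sprintf("<iso_dist> %d x %d (%s), %d excluded\n",
              length(x$labels), length(x$labels), x$metric, nrow(x$excluded)))
  invisible(x)
}

#' @export
as.dist.iso_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$values, diag = diag, upper = upper)
}

#' Export a distance matrix as TSV
#'
#' Writes the square matrix with a chunk-id header row and column, and the
#' exclusion record as a sidecar `<path>.excluded.tsv` when any chunk was
#' dropped.
#'
#' @param dist An `iso_dist` from [build_distance_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dist, path) {
  df <- as.data.frame(dist$values)
  utils::write.table(cbind(chunk_id = dist$labels, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(dist$excluded) > 0) {
    utils::write.table(dist$excluded, paste0(path, ".excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
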