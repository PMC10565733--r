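#' Point-group rotation operators for index reduction
#'
#' Returns the list of 3x3 rotation matrices of a point group, used by
#' [map_to_asu()] to bring Miller indices to a canonical representative.
#' Inputs produced by standard integration pipelines are already reduced to
#' the asymmetric unit, so the default group used throughout the package is
#' the identity (`"1"`). Operator sets are provided for point groups 2
#' (b-unique monoclinic) and 222 (orthorhombic), the symmetries of the C2 and
#' P2(1)2(1)2(1) samples this method is typically applied to.
#'
#' @param group One of `"1"`, `"2"`, `"222"`.
#' @return A list of 3x3 integer matrices forming a group (identity first).
#' @examples
#' length(point_group_ops("222"))  # 4 rotations
#' @export
point_group_ops <- function(group = c("1", "2", "222")) {
  group <- match.arg(group)
  id <- diag(3)
  switch(group,
    "1" = list(id),
    "2" = list(id, diag(c(-1, 1, -1))),
    "222" = list(id, diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  )
}

#' Map Miller indices to a canonical asymmetric-unit representative
#'
#' Applies every rotation in `ops` plus the Friedel inversion (-h,-k,-l) to
#' each index triple and returns the lexicographically greatest image
#' (compared on h, then k, then l). The result is a deterministic canonical
#' key: all symmetry-equivalent observations of a reflection map to the same
#' triple, so intensity comparisons between data sets pair equivalent
#' reflections.
#'
#' @param hkl Integer matrix or data frame with columns h, k, l (one row per
#'   reflection), or a length-3 vector for a single reflection.
#' @param ops List of 3x3 rotation matrices containing the identity, as
#'   returned by [point_group_ops()].
#' @return An integer matrix with columns h, k, l of canonical indices.
#' @examples
#' map_to_asu(c(-1, 2, 3), point_group_ops("222"))
#' @export
map_to_asu <- function(hkl, ops = point_group_ops("1")) {
  if (!is.list(ops) || length(ops) == 0) {
    abort_config("`ops` must be a non-empty list of 3x3 rotation matrices")
  }
  if (is.null(dim(hkl))) hkl <- matrix(hkl, nrow = 1)
  H <- as.matrix(hkl[, 1:3, drop = FALSE])
  storage.mode(H) <- "double"
  best <- NULL
  for (op in ops) {
    for (sgn in c(1, -1)) {
      img <- sgn * (H %*% t(op))
      if (is.null(best)) {
        best <- img
      } else {
        # lexicographic "img > best" on (h, k, l)
        gt <- img[, 1] > best[, 1] |
          (img[, 1] == best[, 1] & img[, 2] > best[, 2]) |
          (img[, 1] == best[, 1] & img[, 2] == best[, 2] & img[, 3] > best[, 3])
        best[gt, ] <- img[gt, , drop = FALSE]
      }
    }
  }
  best <- round(best)
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}
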