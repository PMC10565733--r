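# Unit-cell-based clustering companion: Tukey pre-filtering of cell
# constants, face-diagonal cell distances, and linear cell variation (LCV)
# reporting. Cells travel as a tidy table: one row per chunk with columns
# chunk_id, a, b, c, alpha, beta, gamma.

cell_cols <- c("a", "b", "c", "alpha", "beta", "gamma")

check_cell_table <- function(cells) {
  cells <- as_tibble(cells)
  missing_cols <- setdiff(c("chunk_id", cell_cols), names(cells))
  if (length(missing_cols) > 0) {
    abort_data(paste0("cell table lacks columns: ",
                      paste(missing_cols, collapse = ", ")))
  }
  # constructor validates each row's geometry
  purrr::pwalk(cells[cell_cols], unit_cell)
  cells
}

#' Tukey interquartile-range filter on unit-cell constants
#'
#' For each of the six cell parameters independently, records falling outside
#' `[Q1 - k*IQR, Q3 + k*IQR]` on any parameter are rejected. This is the
#' standard pre-clustering filter that removes chunks whose lattice deviates
#' grossly before intensity comparison.
#'
#' @param cells Tidy cell table (`chunk_id`, `a`, `b`, `c`, `alpha`, `beta`,
#'   `gamma`).
#' @param k IQR multiplier (default 1.5, Tukey's criterion).
#' @return List with `retained` and `rejected` tibbles; `rejected` gains a
#'   `reason` column naming the offending parameter(s). With fewer than 4
#'   records the filter passes everything through with a warning.
#' @export
tukey_filter <- function(cells, k = 1.5) {
  cells <- check_cell_table(cells)
  if (nrow(cells) < 4) {
    warn("fewer than 4 cells: Tukey filter passed all records through")
    return(list(retained = cells,
                rejected = dplyr::mutate(cells[0, ], reason = character())))
  }
  out_flags <- purrr::map(cell_cols, function(p) {
    q <- quantile(cells[[p]], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    cells[[p]] < q[1] - k * iqr | cells[[p]] > q[2] + k * iqr
  })
  names(out_flags) <- cell_cols
  any_out <- Reduce(`|`, out_flags)
  reason <- vapply(seq_len(nrow(cells)), function(i) {
    paste(cell_cols[vapply(out_flags, `[`, logical(1), i)], collapse = ",")
  }, character(1))
  list(
    retained = cells[!any_out, , drop = FALSE],
    rejected = dplyr::mutate(cells[any_out, , drop = FALSE],
                             reason = paste0("outlier: ", reason[any_out]))
  )
}

#' Longer face diagonals of a unit cell
#'
#' For each face of the cell parallelepiped, returns the longer of the two
#' parallelogram diagonals, e.g. `d_ab = sqrt(a^2 + b^2 + 2ab|cos gamma|)`.
#' These three lengths are the cell representation used for both the linear
#' cell variation statistic and the cell distance matrix.
#'
#' @param cell A [unit_cell()].
#' @return Named numeric vector `c(d_ab = , d_bc = , d_ca = )` in angstrom.
#' @examples
#' face_diagonals(unit_cell(10, 20, 30))  # sqrt(500), sqrt(1300), sqrt(1000)
#' @export
face_diagonals <- function(cell) {
  if (!is_unit_cell(cell)) abort_config("`cell` must be a unit_cell")
  longer <- function(p, q, angle_deg) {
    sqrt(p^2 + q^2 + 2 * p * q * abs(cos(angle_deg * pi / 180)))
  }
  c(d_ab = longer(cell$a, cell$b, cell$gamma),
    d_bc = longer(cell$b, cell$c, cell$alpha),
    d_ca = longer(cell$c, cell$a, cell$beta))
}

cell_diagonal_table <- function(cells) {
  cells <- check_cell_table(cells)
  diag3 <- purrr::pmap(cells[cell_cols], function(a, b, c, alpha, beta, gamma) {
    face_diagonals(unit_cell(a, b, c, alpha, beta, gamma))
  })
  tibble(chunk_id = cells$chunk_id,
         d_ab = vapply(diag3, `[[`, numeric(1), "d_ab"),
         d_bc = vapply(diag3, `[[`, numeric(1), "d_bc"),
         d_ca = vapply(diag3, `[[`, numeric(1), "d_ca"))
}

#' Linear cell variation (LCV) across a set of unit cells
#'
#' For every pair of cells and every face diagonal, computes the percentage
#' change `100 * |d_i - d_j| / min(d_i, d_j)`; the LCV is the maximum over
#' all pairs and diagonals. Identical cells give 0; values below about 1%
#' indicate lattice variation too small for unit-cell-based clustering to
#' resolve.
#'
#' @param cells Tidy cell table (>= 2 rows).
#' @return An object of class `lcv_report`: list with `max_lcv_percent`,
#'   `argmax_pair` (the two chunk ids), `diagonal` (which face diagonal
#'   attains the maximum).
#' @export
lcv <- function(cells) {
  diags <- cell_diagonal_table(cells)
  if (nrow(diags) < 2) abort_data("lcv needs at least 2 cells")
  best <- list(value = 0, pair = c(diags$chunk_id[1], diags$chunk_id[2]),
               diagonal = "d_ab")
  for (d in c("d_ab", "d_bc", "d_ca")) {
    v <- diags[[d]]
    rel <- 100 * abs(outer(v, v, `-`)) / outer(v, v, pmin)
    idx <- which(rel == max(rel), arr.ind = TRUE)[1, ]
    if (rel[idx[1], idx[2]] >= best$value) {
      best <- list(value = rel[idx[1], idx[2]],
                   pair = diags$chunk_id[c(idx[1], idx[2])],
                   diagonal = d)
    }
  }
  structure(
    list(max_lcv_percent = best$value, argmax_pair = sort(best$pair),
         diagonal = best$diagonal, n_cells = nrow(diags)),
    class = "lcv_report"
  )
}

#' @export
print.lcv_report <- function(x, ...) {
  cat(sprintf("<lcv_report> max LCV %.3g%% (%s, %s vs %s, n=%d)\n",
              x$max_lcv_percent, x$diagonal,
              x$argmax_pair[1], x$argmax_pair[2], x$n_cells))
  invisible(x)
}

#' @method glance lcv_report
#' @export
glance.lcv_report <- function(x, ...) {
  tibble(max_lcv_percent = x$max_lcv_percent,
         chunk_1 = x$argmax_pair[1], chunk_2 = x$argmax_pair[2],
         diagonal = x$diagonal, n_cells = x$n_cells)
}

#' Unit-cell distance matrix for clustering
#'
#' The distance between two cells is the Euclidean distance between their
#' face-diagonal triples (angstrom), feeding [linkage_cluster()] exactly as
#' the intensity-based distance matrix does.
#'
#' @param cells Tidy cell table (>= 3 rows).
#' @return An `iso_dist` over the chunk ids.
#' @export
cell_distance_matrix <- function(cells) {
  diags <- cell_diagonal_table(cells)
  if (nrow(diags) < 3) abort_data("need at least 3 cells")
  if (anyDuplicated(diags$chunk_id)) abort_data("chunk_ids must be unique")
  D <- as.matrix(stats::dist(as.matrix(diags[, c("d_ab", "d_bc", "d_ca")])))
  new_iso_dist(labels = diags$chunk_id, values = D,
               metric = "euclidean_face_diagonals")
}
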