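#' Construct a crystallographic unit cell
#'
#' A unit cell is described by its three axis lengths (angstrom) and three
#' inter-axial angles (degrees). The constructor validates that the cell is
#' geometrically realisable: all lengths positive, all angles strictly
#' between 0 and 180 degrees, and the metric tensor positive definite.
#'
#' @param a,b,c Axis lengths in angstrom.
#' @param alpha,beta,gamma Inter-axial angles in degrees
#'   (alpha between b and c, beta between a and c, gamma between a and b).
#' @return An object of class `unit_cell`: a named list with elements
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' unit_cell(54.9, 58.6, 67.2)           # orthorhombic, angles default to 90
#' unit_cell(80, 80, 37, gamma = 120)    # hexagonal-shaped cell
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  vals <- list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  bad <- names(vals)[!vapply(vals, is_scalar_number, logical(1))]
  if (length(bad) > 0) {
    abort_config(paste0("unit_cell parameters must be finite scalars: ",
                        paste(bad, collapse = ", ")))
  }
  if (any(unlist(vals[c("a", "b", "c")]) <= 0)) {
    abort_config("unit_cell axis lengths must be positive")
  }
  ang <- unlist(vals[c("alpha", "beta", "gamma")])
  if (any(ang <= 0 | ang >= 180)) {
    abort_config("unit_cell angles must lie strictly between 0 and 180 degrees")
  }
  cell <- structure(vals, class = "unit_cell")
  G <- metric_tensor(cell)
  if (det(G) <= 0) {
    abort_config("unit_cell angles are incompatible (metric tensor not positive definite)")
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

is_unit_cell <- function(x) inherits(x, "unit_cell")

# Direct-space metric tensor G (angstrom^2).
metric_tensor <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  with(cell, matrix(c(
    a * a,      a * b * cg, a * c * cb,
    a * b * cg, b * b,      b * c * ca,
    a * c * cb, b * c * ca, c * c
  ), nrow = 3, byrow = TRUE))
}

#' Resolution (d-spacing) of reflections in a general triclinic cell
#'
#' Computes the lattice-plane spacing d(hkl) = 1 / sqrt(h' G* h) where G* is
#' the reciprocal metric tensor, valid for any cell geometry. Vectorised over
#' Miller indices.
#'
#' @param cell A [unit_cell()].
#' @param h,k,l Integer Miller indices (equal-length vectors). The zero triple
#'   (0,0,0) is not a reflection and raises an error.
#' @return Numeric vector of d-spacings in angstrom.
#' @examples
#' cub <- unit_cell(10, 10, 10)
#' d_spacing(cub, 1, 0, 0)  # 10
#' d_spacing(cub, 1, 1, 0)  # 10 / sqrt(2)
#' @export
d_spacing <- function(cell, h, k, l) {
  if (!is_unit_cell(cell)) abort_config("`cell` must be a unit_cell")
  H <- cbind(h, k, l)
  if (any(rowSums(H != 0) == 0)) {
    abort_config("d_spacing is undefined for the (0,0,0) index")
  }
  Gstar <- solve(metric_tensor(cell))
  1 / sqrt(rowSums((H %*% Gstar) * H))
}
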