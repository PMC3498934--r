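#' Construct a unit cell
#'
#' A unit cell is described by three edge lengths \eqn{a, b, c} in angstroms
#' and three inter-axial angles \eqn{\alpha, \beta, \gamma} in degrees
#' (\eqn{\alpha} between \eqn{b} and \eqn{c}, and so on). The constructor
#' validates geometric realizability: all lengths must be positive, all
#' angles strictly between 0 and 180 degrees, and the squared
#' orthogonalization factor
#' \deqn{v^2 = 1 - \cos^2\alpha - \cos^2\beta - \cos^2\gamma +
#'       2\cos\alpha\cos\beta\cos\gamma}
#' must be strictly positive.
#'
#' @param a,b,c Edge lengths in angstroms.
#' @param alpha,beta,gamma Inter-axial angles in degrees.
#' @return An object of class `unit_cell`: a named list with fields
#'   `a`, `b`, `c`, `alpha`, `beta`, `gamma`.
#' @examples
#' unit_cell(57.8, 57.8, 150.1, 90, 90, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  cell <- structure(
    list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
         alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.numeric(gamma)),
    class = "unit_cell"
  )
  validate_cell(cell)
}

#' Coerce to a unit cell
#'
#' Accepts a `unit_cell`, a numeric vector of length six
#' (`a, b, c, alpha, beta, gamma`), or a one-row data frame with those
#' columns.
#'
#' @param x Object to coerce.
#' @return A validated `unit_cell`.
#' @export
as_unit_cell <- function(x) {
  if (inherits(x, "unit_cell")) return(validate_cell(x))
  if (is.numeric(x) && length(x) == 6L) {
    return(unit_cell(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]]))
  }
  if (is.data.frame(x) && nrow(x) == 1L &&
      all(c("a", "b", "c", "alpha", "beta", "gamma") %in% names(x))) {
    return(unit_cell(x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  }
  stop("cannot interpret object as a unit cell", call. = FALSE)
}

# squared orthogonalization factor; strictly positive for a realizable cell
cell_v2 <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Validate a unit cell
#'
#' Checks the `unit_cell` invariants and returns the cell unchanged if they
#' hold. Degenerate cells (non-positive length, angle outside (0, 180), or
#' squared orthogonalization factor \eqn{v^2 \le 10^{-12}}) raise an error
#' naming the violated invariant.
#'
#' @param cell A `unit_cell`.
#' @return The validated cell, invisibly unchanged.
#' @export
validate_cell <- function(cell) {
  len <- c(cell$a, cell$b, cell$c)
  ang <- c(cell$alpha, cell$beta, cell$gamma)
  if (any(!is.finite(len)) || any(!is.finite(ang))) {
    stop("degenerate cell: non-finite parameter", call. = FALSE)
  }
  if (any(len <= 0)) {
    stop("degenerate cell: non-positive length (a, b, c must be > 0)",
         call. = FALSE)
  }
  if (any(ang <= 0 | ang >= 180)) {
    stop("degenerate cell: angle out of range (0, 180) degrees",
         call. = FALSE)
  }
  if (cell_v2(cell) <= 1e-12) {
    stop("degenerate cell: v² ≤ 0 (angles are not jointly realizable)",
         call. = FALSE)
  }
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("<unit_cell> a=%.4g b=%.4g c=%.4g Å  alpha=%.4g beta=%.4g gamma=%.4g°\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
format.unit_cell <- function(x, digits = 6, ...) {
  paste(formatC(unlist(x, use.names = FALSE), digits = digits, format = "g"),
        collapse = ",")
}

#' Parse a comma-separated cell string
#'
#' Parses `"a,b,c,alpha,beta,gamma"` (e.g. `"24,24,24,90,90,90"`) into a
#' validated [unit_cell()].
#'
#' @param x A single string of six comma-separated numbers.
#' @return A `unit_cell`.
#' @export
parse_cell_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(trimws(x), ",", fixed = TRUE)[[1]]
  if (length(parts) != 6L) {
    stop(sprintf("cell string must have 6 comma-separated numbers, got %d: '%s'",
                 length(parts), x), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(parts))
  if (any(is.na(vals))) {
    bad <- parts[which(is.na(vals))[1]]
    stop(sprintf("cannot parse cell component '%s' as a number", bad),
         call. = FALSE)
  }
  as_unit_cell(vals)
}

#' Cartesian basis of a unit cell
#'
#' Orthogonalizes a unit cell into three Cartesian row vectors using the
#' standard PDB convention: `a` along x, `b` in the xy-plane, right-handed.
#'
#' @param cell A `unit_cell`.
#' @return A 3x3 numeric matrix whose rows are `va`, `vb`, `vc` in angstroms.
#' @export
cell_to_basis <- function(cell) {
  cell <- validate_cell(cell)
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- sqrt(cell_v2(cell))
  m <- rbind(
    c(cell$a, 0, 0),
    c(cell$b * cg, cell$b * sg, 0),
    c(cell$c * cb, cell$c * (ca - cb * cg) / sg, cell$c * v / sg)
  )
  rownames(m) <- c("va", "vb", "vc")
  m
}

#' Unit cell of a Cartesian basis
#'
#' Recovers cell lengths and angles from three basis row vectors. The result
#' is rotation-invariant; handedness is not encoded in cell parameters.
#'
#' @param basis A 3x3 matrix with basis vectors as rows.
#' @return A `unit_cell`.
#' @export
basis_to_cell <- function(basis) {
  basis <- as.matrix(basis)
  stopifnot(identical(dim(basis), c(3L, 3L)))
  if (abs(det(basis)) < 1e-12) {
    stop("singular basis: vectors are not linearly independent", call. = FALSE)
  }
  n <- sqrt(rowSums(basis^2))
  ang <- function(i, j) {
    cosv <- sum(basis[i, ] * basis[j, ]) / (n[i] * n[j])
    acos(max(-1, min(1, cosv))) * 180 / pi
  }
  unit_cell(n[1], n[2], n[3], ang(2, 3), ang(1, 3), ang(1, 2))
}

#' Unit-cell volume
#'
#' @param cell A `unit_cell`.
#' @return Volume in cubic angstroms, \eqn{abc\,v}.
#' @export
cell_volume <- function(cell) {
  cell <- validate_cell(cell)
  cell$a * cell$b * cell$c * sqrt(cell_v2(cell))
}

#' Cell vertex points used for superposition
#'
#' Returns the four labelled Cartesian points that represent a cell for
#' rigid-body superposition: the origin `O` and the three axis endpoints
#' `A`, `B`, `C` (the tips of the basis vectors).
#'
#' @param cell A `unit_cell`.
#' @return A 4x3 numeric matrix with rows `O`, `A`, `B`, `C` (angstroms).
#' @export
cell_vertices <- function(cell) {
  b <- cell_to_basis(cell)
  m <- rbind(O = c(0, 0, 0), A = b[1, ], B = b[2, ], C = b[3, ])
  colnames(m) <- c("x", "y", "z")
  m
}
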