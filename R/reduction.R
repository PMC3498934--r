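# Conventional -> primitive basis transformations and Niggli canonicalization.
# A query (cell, space group) and every database entry are pushed through the
# same two-step reduction so that lattices deposited in different conventional
# descriptions become directly comparable.

#' Conventional-to-primitive centering transformation
#'
#' Returns the 3x3 matrix whose rows express the primitive basis vectors in
#' the conventional basis, for one fixed standard choice per centering type.
#' `P` and `R_rhomb` (already primitive) return the identity;
#' `|det| = 1 / multiplicity` in all cases.
#'
#' @param centering One of `"P"`, `"A"`, `"B"`, `"C"`, `"I"`, `"F"`,
#'   `"R_hex"`, `"R_rhomb"`.
#' @return A 3x3 numeric matrix.
#' @export
centering_transform <- function(centering) {
  switch(centering,
    P = diag(3),
    R_rhomb = diag(3),
    A = rbind(c(1, 0, 0), c(0, 1/2, 1/2), c(0, -1/2, 1/2)),
    B = rbind(c(1/2, 0, 1/2), c(0, 1, 0), c(-1/2, 0, 1/2)),
    C = rbind(c(1/2, 1/2, 0), c(-1/2, 1/2, 0), c(0, 0, 1)),
    I = rbind(c(-1/2, 1/2, 1/2), c(1/2, -1/2, 1/2), c(1/2, 1/2, -1/2)),
    F = rbind(c(0, 1/2, 1/2), c(1/2, 0, 1/2), c(1/2, 1/2, 0)),
    R_hex = rbind(c(2/3, 1/3, 1/3), c(-1/3, 1/3, 1/3), c(-1/3, -2/3, 1/3)),
    stop(sprintf("unknown centering type '%s'", centering), call. = FALSE)
  )
}

#' Primitive cell of a conventional (cell, space group) pair
#'
#' Applies the centering transformation of the space group's lattice type to
#' the conventional basis and returns the primitive cell. The volume shrinks
#' by exactly the centering multiplicity (1 for P and rhombohedral-setting R,
#' 2 for A/B/C/I, 3 for hexagonal-setting R, 4 for F).
#'
#' @param cell A `unit_cell` in the conventional setting.
#' @param sg A `space_group_info` or symbol.
#' @return A `unit_cell` of the primitive lattice.
#' @export
primitive_cell <- function(cell, sg) {
  if (!inherits(sg, "space_group_info")) sg <- parse_space_group(sg)
  cell <- validate_cell(cell)
  m <- centering_transform(sg$centering)
  basis_to_cell(m %*% cell_to_basis(cell))
}

# metric-tensor form used by the reduction:
# A = a^2, B = b^2, C = c^2, xi = 2bc cos(alpha), eta = 2ac cos(beta),
# zeta = 2ab cos(gamma)
cell_to_gruber <- function(cell) {
  a <- cell$a; b <- cell$b; c <- cell$c
  c(A = a^2, B = b^2, C = c^2,
    xi = 2 * b * c * cos(cell$alpha * pi / 180),
    eta = 2 * a * c * cos(cell$beta * pi / 180),
    zeta = 2 * a * b * cos(cell$gamma * pi / 180))
}

gruber_to_cell <- function(g) {
  a <- sqrt(g[["A"]]); b <- sqrt(g[["B"]]); c <- sqrt(g[["C"]])
  clamp <- function(x) max(-1, min(1, x))
  unit_cell(a, b, c,
            acos(clamp(g[["xi"]] / (2 * b * c))) * 180 / pi,
            acos(clamp(g[["eta"]] / (2 * a * c))) * 180 / pi,
            acos(clamp(g[["zeta"]] / (2 * a * b))) * 180 / pi)
}

#' Niggli reduction of a unit cell
#'
#' Computes the Niggli reduced cell by the Krivy-Gruber (1976) iteration on
#' the metric tensor, with epsilon-stabilized comparisons
#' (\eqn{\epsilon = 10^{-5}} times the mean squared cell edge) and a
#' 1000-step cap. The reduced cell is a canonical description of the lattice:
#' \eqn{a \le b \le c}, angle conditions of the Niggli form, same lattice
#' (related to the input by an integer unimodular change of basis), volume
#' preserved.
#'
#' @param cell A `unit_cell`.
#' @return The Niggli reduced `unit_cell`.
#' @export
niggli_reduce <- function(cell) {
  g <- cell_to_gruber(validate_cell(cell))
  A <- g[["A"]]; B <- g[["B"]]; C <- g[["C"]]
  xi <- g[["xi"]]; eta <- g[["eta"]]; zeta <- g[["zeta"]]
  for (step in seq_len(1000L)) {
    # comparisons are stabilized relative to the current cell size; the
    # mean squared edge shrinks as the basis shortens, so two descriptions
    # of one lattice terminate in the same reduced form
    eps <- 1e-5 * (A + B + C) / 3
    # 1: order A <= B
    if (A > B + eps || (abs(A - B) <= eps && abs(xi) > abs(eta) + eps)) {
      tmp <- A; A <- B; B <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
    }
    # 2: order B <= C
    if (B > C + eps || (abs(B - C) <= eps && abs(eta) > abs(zeta) + eps)) {
      tmp <- B; B <- C; C <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      next
    }
    # 3/4: fix the signs of xi, eta, zeta jointly. The actual signs are
    # used, not eps-classified ones: with an even number of negatives the
    # all-positive choice is exactly realizable by a diagonal +-1 change of
    # basis, with an odd number the all-negative choice is; forcing a sign
    # on a merely-near-zero value would alter the lattice by up to eps.
    if (xi * eta * zeta > 0) {
      xi <- abs(xi); eta <- abs(eta); zeta <- abs(zeta)
    } else {
      xi <- -abs(xi); eta <- -abs(eta); zeta <- -abs(zeta)
    }
    # 5
    if (abs(xi) > B + eps ||
        (abs(B - xi) <= eps && 2 * eta < zeta - eps) ||
        (abs(B + xi) <= eps && zeta < -eps)) {
      s <- if (xi > 0) 1 else -1
      C <- B + C - xi * s
      eta <- eta - zeta * s
      xi <- xi - 2 * B * s
      next
    }
    # 6
    if (abs(eta) > A + eps ||
        (abs(A - eta) <= eps && 2 * xi < zeta - eps) ||
        (abs(A + eta) <= eps && zeta < -eps)) {
      s <- if (eta > 0) 1 else -1
      C <- A + C - eta * s
      xi <- xi - zeta * s
      eta <- eta - 2 * A * s
      next
    }
    # 7
    if (abs(zeta) > A + eps ||
        (abs(A - zeta) <= eps && 2 * xi < eta - eps) ||
        (abs(A + zeta) <= eps && eta < -eps)) {
      s <- if (zeta > 0) 1 else -1
      B <- A + B - zeta * s
      xi <- xi - eta * s
      zeta <- zeta - 2 * A * s
      next
    }
    # 8
    if (xi + eta + zeta + A + B < -eps ||
        (abs(xi + eta + zeta + A + B) <= eps &&
         2 * (A + eta) + zeta > eps)) {
      C <- A + B + C + xi + eta + zeta
      xi <- 2 * B + xi + zeta
      eta <- 2 * A + eta + zeta
      next
    }
    return(gruber_to_cell(c(A = A, B = B, C = C,
                            xi = xi, eta = eta, zeta = zeta)))
  }
  stop("Niggli reduction did not converge within 1000 steps (pathological cell)",
       call. = FALSE)
}

#' Reduce a (cell, space group) pair to a canonical primitive P1 cell
#'
#' The core canonicalization of the matching method: the conventional cell
#' is first converted to its primitive lattice cell (removing centering),
#' then Niggli-reduced so that any two descriptions of the same lattice
#' yield the same cell. Both query and database entries pass through this
#' function, making their cells directly superposable.
#'
#' @param cell A `unit_cell` (conventional setting).
#' @param sg A `space_group_info` or symbol; defaults to P1.
#' @return An object of class `p1_cell`: list with fields `cell` (the
#'   reduced primitive cell), `source_cell`, `source_space_group`
#'   (canonical symbol), `setting_defaulted`.
#' @examples
#' reduce_to_p1(unit_cell(10, 10, 10, 90, 90, 90), "I213")
#' @export
reduce_to_p1 <- function(cell, sg = NULL) {
  if (!inherits(sg, "space_group_info")) sg <- parse_space_group(sg)
  cell <- validate_cell(cell)
  reduced <- niggli_reduce(primitive_cell(cell, sg))
  structure(
    list(cell = reduced, source_cell = cell,
         source_space_group = sg$symbol,
         setting_defaulted = isTRUE(sg$setting_defaulted)),
    class = "p1_cell"
  )
}

#' @export
print.p1_cell <- function(x, ...) {
  cat(sprintf("<p1_cell> reduced from %s [%s]\n",
              format(x$source_cell), x$source_space_group))
  print(x$cell)
  invisible(x)
}
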