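# Rigid-body superposition of cell vertex sets. Two reduced P1 cells are
# compared by superposing their four vertex points (O, A, B, C) with the
# least-squares optimal proper rotation + translation, minimized over the
# six right-handed axis assignments of the candidate cell. Improper
# (mirror) operations are never used: protein crystals are enantiomorphic.

# joint permutations of the (length, opposite-angle) pairs, identity first,
# then lexicographic — also the documented tie-break order
.axis_perms <- rbind(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)

#' Optimal rigid-body superposition of two point sets
#'
#' Kabsch superposition: finds the proper rotation and translation that
#' minimize the RMSD between two equal-size sets of corresponding points.
#' Centroids are superposed; the rotation is the SVD solution with the
#' determinant-sign correction, so the result is always a proper rotation
#' (det = +1), never a reflection.
#'
#' @param p,q Numeric n x 3 matrices of corresponding points (rows).
#' @return A list of class `superposition_result` with fields `rmsd`
#'   (angstroms), `rotation` (3x3, det +1), `translation` (length-3), and
#'   `permutation` (`NA` here; filled by [best_cell_rmsd()]).
#'   The transform maps `p` onto `q`: `q ~ p %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!identical(dim(p), dim(q)) || ncol(p) != 3L) {
    stop("point sets must be matching n x 3 matrices", call. = FALSE)
  }
  n <- nrow(p)
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2, cp); q0 <- sweep(q, 2, cq)
  h <- crossprod(p0, q0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- p0 %*% t(rot)
  rmsd <- sqrt(sum((fitted - q0)^2) / n)
  structure(
    list(rmsd = rmsd, rotation = rot,
         translation = as.numeric(cq - rot %*% cp),
         permutation = NA_integer_),
    class = "superposition_result"
  )
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.4f Å%s\n", x$rmsd,
              if (!is.na(x$permutation))
                sprintf(" (axis assignment %d of 6)", x$permutation) else ""))
  invisible(x)
}

#' The six right-handed axis assignments of a cell
#'
#' Generates the six cells obtained by jointly permuting the
#' (length, opposite-angle) pairs (a, alpha), (b, beta), (c, gamma) in all
#' 3! orders. Each permuted cell is re-orthogonalized with the fixed
#' right-handed convention, so all six candidates are proper (right-handed)
#' descriptions — mirror images are never generated.
#'
#' @param cell A `unit_cell`.
#' @return A list of six `unit_cell` objects; the first is the identity
#'   assignment, the rest follow lexicographic permutation order.
#' @export
axis_permutations <- function(cell) {
  cell <- validate_cell(cell)
  len <- c(cell$a, cell$b, cell$c)
  ang <- c(cell$alpha, cell$beta, cell$gamma)
  lapply(seq_len(6L), function(i) {
    p <- .axis_perms[i, ]
    unit_cell(len[p[1]], len[p[2]], len[p[3]],
              ang[p[1]], ang[p[2]], ang[p[3]])
  })
}

#' Best superposition of two cells over the six axis assignments
#'
#' Superposes the vertex points of `query` onto those of each of the six
#' right-handed axis assignments of `candidate` and returns the
#' superposition with the smallest RMSD. Ties are broken by the first
#' assignment in the fixed order (identity first, then lexicographic).
#'
#' @param query,candidate `unit_cell` objects (normally reduced P1 cells).
#' @return A `superposition_result` with `permutation` set to the winning
#'   assignment index (1-6).
#' @export
best_cell_rmsd <- function(query, candidate) {
  vq <- cell_vertices(query)
  best <- NULL
  cands <- axis_permutations(candidate)
  for (i in seq_len(6L)) {
    res <- kabsch_superpose(vq, cell_vertices(cands[[i]]))
    if (is.null(best) || res$rmsd < best$rmsd - 1e-12) {
      res$permutation <- i
      best <- res
    }
  }
  best
}

#' Default match cutoff for a query cell
#'
#' The default r.m.s.-difference cutoff: the larger of 2.5 angstroms or 1%
#' of the sum of the longest and the shortest dimension of the query cell
#' as supplied (before any reduction).
#'
#' @param query A `unit_cell`.
#' @return Cutoff in angstroms (always >= 2.5).
#' @examples
#' default_cutoff(unit_cell(50, 60, 70))   # 2.5
#' default_cutoff(unit_cell(150, 200, 300)) # 4.5
#' @export
default_cutoff <- function(query) {
  query <- validate_cell(query)
  len <- c(query$a, query$b, query$c)
  max(2.5, 0.01 * (max(len) + min(len)))
}

#' Scan a database for cells matching a reduced query cell
#'
#' Compares the query's reduced P1 cell against the precomputed P1 cell of
#' every database entry using [best_cell_rmsd()], and returns one hit per
#' entry within the cutoff, sorted by ascending RMSD (ties broken by entry
#' id). The result is independent of scan order.
#'
#' @param db A `cellmatch_db` (see [db_new()]).
#' @param query_p1 A `p1_cell` from [reduce_to_p1()], or a `unit_cell`
#'   already in reduced form.
#' @param cutoff Match cutoff in angstroms (see [default_cutoff()]).
#' @return A tibble of hits: `entry_id`, `rmsd`, `permutation`, plus the
#'   entry metadata columns (`organism`, `method`, `space_group`, cell
#'   parameters, `r_work`, `r_free`, `chains`).
#' @export
scan_database <- function(db, query_p1, cutoff) {
  stopifnot(inherits(db, "cellmatch_db"), is.numeric(cutoff), cutoff >= 0)
  qcell <- if (inherits(query_p1, "p1_cell")) query_p1$cell
           else as_unit_cell(query_p1)
  entries <- db$entries
  if (nrow(entries) == 0L) {
    warning("database is empty; no cells to scan", call. = FALSE)
    return(empty_hits())
  }
  res <- purrr::map(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    cand <- unit_cell(e$p1_a, e$p1_b, e$p1_c, e$p1_alpha, e$p1_beta, e$p1_gamma)
    fit <- best_cell_rmsd(qcell, cand)
    tibble::tibble(entry_id = e$entry_id, rmsd = fit$rmsd,
                   permutation = fit$permutation)
  })
  hits <- dplyr::bind_rows(res)
  hits <- hits[hits$rmsd <= cutoff + 1e-9, , drop = FALSE]
  hits <- dplyr::left_join(hits, entries, by = "entry_id")
  dplyr::arrange(hits, .data$rmsd, .data$entry_id)
}

empty_hits <- function() {
  tibble::tibble(entry_id = character(), rmsd = numeric(),
                 permutation = integer())
}
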