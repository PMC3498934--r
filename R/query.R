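#' Run a full cell-match query
#'
#' The end-to-end pipeline: parse the query cell and space group, reduce to
#' the canonical primitive P1 cell, scan the database for entries whose
#' reduced cells superpose within the cutoff, and group the hits into
#' sequence families. Deterministic: identical inputs give identical
#' reports.
#'
#' @param db A `cellmatch_db` (from [db_build()] or [db_load()]).
#' @param cell A `unit_cell`, numeric vector of six, or a
#'   `"a,b,c,alpha,beta,gamma"` string.
#' @param space_group Optional space-group symbol; assumed P1 when absent.
#' @param cutoff Optional cutoff in angstroms; defaults to
#'   [default_cutoff()] of the query cell as supplied.
#' @param clustering A [clustering_params()].
#' @return An object of class `cell_query_report`: list with `query_cell`,
#'   `space_group`, `p1` (the reduced cell), `cutoff`, `n_hits`, `hits`
#'   (tibble), `families` (tibble).
#' @examples
#' \dontrun{
#' db <- db_load("pdb-cells.jsonl")
#' run_query(db, "57.8,57.8,150.1,90,90,90", "P41212")
#' }
#' @export
run_query <- function(db, cell, space_group = NULL, cutoff = NULL,
                      clustering = clustering_params()) {
  stopifnot(inherits(db, "cellmatch_db"))
  if (is.character(cell)) cell <- parse_cell_string(cell)
  cell <- as_unit_cell(cell)
  sg <- parse_space_group(space_group, aliases = db$aliases)
  cutoff <- cutoff %||% default_cutoff(cell)
  if (!is.numeric(cutoff) || cutoff < 0) {
    stop("cutoff must be a non-negative number of angstroms", call. = FALSE)
  }
  p1 <- reduce_to_p1(cell, sg)
  hits <- scan_database(db, p1, cutoff)
  families <- group_families(hits, clustering)
  structure(
    list(query_cell = cell, space_group = sg$symbol,
         setting_defaulted = isTRUE(sg$setting_defaulted),
         p1 = p1, cutoff = cutoff,
         n_hits = nrow(hits), hits = hits, families = families),
    class = "cell_query_report"
  )
}

#' @export
print.cell_query_report <- function(x, ...) {
  cat(format_report_text(x))
  invisible(x)
}

#' Fixed-width text report of a query
#'
#' One row per family: family number, representative entry id, its r.m.s.
#' difference (two decimals, angstroms), space group, member count and
#' organism. With `expand = TRUE` every member hit is listed under its
#' family. Byte-identical output for identical reports.
#'
#' @param report A `cell_query_report`.
#' @param expand List all member hits per family.
#' @return A single string (the report text).
#' @export
format_report_text <- function(report, expand = FALSE) {
  stopifnot(inherits(report, "cell_query_report"))
  out <- c(
    sprintf("Query cell : %s", format(report$query_cell)),
    sprintf("Space group: %s%s", report$space_group,
            if (report$setting_defaulted) " (hexagonal setting assumed)" else ""),
    sprintf("Reduced P1 : %s", format(report$p1$cell)),
    sprintf("Cutoff     : %.2f %s", report$cutoff, "Å"),
    sprintf("Hits       : %d in %d families", report$n_hits,
            nrow(report$families)),
    ""
  )
  if (nrow(report$families) == 0L) {
    return(paste(c(out, "No matches within cutoff.", ""), collapse = "\n"))
  }
  hdr <- sprintf("%-7s %-10s %8s  %-12s %7s  %s",
                 "Family", "Entry", "RMSD(Å)", "SpaceGroup",
                 "Members", "Organism")
  rows <- character(0)
  for (i in seq_len(nrow(report$families))) {
    f <- report$families[i, ]
    rows <- c(rows, sprintf("%-7d %-10s %8.2f  %-12s %7d  %s",
                            f$family_id, f$representative, f$rmsd,
                            f$space_group, f$n_members, f$organism))
    if (expand) {
      m <- f$members[[1]]
      rows <- c(rows, sprintf("        - %-10s %6.2f  %-12s %s",
                              m$entry_id, m$rmsd, m$space_group, m$organism))
    }
  }
  paste(c(out, hdr, rows, ""), collapse = "\n")
}

#' JSON report of a query
#'
#' Lossless machine-readable twin of the text report: full-precision RMSDs,
#' stable key order, and a schema version field, so the output can be
#' consumed by other pipelines.
#'
#' @param report A `cell_query_report`.
#' @return A JSON string.
#' @export
format_report_json <- function(report) {
  stopifnot(inherits(report, "cell_query_report"))
  fam <- purrr::map(seq_len(nrow(report$families)), function(i) {
    f <- report$families[i, ]
    m <- f$members[[1]]
    list(
      family_id = f$family_id, representative = f$representative,
      rmsd = f$rmsd, space_group = f$space_group, organism = f$organism,
      n_members = f$n_members, composition = f$composition,
      members = purrr::map(seq_len(nrow(m)), function(j) {
        list(entry_id = m$entry_id[j], rmsd = m$rmsd[j],
             space_group = m$space_group[j], organism = m$organism[j])
      })
    )
  })
  obj <- list(
    schema = "cellmatch-report", schema_version = 1L,
    query = list(
      cell = unclass(report$query_cell),
      space_group = report$space_group,
      setting_defaulted = report$setting_defaulted,
      p1_cell = unclass(report$p1$cell),
      cutoff = report$cutoff
    ),
    n_hits = report$n_hits,
    n_families = nrow(report$families),
    families = fam
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' Tidy a query report
#'
#' `tidy()` returns one row per family (or per hit with
#' `unit = "hits"`); `glance()` returns a one-row summary.
#'
#' @param x A `cell_query_report`.
#' @param unit `"families"` (default) or `"hits"`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.cell_query_report <- function(x, unit = c("families", "hits"), ...) {
  unit <- match.arg(unit)
  if (unit == "hits") {
    cols <- intersect(c("entry_id", "rmsd", "permutation", "space_group",
                        "organism", "method", "r_work", "r_free"),
                      names(x$hits))
    return(tibble::as_tibble(x$hits[, cols, drop = FALSE]))
  }
  dplyr::select(x$families, -"members")
}

#' @rdname tidy.cell_query_report
#' @exportS3Method generics::glance
glance.cell_query_report <- function(x, ...) {
  tibble::tibble(
    n_hits = x$n_hits,
    n_families = nrow(x$families),
    cutoff = x$cutoff,
    best_rmsd = if (x$n_hits > 0) min(x$hits$rmsd) else NA_real_,
    space_group = x$space_group
  )
}

#' Plot a query report
#'
#' Dot plot of hit RMSDs grouped by family, with family representatives
#' emphasized and the cutoff drawn as a dashed line.
#'
#' @param object A `cell_query_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cell_query_report <- function(object, ...) {
  if (nrow(object$families) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no matches within cutoff") +
             ggplot2::theme_void())
  }
  members <- tidyr::unnest(
    dplyr::select(object$families, "family_id", "representative", "members"),
    "members"
  )
  members$family <- factor(
    sprintf("%d: %s", members$family_id, members$representative),
    levels = unique(sprintf("%d: %s", members$family_id,
                            members$representative))
  )
  members$is_rep <- members$entry_id == members$representative
  ggplot2::ggplot(members,
                  ggplot2::aes(x = .data$family, y = .data$rmsd)) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$is_rep,
                                     size = .data$is_rep),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey30")) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 2.6, `FALSE` = 1.6)) +
    ggplot2::labs(x = "family (representative entry)",
                  y = "r.m.s. difference (Å)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
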