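#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

.cellmatch_env <- new.env(parent = emptyenv())

# Embedded table of the 65 Sohncke space groups (67 settings: the two
# rhombohedral groups appear in both the hexagonal ':H' and primitive
# rhombohedral ':R' settings). Only proper operations occur in these groups,
# the ones available to enantiopure protein crystals.
space_group_table <- function() {
  tbl <- .cellmatch_env$sg_table
  if (is.null(tbl)) {
    path <- system.file("extdata", "sohncke_space_groups.tsv",
                        package = "cellmatch", mustWork = TRUE)
    tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    tbl$compact <- compact_symbol(tbl$symbol)
    .cellmatch_env$sg_table <- tbl
  }
  tbl
}

# uppercase, no whitespace/underscores; the spacing-insensitive key
compact_symbol <- function(x) {
  toupper(gsub("[ _]", "", x))
}

# short forms users actually type, mapped to canonical Hermann-Mauguin
builtin_aliases <- function() {
  c(
    "C2" = "C 1 2 1", "P2" = "P 1 2 1", "P21" = "P 1 21 1",
    "H3" = "R 3:H", "H32" = "R 3 2:H"
  )
}

#' Read a space-group alias table
#'
#' Reads a plain-text, two-column alias file mapping observed space-group
#' symbols to canonical Hermann-Mauguin symbols, one pair per line,
#' whitespace- or tab-separated (an optional `->` between the columns is
#' tolerated). Lines starting with `#` are comments.
#'
#' @param path Path to the alias file.
#' @return A named character vector: `names` are observed symbols,
#'   values canonical symbols.
#' @export
read_alias_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(character(0))
  parts <- strsplit(gsub("->", " ", lines, fixed = TRUE), "[ \t]+")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    stop(sprintf("malformed alias line: '%s'", lines[bad][1]), call. = FALSE)
  }
  out <- vapply(parts, function(p) paste(p[-1], collapse = " "), character(1))
  names(out) <- vapply(parts, `[[`, character(1), 1L)
  out
}

#' Parse a space-group symbol
#'
#' Resolves a Hermann-Mauguin symbol, spacing-insensitively (`"P41212"`
#' and `"P 41 21 2"` are equivalent), to the matching entry of the embedded
#' table of the 65 Sohncke space groups. Rhombohedral symbols carry a
#' setting suffix: `":H"` for the hexagonal (centered, multiplicity 3)
#' setting and `":R"` for the primitive rhombohedral setting. A bare
#' rhombohedral symbol such as `"R3"` defaults to the hexagonal setting and
#' the result is flagged with `setting_defaulted = TRUE`. A missing or empty
#' symbol resolves to P1, the assumption used for queries that do not state
#' a space group.
#'
#' @param symbol Space-group symbol, or `NULL`/`NA`/`""` for P1.
#' @param aliases Optional named character vector of extra aliases
#'   (observed -> canonical), e.g. from [read_alias_table()]; consulted
#'   before the embedded table.
#' @return An object of class `space_group_info`: a list with fields
#'   `symbol` (canonical), `number`, `centering` (one of `P A B C I F
#'   R_hex R_rhomb`), `n_ops_conventional`, `multiplicity`,
#'   `n_ops_primitive`, `setting_defaulted`.
#' @examples
#' parse_space_group("P 41 21 2")
#' parse_space_group("R3:R")
#' parse_space_group(NULL) # P1
#' @export
parse_space_group <- function(symbol = NULL, aliases = NULL) {
  if (is.null(symbol) || length(symbol) == 0L || is.na(symbol) ||
      !nzchar(trimws(symbol))) {
    symbol <- "P 1"
  }
  raw <- trimws(symbol)
  tbl <- space_group_table()
  defaulted <- FALSE

  resolve_alias <- function(sym) {
    key <- compact_symbol(sym)
    for (map in list(aliases, builtin_aliases())) {
      if (is.null(map) || length(map) == 0L) next
      hit <- match(key, compact_symbol(names(map)))
      if (!is.na(hit)) return(map[[hit]])
    }
    NULL
  }

  target <- resolve_alias(raw)
  if (!is.null(target)) raw <- target

  key <- compact_symbol(raw)
  idx <- match(key, tbl$compact)
  if (is.na(idx)) {
    # bare rhombohedral symbol without setting: default to hexagonal
    idx <- match(paste0(key, ":H"), tbl$compact)
    if (!is.na(idx)) defaulted <- TRUE
  }
  if (is.na(idx)) {
    cand <- tbl$symbol[order(utils::adist(key, tbl$compact))][1:3]
    stop(sprintf("unknown space group '%s' (nearest symbols: %s)",
                 symbol, paste(cand, collapse = ", ")), call. = FALSE)
  }
  row <- tbl[idx, ]
  structure(
    list(symbol = row$symbol, number = row$number,
         centering = row$centering,
         n_ops_conventional = as.integer(row$n_ops_conventional),
         multiplicity = as.integer(row$multiplicity),
         n_ops_primitive = as.integer(row$n_ops_primitive),
         setting_defaulted = defaulted),
    class = "space_group_info"
  )
}

#' @export
print.space_group_info <- function(x, ...) {
  cat(sprintf("<space_group> %s (no. %d)  centering %s  ops %d (conventional) / %d (primitive)%s\n",
              x$symbol, x$number, x$centering, x$n_ops_conventional,
              x$n_ops_primitive,
              if (isTRUE(x$setting_defaulted)) "  [hexagonal setting assumed]" else ""))
  invisible(x)
}

#' Symmetry-operator counts of a space group
#'
#' Returns the number of symmetry operators of a space group in its
#' conventional setting (including centering translations) and in the
#' primitive setting (conventional count divided by the centering
#' multiplicity). The primitive count is what scales asymmetric-unit
#' content up to the content of the primitive P1 cell.
#'
#' @param sg A `space_group_info` (from [parse_space_group()]) or a symbol.
#' @return A named integer vector `c(n_conventional, n_primitive)`.
#' @export
symop_count <- function(sg) {
  if (!inherits(sg, "space_group_info")) sg <- parse_space_group(sg)
  c(n_conventional = sg$n_ops_conventional, n_primitive = sg$n_ops_primitive)
}
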