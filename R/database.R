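# The local metadata store: one row per structure entry carrying the
# conventional cell, space group, experiment metadata, chain sequences and
# the precomputed reduced P1 cell. P1 cells are computed once at ingest so
# a query only ever superposes precomputed cells.

DB_FORMAT <- "cellmatch-db"
DB_VERSION <- 1L

#' Create an empty cell-match database
#'
#' @param aliases Named character vector of space-group aliases
#'   (observed -> canonical), e.g. from [read_alias_table()].
#' @param residue_table Named character vector of extra residue mappings
#'   (three-letter -> one-letter), consulted before the embedded table.
#' @return An object of class `cellmatch_db`: a list with an `entries`
#'   tibble, the two tables, and a format-version tag.
#' @export
db_new <- function(aliases = NULL, residue_table = NULL) {
  structure(
    list(entries = empty_entries(),
         aliases = aliases %||% character(0),
         residue_table = residue_table %||% character(0),
         version = DB_VERSION),
    class = "cellmatch_db"
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

empty_entries <- function() {
  tibble::tibble(
    entry_id = character(), organism = character(), method = character(),
    a = numeric(), b = numeric(), c = numeric(),
    alpha = numeric(), beta = numeric(), gamma = numeric(),
    space_group = character(), r_work = numeric(), r_free = numeric(),
    p1_a = numeric(), p1_b = numeric(), p1_c = numeric(),
    p1_alpha = numeric(), p1_beta = numeric(), p1_gamma = numeric(),
    n_ops_conventional = integer(), n_ops_primitive = integer(),
    chains = list()
  )
}

#' @export
print.cellmatch_db <- function(x, ...) {
  cat(sprintf("<cellmatch_db> %d entries, %d aliases, %d residue mappings\n",
              nrow(x$entries), length(x$aliases), length(x$residue_table)))
  invisible(x)
}

# build one entries-tibble row from parsed fields; computes the P1 cell
make_entry <- function(entry_id, organism, method, cell, space_group,
                       r_work, r_free, chains, aliases = NULL) {
  sg <- parse_space_group(space_group, aliases = aliases)
  cell <- as_unit_cell(cell)
  p1 <- reduce_to_p1(cell, sg)
  stopifnot(is.data.frame(chains),
            all(c("chain_id", "sequence") %in% names(chains)),
            nrow(chains) >= 1L)
  chains$sequence <- sanitize_sequence(chains$sequence)
  tibble::tibble(
    entry_id = as.character(entry_id),
    organism = as.character(organism %||% ""),
    method = as.character(method %||% ""),
    a = cell$a, b = cell$b, c = cell$c,
    alpha = cell$alpha, beta = cell$beta, gamma = cell$gamma,
    space_group = sg$symbol,
    r_work = as.numeric(r_work %||% NA_real_),
    r_free = as.numeric(r_free %||% NA_real_),
    p1_a = p1$cell$a, p1_b = p1$cell$b, p1_c = p1$cell$c,
    p1_alpha = p1$cell$alpha, p1_beta = p1$cell$beta,
    p1_gamma = p1$cell$gamma,
    n_ops_conventional = sg$n_ops_conventional,
    n_ops_primitive = sg$n_ops_primitive,
    chains = list(tibble::tibble(chain_id = as.character(chains$chain_id),
                                 sequence = chains$sequence))
  )
}

#' Insert or replace a database entry
#'
#' Replaces any existing entry with the same `entry_id`; idempotent.
#'
#' @param db A `cellmatch_db`.
#' @param record A one-row entry tibble (as produced by the ingest
#'   functions), or a list with fields `entry_id`, `organism`, `method`,
#'   `cell`, `space_group`, `r_work`, `r_free`, `chains`.
#' @return The updated database.
#' @export
upsert_entry <- function(db, record) {
  stopifnot(inherits(db, "cellmatch_db"))
  if (!is.data.frame(record)) {
    record <- make_entry(record$entry_id, record$organism, record$method,
                         record$cell, record$space_group,
                         record$r_work, record$r_free, record$chains,
                         aliases = db$aliases)
  }
  stopifnot(nrow(record) == 1L)
  db$entries <- dplyr::bind_rows(
    db$entries[db$entries$entry_id != record$entry_id, , drop = FALSE],
    record
  )
  db$entries <- dplyr::arrange(db$entries, .data$entry_id)
  db
}

#' Remove a database entry
#'
#' Removing an absent id is a no-op with a warning (so purging a superseded
#' entry twice is harmless).
#'
#' @param db A `cellmatch_db`.
#' @param entry_id Entry identifier to remove.
#' @return The updated database.
#' @export
purge_entry <- function(db, entry_id) {
  stopifnot(inherits(db, "cellmatch_db"))
  if (!entry_id %in% db$entries$entry_id) {
    warning(sprintf("entry '%s' not in database; nothing purged", entry_id),
            call. = FALSE)
    return(db)
  }
  db$entries <- db$entries[db$entries$entry_id != entry_id, , drop = FALSE]
  db
}

#' Ingest entries from a tab-separated metadata dump
#'
#' Reads the bulk TSV layout: one entry per row with columns `entry_id`,
#' `organism`, `method`, `a`, `b`, `c`, `alpha`, `beta`, `gamma`,
#' `space_group`, `r_work`, `r_free`, `chains` (semicolon-joined
#' `chain:SEQUENCE` pairs). Empty strings mark missing optional fields.
#' Malformed rows (unparseable cell, unknown space group without an alias,
#' missing chains) are skipped with a per-row warning; valid rows become
#' entry records with the P1 cell computed on ingest.
#'
#' @param path Path to the TSV file.
#' @param aliases Named character vector of space-group aliases.
#' @return A tibble of entry records (possibly fewer rows than the file).
#' @export
ingest_tsv <- function(path, aliases = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("entry_id", "organism", "method", "a", "b", "c",
              "alpha", "beta", "gamma", "space_group",
              "r_work", "r_free", "chains")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop(sprintf("TSV is missing required columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(raw)), function(i) {
    r <- raw[i, ]
    tryCatch({
      chains <- parse_chain_field(r$chains)
      make_entry(
        r$entry_id, r$organism %||% "", r$method %||% "",
        as.numeric(c(r$a, r$b, r$c, r$alpha, r$beta, r$gamma)),
        r$space_group,
        if (nzchar(r$r_work %||% "")) as.numeric(r$r_work) else NA_real_,
        if (nzchar(r$r_free %||% "")) as.numeric(r$r_free) else NA_real_,
        chains, aliases = aliases
      )
    }, error = function(e) {
      warning(sprintf("row %d (%s) skipped: %s", i,
                      r$entry_id %||% "?", conditionMessage(e)),
              call. = FALSE)
      NULL
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) && anyDuplicated(out$entry_id)) {
    warning("duplicated entry_id in file; the last occurrence wins",
            call. = FALSE)
    out <- out[!duplicated(out$entry_id, fromLast = TRUE), , drop = FALSE]
  }
  out
}

parse_chain_field <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(x)) {
    stop("no chains listed", call. = FALSE)
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  if (any(vapply(kv, length, 1L) != 2L)) {
    stop("malformed chains field (expected 'chain:SEQ;...')", call. = FALSE)
  }
  tibble::tibble(chain_id = vapply(kv, `[[`, character(1), 1L),
                 sequence = vapply(kv, `[[`, character(1), 2L))
}

#' Ingest one entry from an mmCIF header
#'
#' Parses the header categories of an mmCIF file — cell, symmetry,
#' experimental method, refinement R factors, source organism, and the
#' polymer sequence loop — into a single entry record. Three-letter residue
#' codes from `_entity_poly_seq.mon_id` are mapped to one-letter codes with
#' [map_residue()]; the reduced P1 cell is computed on ingest. Files
#' lacking a cell or space group are rejected with the reason; missing
#' organism or R factors leave those fields empty but the entry is
#' accepted.
#'
#' @param path Path to an mmCIF file (header categories suffice; atom
#'   records are ignored).
#' @param aliases Named character vector of space-group aliases.
#' @param residue_table Extra residue mappings for [map_residue()].
#' @return A one-row entry tibble.
#' @export
ingest_mmcif_header <- function(path, aliases = NULL, residue_table = NULL) {
  cif <- parse_mmcif_minimal(path)
  item <- function(...) {
    for (k in c(...)) {
      v <- cif$items[[k]]
      if (!is.null(v) && nzchar(v) && !v %in% c(".", "?")) return(v)
    }
    NULL
  }
  cellvals <- suppressWarnings(as.numeric(c(
    item("_cell.length_a"), item("_cell.length_b"), item("_cell.length_c"),
    item("_cell.angle_alpha"), item("_cell.angle_beta"),
    item("_cell.angle_gamma")
  )))
  if (length(cellvals) != 6L || any(is.na(cellvals))) {
    stop(sprintf("mmCIF '%s' rejected: missing or incomplete _cell category",
                 basename(path)), call. = FALSE)
  }
  sg <- item("_symmetry.space_group_name_H-M", "_space_group.name_H-M_alt")
  if (is.null(sg)) {
    stop(sprintf("mmCIF '%s' rejected: missing space group", basename(path)),
         call. = FALSE)
  }
  entry_id <- item("_entry.id") %||% tools::file_path_sans_ext(basename(path))
  organism <- item("_entity_src_nat.pdbx_organism_scientific",
                   "_entity_src_gen.pdbx_gene_src_scientific_name") %||% ""
  method <- item("_exptl.method") %||% ""
  r_work <- item("_refine.ls_R_factor_R_work")
  r_free <- item("_refine.ls_R_factor_R_free")
  chains <- mmcif_chains(cif, residue_table)
  if (nrow(chains) == 0L) {
    stop(sprintf("mmCIF '%s' rejected: no polymer chains", basename(path)),
         call. = FALSE)
  }
  make_entry(entry_id, organism, method, cellvals, sg,
             if (!is.null(r_work)) as.numeric(r_work) else NA_real_,
             if (!is.null(r_free)) as.numeric(r_free) else NA_real_,
             chains, aliases = aliases)
}

# chain table from _entity_poly (entity -> strand ids) plus the
# _entity_poly_seq three-letter sequence loop
mmcif_chains <- function(cif, residue_table = NULL) {
  seqloop <- cif$loops[["_entity_poly_seq.entity_id"]]
  poly <- cif$loops[["_entity_poly.entity_id"]]
  out <- tibble::tibble(chain_id = character(), sequence = character())
  if (is.null(seqloop)) return(out)
  seqs <- split(seqloop[["_entity_poly_seq.mon_id"]],
                seqloop[["_entity_poly_seq.entity_id"]])
  seqs <- lapply(seqs, function(mon) {
    paste(map_residue(mon, table = residue_table), collapse = "")
  })
  strand_of <- function(eid) {
    if (!is.null(poly) &&
        "_entity_poly.pdbx_strand_id" %in% names(poly)) {
      i <- match(eid, poly[["_entity_poly.entity_id"]])
      if (!is.na(i)) {
        s <- poly[["_entity_poly.pdbx_strand_id"]][i]
        return(trimws(strsplit(s, ",", fixed = TRUE)[[1]]))
      }
    }
    eid
  }
  rows <- purrr::map(names(seqs), function(eid) {
    tibble::tibble(chain_id = strand_of(eid), sequence = seqs[[eid]])
  })
  dplyr::bind_rows(rows)
}

# Minimal mmCIF reader for header categories: scalar '_tag value' pairs and
# 'loop_' blocks with simple (possibly quoted) values. Multi-line
# semicolon text blocks are consumed and attached to scalar tags. This is
# deliberately not a full CIF parser; it covers the categories named above.
parse_mmcif_minimal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  items <- list(); loops <- list()
  i <- 1L; n <- length(lines)
  read_semicolon_block <- function(i) {
    txt <- character(0)
    i <- i + 1L
    while (i <= n && !startsWith(lines[i], ";")) {
      txt <- c(txt, lines[i]); i <- i + 1L
    }
    list(value = paste(txt, collapse = ""), next_i = i + 1L)
  }
  tokenize <- function(line) {
    toks <- regmatches(line,
      gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1]]
    gsub("^['\"]|['\"]$", "", toks)
  }
  while (i <= n) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#") || startsWith(line, "data_")) {
      i <- i + 1L; next
    }
    if (identical(tolower(line), "loop_")) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n) {
        l <- trimws(lines[i])
        if (!nzchar(l) || startsWith(l, "_") || startsWith(l, "#") ||
            tolower(l) == "loop_" || startsWith(l, "data_")) break
        if (startsWith(lines[i], ";")) {
          blk <- read_semicolon_block(i)
          vals <- c(vals, blk$value); i <- blk$next_i
        } else {
          vals <- c(vals, tokenize(lines[i])); i <- i + 1L
        }
      }
      if (length(tags) && length(vals) %% length(tags) == 0L) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(m, stringsAsFactors = FALSE)
        names(df) <- tags
        loops[[tags[1]]] <- df
      }
      next
    }
    if (startsWith(line, "_")) {
      toks <- tokenize(line)
      tag <- toks[1]
      if (length(toks) >= 2L) {
        items[[tag]] <- paste(toks[-1], collapse = " ")
        i <- i + 1L
      } else if (i + 1L <= n && startsWith(lines[i + 1L], ";")) {
        blk <- read_semicolon_block(i + 1L)
        items[[tag]] <- blk$value
        i <- blk$next_i
      } else if (i + 1L <= n) {
        items[[tag]] <- gsub("^['\"]|['\"]$", "", trimws(lines[i + 1L]))
        i <- i + 2L
      } else {
        i <- i + 1L
      }
      next
    }
    i <- i + 1L
  }
  list(items = items, loops = loops)
}

#' FASTA text for an entry's chains
#'
#' One FASTA block per chain, in chain order, with header
#' `>{entry_id}_{chain_id} {organism}` and the sequence wrapped at 60
#' columns.
#'
#' @param record A one-row entry tibble.
#' @return A single FASTA-formatted string.
#' @export
entry_fasta <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  chains <- record$chains[[1]]
  if (is.null(chains) || nrow(chains) == 0L) {
    stop(sprintf("entry '%s' has no chains", record$entry_id), call. = FALSE)
  }
  blocks <- purrr::map_chr(seq_len(nrow(chains)), function(i) {
    seq <- chains$sequence[i]
    wrapped <- gsub("(.{60})", "\\1\n", seq)
    wrapped <- sub("\n$", "", wrapped)
    header <- trimws(sprintf(">%s_%s %s", record$entry_id,
                             chains$chain_id[i], record$organism))
    paste0(header, "\n", wrapped, "\n")
  })
  paste(blocks, collapse = "")
}

#' Save / load a database as JSON Lines
#'
#' The on-disk format is JSON Lines: a one-line header object carrying the
#' format tag, version and the alias and residue tables, then one JSON
#' object per entry. The round trip is lossless and byte-stable (saving the
#' same database twice produces identical files).
#'
#' @param db A `cellmatch_db`.
#' @param path File path.
#' @return `db_save` returns `path` invisibly; `db_load` returns the
#'   database.
#' @export
db_save <- function(db, path) {
  stopifnot(inherits(db, "cellmatch_db"))
  header <- jsonlite::toJSON(
    list(format = DB_FORMAT, version = db$version,
         n_entries = nrow(db$entries),
         aliases = as.list(db$aliases),
         residue_table = as.list(db$residue_table)),
    auto_unbox = TRUE, digits = NA
  )
  entry_lines <- purrr::map_chr(seq_len(nrow(db$entries)), function(i) {
    e <- db$entries[i, ]
    rec <- as.list(e[setdiff(names(e), "chains")])
    rec$chains <- list(chain_id = e$chains[[1]]$chain_id,
                       sequence = e$chains[[1]]$sequence)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                  na = "null"))
  })
  writeLines(c(as.character(header), entry_lines), path)
  invisible(path)
}

#' @rdname db_save
#' @export
db_load <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("corrupt database file: empty", call. = FALSE)
  header <- tryCatch(jsonlite::fromJSON(lines[1]),
                     error = function(e) NULL)
  if (is.null(header) || !identical(header$format, DB_FORMAT)) {
    stop("corrupt database file: bad header", call. = FALSE)
  }
  if (!identical(as.integer(header$version), DB_VERSION)) {
    stop(sprintf("database format version %s not supported (expected %d)",
                 header$version, DB_VERSION), call. = FALSE)
  }
  n_expected <- as.integer(header$n_entries)
  body <- lines[-1]
  if (length(body) != n_expected) {
    stop("corrupt database file: truncated (entry count mismatch)",
         call. = FALSE)
  }
  rows <- purrr::map(body, function(l) {
    rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(rec)) stop("corrupt database file: bad entry line",
                           call. = FALSE)
    chains <- tibble::tibble(chain_id = as.character(rec$chains$chain_id),
                             sequence = as.character(rec$chains$sequence))
    rec$chains <- NULL
    row <- tibble::as_tibble(lapply(rec, function(x) {
      if (is.null(x)) NA else x
    }))
    row$r_work <- as.numeric(row$r_work %||% NA_real_)
    row$r_free <- as.numeric(row$r_free %||% NA_real_)
    row$n_ops_conventional <- as.integer(row$n_ops_conventional)
    row$n_ops_primitive <- as.integer(row$n_ops_primitive)
    row$chains <- list(chains)
    row
  })
  db <- db_new(
    aliases = unlist(header$aliases) %||% character(0),
    residue_table = unlist(header$residue_table) %||% character(0)
  )
  db$entries <- if (length(rows)) dplyr::bind_rows(rows) else empty_entries()
  db$entries <- dplyr::arrange(db$entries, .data$entry_id)
  db
}

#' Build a database from ingested records
#'
#' Convenience wrapper: starts from [db_new()] and upserts every row of the
#' record tibble (later duplicates replace earlier ones).
#'
#' @param records A tibble of entry records (from [ingest_tsv()] or
#'   repeated [ingest_mmcif_header()] calls).
#' @inheritParams db_new
#' @return A `cellmatch_db`.
#' @export
db_build <- function(records, aliases = NULL, residue_table = NULL) {
  db <- db_new(aliases = aliases, residue_table = residue_table)
  for (i in seq_len(nrow(records))) {
    db <- upsert_entry(db, records[i, ])
  }
  db
}
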