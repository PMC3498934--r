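make_test_mmcif <- function(path, entry_id = "1abc",
                            cell = c(57.8, 57.8, 150.1, 90, 90, 90),
                            sg = "'P 41 21 2'",
                            with_cell = TRUE, mon_ids = NULL) {
  mon_ids <- mon_ids %||% c("MET", "ALA", "MSE", "GLY", "ZZZ")
  lines <- c(
    sprintf("data_%s", entry_id),
    sprintf("_entry.id %s", entry_id),
    if (with_cell) c(
      sprintf("_cell.length_a %.3f", cell[1]),
      sprintf("_cell.length_b %.3f", cell[2]),
      sprintf("_cell.length_c %.3f", cell[3]),
      sprintf("_cell.angle_alpha %.2f", cell[4]),
      sprintf("_cell.angle_beta %.2f", cell[5]),
      sprintf("_cell.angle_gamma %.2f", cell[6])
    ),
    sprintf("_symmetry.space_group_name_H-M %s", sg),
    "_exptl.method 'X-RAY DIFFRACTION'",
    "_refine.ls_R_factor_R_work 0.185",
    "_refine.ls_R_factor_R_free 0.221",
    "_entity_src_gen.pdbx_gene_src_scientific_name 'Thaumatococcus daniellii'",
    "loop_",
    "_entity_poly.entity_id",
    "_entity_poly.pdbx_strand_id",
    "1 'A,B'",
    "loop_",
    "_entity_poly_seq.entity_id",
    "_entity_poly_seq.num",
    "_entity_poly_seq.mon_id",
    sprintf("1 %d %s", seq_along(mon_ids), mon_ids)
  )
  writeLines(lines, path)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("mmCIF headers ingest with mapped sequences and a precomputed P1 cell", {
  path <- make_test_mmcif(withr::local_tempfile(fileext = ".cif"))
  rec <- ingest_mmcif_header(path)
  expect_identical(rec$entry_id, "1abc")
  expect_identical(rec$space_group, "P 41 21 2")
  expect_identical(rec$n_ops_conventional, 8L)
  expect_identical(rec$organism, "Thaumatococcus daniellii")
  expect_equal(rec$r_free, 0.221)
  chains <- rec$chains[[1]]
  expect_identical(chains$chain_id, c("A", "B"))
  # MSE -> M, unknown ZZZ -> X, both chains share entity 1's sequence
  expect_identical(unique(chains$sequence), "MAMGX")
  # stored P1 cell is recomputable from (cell, space group)
  p1 <- reduce_to_p1(unit_cell(rec$a, rec$b, rec$c, rec$alpha, rec$beta,
                               rec$gamma), rec$space_group)
  expect_equal(c(rec$p1_a, rec$p1_b, rec$p1_c),
               c(p1$cell$a, p1$cell$b, p1$cell$c), tolerance = 1e-9)
})

test_that("mmCIF files without a cell or space group are rejected with the reason", {
  nocell <- make_test_mmcif(withr::local_tempfile(fileext = ".cif"),
                            with_cell = FALSE)
  expect_error(ingest_mmcif_header(nocell), "_cell")
  path <- withr::local_tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell.length_a 10", "_cell.length_b 10",
               "_cell.length_c 10", "_cell.angle_alpha 90",
               "_cell.angle_beta 90", "_cell.angle_gamma 90"), path)
  expect_error(ingest_mmcif_header(path), "space group")
})

test_that("residue mapping is total: standard, modified, unknown, custom", {
  expect_identical(map_residue(c("MSE", "ALA", "ZZZ")), c("M", "A", "X"))
  expect_identical(map_residue("mse"), "M")
  expect_identical(map_residue("SEP"), "S")
  expect_identical(map_residue("QQQ", table = c(QQQ = "W")), "W")
  # every mapped value stays inside the closed alphabet
  all_codes <- c(names(cellmatch:::.standard_aa),
                 names(cellmatch:::.modified_aa), "???", "AB")
  expect_true(all(map_residue(all_codes) %in% cellmatch:::.seq_alphabet))
})

test_that("TSV ingest validates per row and the last duplicate wins", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  hdr <- paste(c("entry_id", "organism", "method", "a", "b", "c", "alpha",
                 "beta", "gamma", "space_group", "r_work", "r_free",
                 "chains"), collapse = "\t")
  row <- function(id, sg = "P 1", a = "20") {
    paste(c(id, "org", "X-RAY", a, "25", "30", "85", "90", "95", sg,
            "0.2", "", "A:MKVL"), collapse = "\t")
  }
  writeLines(c(hdr, row("E001"), row("E002", sg = "Q9"),
               row("E003"), row("E001", a = "21")), tsv)
  warns <- capture_warnings(recs <- ingest_tsv(tsv))
  expect_match(warns, "unknown space group", all = FALSE)
  expect_match(warns, "last occurrence wins", all = FALSE)
  expect_setequal(recs$entry_id, c("E001", "E003"))
  expect_equal(recs$a[recs$entry_id == "E001"], 21)  # later row wins
  expect_true(all(is.na(recs$r_free)))
})

test_that("upsert replaces by id and recomputes the P1 cell; purge removes", {
  fx <- build_fixture_db(fixture_spec(seed = 41, n_groups = 1, n_decoys = 2),
                         dir = withr::local_tempdir())
  db <- db_build(ingest_tsv(fx$tsv))
  id <- db$entries$entry_id[1]
  rec <- db$entries[db$entries$entry_id == id, ]
  rec$a <- rec$a + 5
  p1_before <- rec$p1_a
  rec2 <- cellmatch:::make_entry(rec$entry_id, rec$organism, rec$method,
                                 c(rec$a, rec$b, rec$c, rec$alpha, rec$beta,
                                   rec$gamma),
                                 rec$space_group, rec$r_work, rec$r_free,
                                 rec$chains[[1]])
  db2 <- upsert_entry(db, rec2)
  expect_identical(nrow(db2$entries), nrow(db$entries))
  stored <- db2$entries[db2$entries$entry_id == id, ]
  expect_equal(stored$a, rec$a)
  expect_false(isTRUE(all.equal(stored$p1_a, p1_before)))

  db3 <- purge_entry(db2, id)
  expect_false(id %in% db3$entries$entry_id)
  expect_warning(purge_entry(db3, id), "nothing purged")
})

test_that("interleaved upserts and purges equal a naive last-write-wins map", {
  fx <- build_fixture_db(fixture_spec(seed = 43, n_groups = 2, n_decoys = 4),
                         dir = withr::local_tempdir())
  recs <- ingest_tsv(fx$tsv)
  withr::with_seed(43, {
    db <- db_new()
    alive <- character(0)
    for (step in 1:60) {
      i <- sample(nrow(recs), 1)
      id <- recs$entry_id[i]
      if (stats::runif(1) < 0.7 || !(id %in% alive)) {
        db <- upsert_entry(db, recs[i, ])
        alive <- union(alive, id)
      } else {
        db <- purge_entry(db, id)
        alive <- setdiff(alive, id)
      }
    }
    expect_setequal(db$entries$entry_id, alive)
  })
})

test_that("FASTA output wraps at 60 columns and round-trips through Biostrings", {
  long_seq <- paste(rep("ACDEFGHIKLMNPQRSTVWY", 8), collapse = "")  # 160 aa
  rec <- cellmatch:::make_entry(
    "9xyz", "Homo sapiens", "X-RAY", c(40, 50, 60, 90, 90, 90), "P 21 21 21",
    NA, NA, tibble::tibble(chain_id = c("A", "B"),
                           sequence = c(long_seq, "MKV"))
  )
  fa <- entry_fasta(rec)
  lines <- strsplit(fa, "\n")[[1]]
  expect_identical(lines[1], ">9xyz_A Homo sapiens")
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(fa, tmp)
  parsed <- Biostrings::readAAStringSet(tmp)
  expect_identical(names(parsed), c("9xyz_A Homo sapiens",
                                    "9xyz_B Homo sapiens"))
  expect_identical(as.character(parsed[[1]]), long_seq)
  expect_identical(as.character(parsed[[2]]), "MKV")

  rec$chains <- list(tibble::tibble(chain_id = character(),
                                    sequence = character()))
  expect_error(entry_fasta(rec), "no chains")
})

test_that("databases round-trip losslessly and byte-stably through JSON Lines", {
  fx <- build_fixture_db(fixture_spec(seed = 47, n_groups = 2, n_decoys = 5),
                         dir = withr::local_tempdir())
  db <- db_build(ingest_tsv(fx$tsv),
                 aliases = c("B1995" = "P 21 21 21"),
                 residue_table = c(QQQ = "W"))
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  db_save(db, p1)
  back <- db_load(p1)
  expect_identical(back$aliases, db$aliases)
  expect_identical(back$residue_table, db$residue_table)
  expect_equal(as.data.frame(back$entries), as.data.frame(db$entries),
               tolerance = 1e-12)
  db_save(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("corrupt or truncated database files are rejected whole", {
  fx <- build_fixture_db(fixture_spec(seed = 53, n_groups = 1, n_decoys = 2),
                         dir = withr::local_tempdir())
  db <- db_build(ingest_tsv(fx$tsv))
  path <- withr::local_tempfile(fileext = ".jsonl")
  db_save(db, path)
  lines <- readLines(path)
  trunc <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(lines[1:(length(lines) - 1)], trunc)
  expect_error(db_load(trunc), "truncated")
  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c("{\"format\":\"something-else\"}", lines[-1]), bad)
  expect_error(db_load(bad), "bad header")
  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_error(db_load(empty), "empty")
})

test_that("stored P1 cells recheck against reduce_to_p1 for every entry", {
  fx <- build_fixture_db(fixture_spec(seed = 59, n_groups = 3, n_decoys = 10),
                         dir = withr::local_tempdir())
  db <- db_build(ingest_tsv(fx$tsv))
  for (i in seq_len(nrow(db$entries))) {
    e <- db$entries[i, ]
    p1 <- reduce_to_p1(unit_cell(e$a, e$b, e$c, e$alpha, e$beta, e$gamma),
                       e$space_group)
    expect_equal(c(e$p1_a, e$p1_b, e$p1_c, e$p1_alpha, e$p1_beta, e$p1_gamma),
                 unname(unlist(p1$cell)), tolerance = 1e-6)
  }
})
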