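# Synthetic metadata dumps with known ground truth. The generator plants
# match groups (a parent cell plus near-copies constructed inside the match
# cutoff), optional distinct protein contents sharing one cell (different
# crystals, coincidentally similar lattices), and decoy cells constructed
# outside the cutoff, so scanning and family grouping can be checked
# against the planting exactly.

#' Specification for a synthetic fixture database
#'
#' Defaults describe a small protein-crystallography-like dump: a handful
#' of planted match groups across common Sohncke space groups, cell edges
#' in the 30-150 angstrom range, sub-0.1-angstrom perturbations for
#' within-cutoff copies, and sequence families at 95% intra-family
#' identity, far above the ~6% identity of unrelated random sequences.
#'
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   fixture files.
#' @param n_groups Number of planted match groups (distinct parent cells).
#' @param copies_per_content Entries per content family within a group
#'   (perturbed copies of the group's parent cell).
#' @param contents_per_group Distinct protein contents sharing each
#'   group's cell (1 = every member of the group is the same protein).
#' @param n_decoys Unrelated entries with cells outside every group's
#'   cutoff.
#' @param sg_palette Space-group symbols sampled for parents and decoys.
#' @param length_range,angle_range Ranges for free cell edges (angstroms)
#'   and free angles (degrees).
#' @param sigma_length,sigma_angle Gaussian jitter for within-cutoff copies
#'   (angstroms / degrees).
#' @param seq_length,chains_range Sequence length and per-entry chain count
#'   range.
#' @param intra_identity Within-family sequence identity of planted
#'   mutants.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_groups = 3L, copies_per_content = 5L,
                         contents_per_group = 1L, n_decoys = 30L,
                         sg_palette = c("P 1", "P 1 21 1", "C 1 2 1",
                                        "P 21 21 21", "P 41 21 2",
                                        "P 3 2 1", "R 3:H", "I 2 3"),
                         length_range = c(30, 150),
                         angle_range = c(75, 110),
                         sigma_length = 0.05, sigma_angle = 0.05,
                         seq_length = 120L, chains_range = c(1L, 2L),
                         intra_identity = 0.95) {
  stopifnot(n_groups >= 1L, copies_per_content >= 1L,
            contents_per_group >= 1L, n_decoys >= 0L,
            intra_identity > 0, intra_identity <= 1)
  structure(
    list(seed = as.integer(seed), n_groups = as.integer(n_groups),
         copies_per_content = as.integer(copies_per_content),
         contents_per_group = as.integer(contents_per_group),
         n_decoys = as.integer(n_decoys), sg_palette = sg_palette,
         length_range = length_range, angle_range = angle_range,
         sigma_length = sigma_length, sigma_angle = sigma_angle,
         seq_length = as.integer(seq_length),
         chains_range = as.integer(chains_range),
         intra_identity = intra_identity),
    class = "fixture_spec"
  )
}

crystal_system <- function(sg) {
  if (!inherits(sg, "space_group_info")) sg <- parse_space_group(sg)
  n <- sg$number
  if (n <= 2) "triclinic"
  else if (n <= 15) "monoclinic"
  else if (n <= 74) "orthorhombic"
  else if (n <= 142) "tetragonal"
  else if (n <= 194) {
    if (identical(sg$centering, "R_rhomb")) "rhombohedral" else "hexagonal"
  } else "cubic"
}

#' Draw a random cell consistent with a space group
#'
#' Samples cell parameters uniformly within the spec's ranges and then
#' imposes the metric constraints of the space group's crystal system
#' (e.g. tetragonal: a = b, all angles 90; rhombohedral setting:
#' a = b = c with one free angle), resampling until the cell validates.
#'
#' @param spec A [fixture_spec()] (only the ranges are used).
#' @param sg A `space_group_info` or symbol.
#' @return A valid `unit_cell`.
#' @export
synth_cell <- function(spec, sg) {
  if (!inherits(sg, "space_group_info")) sg <- parse_space_group(sg)
  system <- crystal_system(sg)
  lr <- spec$length_range; ar <- spec$angle_range
  repeat {
    len <- stats::runif(3, lr[1], lr[2])
    ang <- stats::runif(3, ar[1], ar[2])
    cand <- switch(system,
      triclinic    = c(len, ang),
      monoclinic   = c(len, 90, stats::runif(1, 91, 120), 90),
      orthorhombic = c(len, 90, 90, 90),
      tetragonal   = c(len[1], len[1], len[2], 90, 90, 90),
      hexagonal    = c(len[1], len[1], len[2], 90, 90, 120),
      rhombohedral = c(len[1], len[1], len[1], ang[1], ang[1], ang[1]),
      cubic        = c(len[1], len[1], len[1], 90, 90, 90)
    )
    cell <- tryCatch(as_unit_cell(cand), error = function(e) NULL)
    if (!is.null(cell)) return(cell)
  }
}

# free-parameter mask per crystal system: which of the six parameters may
# be jittered independently (constrained ones follow their partner)
perturb_mask <- function(system) {
  switch(system,
    triclinic    = list(len = 1:3, ang = 1:3, tie_len = NULL, tie_ang = NULL),
    monoclinic   = list(len = 1:3, ang = 2, tie_len = NULL, tie_ang = NULL),
    orthorhombic = list(len = 1:3, ang = NULL, tie_len = NULL, tie_ang = NULL),
    tetragonal   = list(len = c(1, 3), ang = NULL, tie_len = c(2, 1),
                        tie_ang = NULL),
    hexagonal    = list(len = c(1, 3), ang = NULL, tie_len = c(2, 1),
                        tie_ang = NULL),
    rhombohedral = list(len = 1, ang = 1, tie_len = rbind(c(2, 1), c(3, 1)),
                        tie_ang = rbind(c(2, 1), c(3, 1))),
    cubic        = list(len = 1, ang = NULL, tie_len = rbind(c(2, 1), c(3, 1)),
                        tie_ang = NULL)
  )
}

#' Jitter a cell to create a near-match
#'
#' Adds Gaussian noise to the cell's free parameters (free within the
#' crystal system of `sg`, so the jittered cell stays consistent with its
#' space-group symbol), resampling until the result validates. The true
#' perturbation applied is recorded in attribute `"perturbation"`.
#'
#' @param cell A valid `unit_cell`.
#' @param sigma_length,sigma_angle Standard deviations (angstroms,
#'   degrees).
#' @param sg Space group constraining which parameters are free; `NULL`
#'   treats the cell as triclinic (all six free).
#' @param seed Optional integer seed for a self-contained draw.
#' @return A valid `unit_cell` with attribute `"perturbation"`.
#' @export
perturb_cell <- function(cell, sigma_length, sigma_angle, sg = NULL,
                         seed = NULL) {
  draw <- function() {
    system <- if (is.null(sg)) "triclinic" else crystal_system(sg)
    mask <- perturb_mask(system)
    repeat {
      len <- c(cell$a, cell$b, cell$c)
      ang <- c(cell$alpha, cell$beta, cell$gamma)
      dlen <- numeric(3); dang <- numeric(3)
      if (length(mask$len)) {
        dlen[mask$len] <- stats::rnorm(length(mask$len), 0, sigma_length)
      }
      if (length(mask$ang)) {
        dang[mask$ang] <- stats::rnorm(length(mask$ang), 0, sigma_angle)
      }
      tie <- function(d, ties) {
        if (is.null(ties)) return(d)
        ties <- matrix(ties, ncol = 2)
        for (r in seq_len(nrow(ties))) d[ties[r, 1]] <- d[ties[r, 2]]
        d
      }
      dlen <- tie(dlen, mask$tie_len)
      dang <- tie(dang, mask$tie_ang)
      out <- tryCatch(
        as_unit_cell(c(len + dlen, ang + dang)),
        error = function(e) NULL
      )
      if (!is.null(out)) {
        attr(out, "perturbation") <- c(dlen, dang)
        return(out)
      }
    }
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a planted sequence family
#'
#' Draws a random parent sequence over the 20 standard amino acids, then
#' `n - 1` mutants each with exactly
#' `round((1 - intra_identity) * length)` substitutions at distinct random
#' positions (every substitution changes the letter), so pairwise identity
#' of parent and mutant equals `intra_identity` exactly.
#'
#' @param n Number of sequences (parent first).
#' @param length Sequence length.
#' @param intra_identity Target identity of each mutant to the parent.
#' @param seed Optional integer seed for a self-contained draw.
#' @return Character vector of `n` sequences.
#' @export
synth_sequence_family <- function(n, length, intra_identity, seed = NULL) {
  stopifnot(n >= 1, length >= 1, intra_identity > 0, intra_identity <= 1)
  aa <- unname(.standard_aa)
  draw <- function() {
    parent <- paste(sample(aa, length, replace = TRUE), collapse = "")
    k <- round((1 - intra_identity) * length)
    mutants <- vapply(seq_len(max(0, n - 1)), function(i) {
      ch <- strsplit(parent, "", fixed = TRUE)[[1]]
      if (k > 0) {
        pos <- sample.int(length, k)
        for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
      }
      paste(ch, collapse = "")
    }, character(1))
    c(parent, mutants)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Build a synthetic fixture database with ground truth
#'
#' Generates the TSV metadata dump for [ingest_tsv()] plus a JSON manifest
#' recording the planting: which entries are within-cutoff copies of which
#' parent cell, which content family each chain belongs to, and the true
#' reduced-cell RMSD of every copy to its parent. Copies are accepted only
#' if their reduced-cell RMSD to the parent is below 45% of the parent's
#' default cutoff, and decoys only if they are beyond twice the cutoff of
#' every parent, so the planted hit sets are recoverable exactly.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for the two output files.
#' @return Invisibly, a list with `tsv`, `manifest` (paths) and
#'   `ground_truth` (the manifest as a tibble).
#' @export
build_fixture_db <- function(spec, dir = tempdir(), basename = "fixture") {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, {
    res <- generate_fixture(spec)
  })
  tsv_path <- file.path(dir, paste0(basename, ".tsv"))
  manifest_path <- file.path(dir, paste0(basename, ".manifest.json"))
  write_fixture_tsv(res$rows, tsv_path)
  manifest <- list(
    format = "cellmatch-fixture-manifest", version = 1L,
    seed = spec$seed,
    entries = res$truth
  )
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, dataframe = "rows")),
             manifest_path)
  invisible(list(tsv = tsv_path, manifest = manifest_path,
                 ground_truth = tibble::as_tibble(res$truth)))
}

num_fmt <- function(x) sprintf("%.10g", x)

write_fixture_tsv <- function(rows, path) {
  hdr <- paste(c("entry_id", "organism", "method", "a", "b", "c",
                 "alpha", "beta", "gamma", "space_group",
                 "r_work", "r_free", "chains"), collapse = "\t")
  body <- vapply(rows, function(r) paste(r, collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
}

generate_fixture <- function(spec) {
  rows <- list(); truth <- list()
  parents <- list()
  seq_family_id <- 0L
  entry_counter <- 0L
  next_id <- function() {
    entry_counter <<- entry_counter + 1L
    sprintf("S%03d", entry_counter)
  }
  add_entry <- function(id, cell, sg, chains_tbl, role, group, content,
                        parent_id, rmsd_to_parent, within) {
    rows[[length(rows) + 1L]] <<- c(
      id, sprintf("synthetic organism %d", content), "X-RAY DIFFRACTION",
      num_fmt(cell$a), num_fmt(cell$b), num_fmt(cell$c),
      num_fmt(cell$alpha), num_fmt(cell$beta), num_fmt(cell$gamma),
      sg$symbol, num_fmt(round(stats::runif(1, 0.15, 0.25), 3)),
      num_fmt(round(stats::runif(1, 0.18, 0.30), 3)),
      paste(sprintf("%s:%s", chains_tbl$chain_id, chains_tbl$sequence),
            collapse = ";")
    )
    truth[[length(truth) + 1L]] <<- data.frame(
      entry_id = id, role = role, cell_group = group,
      content_family = content, parent_id = parent_id,
      rmsd_to_parent = rmsd_to_parent, within_cutoff = within,
      space_group = sg$symbol,
      n_chains = nrow(chains_tbl),
      conventional_volume = cell_volume(cell),
      primitive_volume = cell_volume(cell) / sg$multiplicity,
      multiplicity = sg$multiplicity,
      stringsAsFactors = FALSE
    )
  }

  # planted match groups: one parent cell each, mutually distant
  for (g in seq_len(spec$n_groups)) {
    sg <- parse_space_group(
      spec$sg_palette[(g - 1L) %% length(spec$sg_palette) + 1L]
    )
    repeat {
      parent_cell <- synth_cell(spec, sg)
      cutoff <- default_cutoff(parent_cell)
      far <- all(vapply(parents, function(p) {
        best_cell_rmsd(p$p1, reduce_to_p1(parent_cell, sg)$cell)$rmsd >
          2 * max(cutoff, p$cutoff)
      }, logical(1)))
      if (far) break
    }
    p1 <- reduce_to_p1(parent_cell, sg)$cell
    parents[[g]] <- list(cell = parent_cell, sg = sg, p1 = p1,
                         cutoff = cutoff)

    n_chains <- sample(seq(spec$chains_range[1], spec$chains_range[2]), 1)
    for (ct in seq_len(spec$contents_per_group)) {
      seq_family_id <- seq_family_id + 1L
      fam_seqs <- synth_sequence_family(
        spec$copies_per_content * n_chains, spec$seq_length,
        spec$intra_identity
      )
      for (cp in seq_len(spec$copies_per_content)) {
        is_parent_entry <- (ct == 1L && cp == 1L)
        if (is_parent_entry) {
          cell <- parent_cell; r <- 0
        } else {
          repeat {
            cell <- perturb_cell(parent_cell, spec$sigma_length,
                                 spec$sigma_angle, sg = sg)
            r <- best_cell_rmsd(p1, reduce_to_p1(cell, sg)$cell)$rmsd
            if (r < 0.45 * cutoff) break
          }
        }
        chains <- tibble::tibble(
          chain_id = LETTERS[seq_len(n_chains)],
          sequence = fam_seqs[((cp - 1L) * n_chains) + seq_len(n_chains)]
        )
        id <- next_id()
        add_entry(id, cell, sg, chains,
                  role = if (is_parent_entry) "parent" else "copy",
                  group = g, content = seq_family_id,
                  parent_id = if (is_parent_entry) NA_character_
                              else sprintf("S%03d",
                                           which_parent_entry(g, spec)),
                  rmsd_to_parent = r, within = TRUE)
      }
    }
  }

  # decoys: unrelated cells beyond twice every parent's cutoff
  for (d in seq_len(spec$n_decoys)) {
    sg <- parse_space_group(sample(spec$sg_palette, 1))
    repeat {
      cell <- synth_cell(spec, sg)
      dp1 <- reduce_to_p1(cell, sg)$cell
      far <- all(vapply(parents, function(p) {
        best_cell_rmsd(p$p1, dp1)$rmsd > 2 * p$cutoff
      }, logical(1)))
      if (far) break
    }
    seq_family_id <- seq_family_id + 1L
    n_chains <- sample(seq(spec$chains_range[1], spec$chains_range[2]), 1)
    seqs <- synth_sequence_family(n_chains, spec$seq_length, 1)
    chains <- tibble::tibble(chain_id = LETTERS[seq_len(n_chains)],
                             sequence = seqs)
    add_entry(next_id(), cell, sg, chains, role = "decoy",
              group = NA_integer_, content = seq_family_id,
              parent_id = NA_character_, rmsd_to_parent = NA_real_,
              within = FALSE)
  }

  list(rows = rows, truth = do.call(rbind, truth))
}

# entry counter value at which group g's parent entry was emitted
which_parent_entry <- function(g, spec) {
  per_group <- spec$contents_per_group * spec$copies_per_content
  (g - 1L) * per_group + 1L
}
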