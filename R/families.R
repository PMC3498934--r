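# Sequence-level grouping of cell-match hits. Chains of all hits are
# clustered greedily at a sequence-identity threshold; each hit's primitive
# P1 cell content is then a vector of cluster multiplicities
# (chains per asymmetric unit x primitive symmetry-operator count), and
# hits with identical vectors form one family, reported through the member
# with the smallest r.m.s. difference.

#' Clustering parameters
#'
#' @param identity_threshold Fraction of identical positions, relative to
#'   the shorter sequence, required to join a cluster. Default 0.90.
#' @return A list of class `clustering_params`.
#' @export
clustering_params <- function(identity_threshold = 0.90) {
  stopifnot(is.numeric(identity_threshold),
            identity_threshold > 0, identity_threshold <= 1)
  structure(list(identity_threshold = identity_threshold),
            class = "clustering_params")
}

#' Pairwise sequence identity over the shorter sequence
#'
#' Aligns two sequences globally (match +1, mismatch 0, affine gap open 10 /
#' extend 0.5 — the gap costs only shape the alignment) and returns the
#' number of identical aligned positions divided by the length of the
#' shorter sequence. Symmetric in its arguments.
#'
#' @param s1,s2 Non-empty amino-acid sequences (one-letter codes).
#' @return Identity fraction in \eqn{[0, 1]} (can exceed counting over the
#'   alignment length since the denominator is the shorter input length;
#'   capped at 1).
#' @export
pairwise_identity <- function(s1, s2) {
  if (!nzchar(s1) || !nzchar(s2)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  if (identical(s1, s2)) return(1)
  sub <- identity_submat()
  aln <- Biostrings::pairwiseAlignment(
    pattern = s1, subject = s2, type = "global",
    substitutionMatrix = sub, gapOpening = 10, gapExtension = 0.5,
    scoreOnly = FALSE
  )
  nid <- Biostrings::nmatch(aln)
  min(1, nid / min(nchar(s1), nchar(s2)))
}

identity_submat <- function() {
  m <- .cellmatch_env$submat
  if (is.null(m)) {
    letters <- c(.seq_alphabet, "*")
    m <- matrix(0, length(letters), length(letters),
                dimnames = list(letters, letters))
    diag(m) <- 1
    .cellmatch_env$submat <- m
  }
  m
}

#' Greedy incremental sequence clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted by length
#' descending (ties broken lexicographically by sequence, then by entry and
#' chain id); the first seeds cluster 1, and each subsequent sequence joins
#' the first existing cluster whose representative it matches at or above
#' the identity threshold, otherwise it seeds a new cluster. Fully
#' deterministic.
#'
#' @param sequences A data frame with columns `entry_id`, `chain_id`,
#'   `sequence` (one row per chain).
#' @param params A [clustering_params()].
#' @return A tibble with columns `cluster_id`, `entry_id`, `chain_id`,
#'   `sequence`, `is_representative`, `identity_to_representative`.
#' @export
greedy_cluster <- function(sequences, params = clustering_params()) {
  stopifnot(is.data.frame(sequences),
            all(c("entry_id", "chain_id", "sequence") %in% names(sequences)),
            nrow(sequences) >= 1L)
  ord <- order(-nchar(sequences$sequence), sequences$sequence,
               sequences$entry_id, sequences$chain_id, method = "radix")
  s <- sequences[ord, , drop = FALSE]
  reps <- character(0)
  assign <- integer(nrow(s))
  ident <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      idv <- pairwise_identity(reps[k], s$sequence[i])
      if (idv >= params$identity_threshold - 1e-12) {
        assign[i] <- k; ident[i] <- idv; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, s$sequence[i])
      assign[i] <- length(reps); ident[i] <- 1
    }
  }
  tibble::tibble(
    cluster_id = assign,
    entry_id = s$entry_id, chain_id = s$chain_id, sequence = s$sequence,
    is_representative = !duplicated(assign),
    identity_to_representative = ident
  )
}

#' Symmetry-scaled cluster composition of an entry
#'
#' Describes the content of an entry's primitive P1 cell as multiplicities
#' per sequence cluster: the number of the entry's chains in each cluster
#' times the primitive symmetry-operator count of its space group (the
#' asymmetric-unit content expanded to fill the primitive cell).
#'
#' @param record A one-row entry tibble (must carry `n_ops_primitive`).
#' @param clusters Output of [greedy_cluster()] covering all of the
#'   record's chains.
#' @return A named integer vector: names are cluster ids, values positive
#'   multiplicities.
#' @export
composition_vector <- function(record, clusters) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  mine <- clusters[clusters$entry_id == record$entry_id, , drop = FALSE]
  chains <- record$chains[[1]]
  missing <- setdiff(chains$chain_id, mine$chain_id)
  if (length(missing)) {
    stop(sprintf("chains of entry '%s' were not clustered: %s",
                 record$entry_id, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  counts <- table(mine$cluster_id)
  v <- as.integer(counts) * record$n_ops_primitive
  names(v) <- names(counts)
  v[order(as.integer(names(v)))]
}

composition_key <- function(v) {
  paste(sprintf("%s:%d", names(v), v), collapse = ";")
}

#' Group cell-match hits into families
#'
#' Clusters the chains of all hits with [greedy_cluster()] (recomputed per
#' query over the hit set only), computes each hit's symmetry-scaled
#' composition vector, and places two hits in the same family exactly when
#' their cluster composition and multiplicities match. Families are sorted
#' by their representative's RMSD ascending; the representative is the
#' member with the smallest RMSD (ties broken by entry id).
#'
#' @param hits A hit tibble from [scan_database()] (needs `entry_id`,
#'   `rmsd`, `n_ops_primitive`, `chains`, and metadata columns).
#' @param params A [clustering_params()].
#' @return A tibble of families: `family_id`, `representative`, `rmsd`
#'   (representative's), `space_group`, `organism`, `n_members`,
#'   `composition`, and a `members` list-column of per-hit tibbles sorted
#'   by RMSD. Also carries the chain clustering as attribute `"clusters"`.
#' @export
group_families <- function(hits, params = clustering_params()) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble::tibble(
      family_id = integer(), representative = character(), rmsd = numeric(),
      space_group = character(), organism = character(),
      n_members = integer(), composition = character(), members = list()
    ))
  }
  seqs <- tidyr::unnest(
    dplyr::select(hits, "entry_id", "chains"), "chains"
  )
  clusters <- greedy_cluster(seqs, params)
  keys <- vapply(seq_len(nrow(hits)), function(i) {
    composition_key(composition_vector(hits[i, ], clusters))
  }, character(1))
  hits$composition <- keys
  fam_list <- split(seq_len(nrow(hits)), keys)
  fams <- purrr::map(fam_list, function(idx) {
    m <- hits[idx, , drop = FALSE]
    m <- dplyr::arrange(m, .data$rmsd, .data$entry_id)
    rep <- m[1, ]
    tibble::tibble(
      representative = rep$entry_id, rmsd = rep$rmsd,
      space_group = rep$space_group, organism = rep$organism,
      n_members = nrow(m), composition = rep$composition,
      members = list(dplyr::select(m, "entry_id", "rmsd", "space_group",
                                   "organism", "composition"))
    )
  })
  out <- dplyr::bind_rows(fams)
  out <- dplyr::arrange(out, .data$rmsd, .data$representative)
  out <- dplyr::mutate(out, family_id = dplyr::row_number(),
                       .before = 1)
  attr(out, "clusters") <- clusters
  out
}
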