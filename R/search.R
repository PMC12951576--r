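# Orchestration of one- and two-vector searches of a library against a query,
# and the ranked CSV/SDF output.

prepare_query <- function(query, seed, charges = NULL) {
  het <- parse_heterocycle(query)
  conf <- embed_conformer(het, seed = seed)
  if (is.null(charges)) {
    conf <- assign_partial_charges(conf, "gasteiger")
  } else {
    conf <- assign_partial_charges(conf, "external", charges = charges)
  }
  conf
}

validate_query_vector <- function(qev, vector_atom) {
  hit <- qev[qev$ring_atom == vector_atom, , drop = FALSE]
  if (nrow(hit) != 1) {
    rlang::abort(
      sprintf(
        "atom %d is not an exit-vector (aromatic C-H/N-H); valid atoms: %s",
        vector_atom, paste(qev$ring_atom, collapse = ", ")
      ),
      class = "ringhop_input_error"
    )
  }
  hit
}

library_conformers <- function(lib, seed) {
  confs <- embed_conformers(lib$smiles, seed = seed)
  names(confs) <- as.character(lib$reg_id)
  for (k in seq_along(confs)) {
    if (!is.null(confs[[k]])) {
      confs[[k]] <- assign_partial_charges(confs[[k]], "gasteiger")
    }
  }
  confs
}

finalize_results <- function(rows, query_conf, descriptors) {
  res <- dplyr::bind_rows(rows)
  res <- dplyr::arrange(res, dplyr::desc(.data$total), .data$reg_id)
  res$rank <- seq_len(nrow(res))
  res$is_query <- res$smiles == query_conf$smiles
  if (descriptors && nrow(res)) {
    qd <- fragment_descriptors(query_conf$smiles)
    pd <- fragment_descriptors(res$smiles)
    res$mw <- pd$mw; res$clogp <- pd$clogp; res$tpsa <- pd$tpsa
    res$hba <- pd$hba; res$hbd <- pd$hbd
    res$d_mw <- pd$mw - qd$mw
    res$d_clogp <- pd$clogp - qd$clogp
    res$d_tpsa <- pd$tpsa - qd$tpsa
    res$d_hba <- pd$hba - qd$hba
    res$d_hbd <- pd$hbd - qd$hbd
  }
  front <- intersect(
    c("rank", "reg_id", "smiles", "total", "shape", "esp", "esp_raw",
      "d", "alpha_v", "flip", "rmsd", "is_query",
      "mw", "clogp", "tpsa", "hba", "hbd",
      "d_mw", "d_clogp", "d_tpsa", "d_hba", "d_hbd"),
    names(res)
  )
  res <- res[, c(front, setdiff(names(res), front))]
  structure(res, class = c("ringhop_results", class(res)),
            query = query_conf$smiles)
}

#' One-vector bioisostere search
#'
#' Aligns every exit-vector of every retained library molecule onto the
#' designated query exit-vector, in both flip states, scores each alignment
#' for shape and electrostatic similarity, and keeps the best-scoring
#' alignment per molecule. Results are ranked by descending weighted total
#' score (ties broken by ascending RegID).
#'
#' @param library A `ringhop_library` tibble (only retained entries are
#'   searched).
#' @param query Query SMILES string.
#' @param vector_atom Atom index (in the query SMILES heavy-atom order) of
#'   the exit-vector ring atom.
#' @param w_shape,w_esp Score weights (default 1, 1; totals then span 0-2).
#' @param seed Conformer embedding seed.
#' @param charges Optional external per-atom charges for the query.
#' @param descriptors Attach physicochemical descriptors and deltas
#'   (default `TRUE`).
#' @return A `ringhop_results` tibble: one row per scored library entry with
#'   `rank`, `reg_id`, `smiles`, `total`, `shape`, `esp`, `esp_raw`, `flip`,
#'   `rmsd`, `is_query`, descriptor columns, and the best-aligned conformer
#'   in the `conformer` list column.
#' @export
search_one_vector <- function(library, query, vector_atom,
                              w_shape = 1, w_esp = 1, seed = 42L,
                              charges = NULL, descriptors = TRUE) {
  if (any(c(w_shape, w_esp) < 0)) {
    rlang::abort("weights must be nonnegative", class = "ringhop_config_error")
  }
  qconf <- prepare_query(query, seed, charges)
  qvec <- validate_query_vector(enumerate_exit_vectors(qconf), vector_atom)
  lib <- library[library$retained, , drop = FALSE]
  confs <- library_conformers(lib, seed)
  qprep <- prepare_query_scoring(qconf)

  rows <- list()
  for (k in seq_len(nrow(lib))) {
    probe <- confs[[as.character(lib$reg_id[k])]]
    if (is.null(probe)) next
    ev <- enumerate_exit_vectors(probe)
    if (nrow(ev) == 0) next
    best <- NULL
    for (v in seq_len(nrow(ev))) {
      for (flip in c(FALSE, TRUE)) {
        al <- align_one_vector(qconf, qvec, probe, ev[v, ], flip = flip)
        sc <- score_alignment(qprep, probe, al, w_shape, w_esp)
        if (is.null(best) || sc$total > best$score$total) {
          best <- list(score = sc, alignment = al)
        }
      }
    }
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(reg_id = lib$reg_id[k], smiles = lib$smiles[k]),
      best$score,
      tibble::tibble(
        flip = best$alignment$flip,
        rmsd = best$alignment$rmsd,
        conformer = list(apply_alignment(probe, best$alignment))
      )
    )
  }
  finalize_results(rows, qconf, descriptors)
}

#' Two-vector bioisostere search
#'
#' Hashes the geometry (ring-atom distance, bond-vector angle) of the
#' designated query exit-vector pair and aligns only library exit-vector
#' pairs stored under the same hash, in both pair orders. The best alignment
#' per molecule is kept and results are ranked by total score.
#'
#' @inheritParams search_one_vector
#' @param vector_atoms Integer vector of length 2: the two exit-vector ring
#'   atoms of the query.
#' @param index Optional precomputed [build_hash_index()]; built on the fly
#'   when `NULL`.
#' @param n_dist_bins,n_angle_bins,dist_range Hash binning configuration
#'   (used when building the index here; ignored if `index` is supplied).
#' @return A `ringhop_results` tibble; `d` and `alpha_v` give each probe
#'   pair's geometry.
#' @export
search_two_vector <- function(library, query, vector_atoms,
                              index = NULL, w_shape = 1, w_esp = 1,
                              seed = 42L, charges = NULL, descriptors = TRUE,
                              n_dist_bins = 18L, n_angle_bins = 6L,
                              dist_range = c(1.2, 7.5)) {
  stopifnot(length(vector_atoms) == 2)
  qconf <- prepare_query(query, seed, charges)
  qev <- enumerate_exit_vectors(qconf)
  qpair <- dplyr::bind_rows(
    validate_query_vector(qev, vector_atoms[1]),
    validate_query_vector(qev, vector_atoms[2])
  )
  lib <- library[library$retained, , drop = FALSE]
  confs <- library_conformers(lib, seed)
  if (is.null(index)) {
    index <- build_hash_index(library, conformers = confs, seed = seed,
                              n_dist_bins = n_dist_bins,
                              n_angle_bins = n_angle_bins,
                              dist_range = dist_range)
  }
  cfg <- attr(index, "config")
  qgeom <- vector_pair_geometry(qconf, qpair, cfg$n_dist_bins,
                                cfg$n_angle_bins, cfg$dist_range)
  bucket <- lookup_hash(index, qgeom$hash)
  qprep <- prepare_query_scoring(qconf)

  rows <- list()
  for (rid in unique(bucket$reg_id)) {
    probe <- confs[[as.character(rid)]]
    if (is.null(probe)) next
    cand <- bucket[bucket$reg_id == rid, , drop = FALSE]
    best <- NULL
    for (c_i in seq_len(nrow(cand))) {
      ppair <- tibble::tibble(
        ring_atom = c(cand$atom_1[c_i], cand$atom_2[c_i]),
        h_atom = c(cand$h_1[c_i], cand$h_2[c_i])
      )
      for (ord in c(FALSE, TRUE)) {
        al <- align_two_vector(qconf, qpair, probe, ppair, order = ord)
        sc <- score_alignment(qprep, probe, al, w_shape, w_esp)
        if (is.null(best) || sc$total > best$score$total) {
          best <- list(score = sc, alignment = al,
                       d = cand$d[c_i], alpha_v = cand$alpha_v[c_i])
        }
      }
    }
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(
        reg_id = rid,
        smiles = lib$smiles[match(rid, lib$reg_id)]
      ),
      best$score,
      tibble::tibble(
        d = best$d, alpha_v = best$alpha_v,
        flip = best$alignment$flip, rmsd = best$alignment$rmsd,
        conformer = list(apply_alignment(probe, best$alignment))
      )
    )
  }
  finalize_results(rows, qconf, descriptors)
}

#' Write ranked search results to CSV and SDF
#'
#' The CSV holds the full ranked table (without the conformer list column);
#' the SDF holds the `min(top_n, nrow(results))` highest-ranked molecules in
#' their best-aligned coordinates, with score fields attached as SDF data
#' items.
#'
#' @param results A `ringhop_results` tibble.
#' @param dir Output directory (created if absent).
#' @param top_n Number of molecules exported to the SDF (default 50).
#' @return Invisibly, a list with the `csv` and `sdf` paths.
#' @export
write_results <- function(results, dir, top_n = 50L) {
  if (nrow(results) == 0) {
    rlang::abort("no results to write", class = "ringhop_io_error")
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create ", dir), class = "ringhop_io_error")
  }
  csv_path <- file.path(dir, "results.csv")
  sdf_path <- file.path(dir, "results.sdf")
  flat <- results[, !vapply(results, is.list, TRUE), drop = FALSE]
  readr::write_csv(flat, csv_path)

  n_sdf <- min(top_n, nrow(results))
  blocks <- character(n_sdf)
  for (k in seq_len(n_sdf)) {
    conf <- results$conformer[[k]]
    conf$name <- as.character(results$reg_id[k])
    sdf <- mol2_to_sdf(write_mol2(conf))
    props <- sprintf(
      "> <smiles>\n%s\n\n> <rank>\n%d\n\n> <total>\n%.6f\n\n> <shape>\n%.6f\n\n> <esp>\n%.6f\n",
      results$smiles[k], results$rank[k], results$total[k],
      results$shape[k], results$esp[k]
    )
    blocks[k] <- sub("\\$\\$\\$\\$", paste0(props, "\n$$$$"), sdf)
  }
  writeLines(paste(blocks, collapse = ""), sdf_path, sep = "")
  invisible(list(csv = csv_path, sdf = sdf_path))
}
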