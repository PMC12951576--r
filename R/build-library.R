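#' Build a searchable heterocycle library
#'
#' Runs the full enumeration and filter pipeline: seed parsing, optional
#' mono- and bifunctionalization, global canonical-SMILES deduplication, the
#' nine-rule stability (PEB) filter, removal of molecules with no remaining
#' exit-vectors, and removal of molecules that pucker out of plane after 3D
#' embedding. RegIDs are assigned sequentially over the deduplicated
#' enumeration in canonical-SMILES sort order, so they are stable across
#' runs.
#'
#' @param seeds Character vector of seed SMILES.
#' @param subs Substituent set, see [default_substituents()].
#' @param functionalize One of `"bi"` (seeds + mono + bi, the default),
#'   `"mono"` (seeds + mono) or `"none"` (seeds only).
#' @param planarity_threshold Maximum out-of-plane deviation (Angstrom)
#'   tolerated by the planarity filter.
#' @param seed Integer seed recorded with embedded conformers.
#' @return A tibble of class `ringhop_library` with one row per unique
#'   enumerated molecule: `reg_id`, `smiles`, `generation` (`seed`/`mono`/
#'   `bi`), `exit_vector_count`, `filter_flags` (list column of violated rule
#'   ids), `retained`. Per-stage counts are stored in
#'   `attr(x, "stage_counts")`. Molecules whose SMILES fail to parse are
#'   skipped with a warning.
#' @export
build_library <- function(seeds, subs = default_substituents(),
                          functionalize = c("bi", "mono", "none"),
                          planarity_threshold = 0.3, seed = 42L) {
  functionalize <- match.arg(functionalize)
  empty <- tibble::tibble(
    reg_id = integer(), smiles = character(), generation = character(),
    exit_vector_count = integer(), filter_flags = list(), retained = logical()
  )
  if (length(seeds) == 0) {
    return(structure(empty, class = c("ringhop_library", class(empty)),
                     stage_counts = NULL))
  }
  validate_substituent_set(subs)

  hets <- list()
  skipped <- 0L
  for (s in seeds) {
    h <- tryCatch(parse_heterocycle(s, library_mode = TRUE),
                  error = function(e) NULL)
    if (is.null(h)) skipped <- skipped + 1L else hets[[length(hets) + 1]] <- h
  }
  if (skipped > 0) {
    rlang::warn(sprintf("%d seed SMILES failed to parse and were skipped", skipped))
  }
  seed_smiles <- unique(vapply(hets, `[[`, "", "smiles"))

  mono_smiles <- character()
  bi_smiles <- character()
  if (functionalize %in% c("mono", "bi")) {
    mono <- dplyr::bind_rows(purrr::map(hets, monofunctionalize, subs = subs))
    mono <- dplyr::distinct(mono, .data$smiles, .keep_all = TRUE)
    mono_smiles <- setdiff(mono$smiles, seed_smiles)
    if (functionalize == "bi" && length(mono_smiles)) {
      bi <- bifunctionalize(mono_smiles, subs = subs,
                            exclude = c(seed_smiles, mono_smiles))
      bi_smiles <- bi$smiles
    }
  }

  entries <- tibble::tibble(
    smiles = c(seed_smiles, mono_smiles, bi_smiles),
    generation = c(
      rep("seed", length(seed_smiles)),
      rep("mono", length(mono_smiles)),
      rep("bi", length(bi_smiles))
    )
  )
  entries <- dplyr::distinct(entries, .data$smiles, .keep_all = TRUE)
  entries <- dplyr::arrange(entries, .data$smiles)
  entries$reg_id <- seq_len(nrow(entries))

  parsed <- purrr::map(entries$smiles, parse_heterocycle)
  entries$exit_vector_count <-
    vapply(parsed, function(h) nrow(enumerate_exit_vectors(h)), integer(1))
  peb <- purrr::map(parsed, peb_filter)
  entries$filter_flags <- purrr::map(peb, "violated")
  peb_ok <- vapply(peb, "[[", TRUE, "retain")
  ev_ok <- entries$exit_vector_count >= 1

  # planarity is only checked where the cheaper filters pass
  flat_ok <- rep(TRUE, nrow(entries))
  need3d <- which(peb_ok & ev_ok)
  if (length(need3d)) {
    confs <- embed_conformers(entries$smiles[need3d], seed = seed)
    for (k in seq_along(need3d)) {
      i <- need3d[k]
      flat_ok[i] <- !is.null(confs[[k]]) &&
        planarity_check(confs[[k]], threshold = planarity_threshold)
      if (!flat_ok[i]) {
        entries$filter_flags[[i]] <- c(entries$filter_flags[[i]], "not_flat")
      }
    }
  }
  if (any(!ev_ok)) {
    for (i in which(!ev_ok)) {
      entries$filter_flags[[i]] <- c(entries$filter_flags[[i]], "no_exit_vector")
    }
  }
  entries$retained <- peb_ok & ev_ok & flat_ok

  stage_counts <- entries |>
    dplyr::group_by(.data$generation) |>
    dplyr::summarise(
      enumerated = dplyr::n(),
      without_exit_vectors = sum(.data$exit_vector_count < 1),
      peb = sum(!vapply(.data$filter_flags, function(f)
        length(setdiff(f, c("not_flat", "no_exit_vector"))) == 0, TRUE)),
      not_flat = sum(vapply(.data$filter_flags, function(f) "not_flat" %in% f, TRUE)),
      remaining = sum(.data$retained),
      .groups = "drop"
    )

  out <- entries[, c("reg_id", "smiles", "generation", "exit_vector_count",
                     "filter_flags", "retained")]
  structure(out, class = c("ringhop_library", class(out)),
            stage_counts = stage_counts)
}

#' @export
print.ringhop_library <- function(x, ...) {
  cat("# A ringhop library:", nrow(x), "enumerated,", sum(x$retained),
      "retained\n")
  sc <- attr(x, "stage_counts")
  if (!is.null(sc)) print(sc)
  NextMethod()
}

#' Per-stage counts of a built library
#'
#' @param library A `ringhop_library` tibble from [build_library()].
#' @return A tibble with one row per generation and columns `enumerated`,
#'   `without_exit_vectors`, `peb`, `not_flat`, `remaining`.
#' @export
library_stage_counts <- function(library) {
  attr(library, "stage_counts")
}

#' Write / read a library as a tab-separated SMILES file
#'
#' Columns: `smiles`, `reg_id`, `generation` (plus `retained`).
#'
#' @param library A `ringhop_library` tibble.
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   the library tibble.
#' @export
write_library <- function(library, path) {
  readr::write_tsv(
    library[, c("smiles", "reg_id", "generation", "retained")], path
  )
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  x$filter_flags <- replicate(nrow(x), character(), simplify = FALSE)
  x$exit_vector_count <- vapply(
    x$smiles,
    function(s) nrow(enumerate_exit_vectors(parse_heterocycle(s))),
    integer(1), USE.NAMES = FALSE
  )
  x <- x[, c("reg_id", "smiles", "generation", "exit_vector_count",
             "filter_flags", "retained")]
  structure(tibble::as_tibble(x),
            class = c("ringhop_library", class(tibble::tibble())),
            stage_counts = NULL)
}

# Template catalogue backing fixture_library(): common mono- and bicyclic
# aromatic heterocycles (annular tautomers listed separately), all within
# {C,N,O,S,H}.
.fixture_catalogue <- c(
  "c1ccccc1",            # benzene
  "c1ccncc1",            # pyridine
  "c1ccnnc1",            # pyridazine
  "c1cncnc1",            # pyrimidine
  "c1cnccn1",            # pyrazine
  "c1ncncn1",            # 1,3,5-triazine
  "c1ccoc1",             # furan
  "c1ccsc1",             # thiophene
  "c1cc[nH]c1",          # pyrrole
  "c1cnco1",             # oxazole
  "c1ccsn1",             # isothiazole
  "c1cncs1",             # thiazole
  "c1cc[nH]n1",          # pyrazole
  "c1c[nH]cn1",          # imidazole
  "c1conc1",             # isoxazole
  "c1nc[nH]n1",          # 1,2,4-triazole (1H)
  "c1c[nH]nn1",          # 1,2,3-triazole (1H)
  "c1cn[nH]n1",          # 1,2,3-triazole (2H)
  "c1nnn[nH]1",          # tetrazole (1H)
  "c1nn[nH]n1",          # tetrazole (2H)
  "c1ocnn1",             # 1,3,4-oxadiazole
  "c1scnn1",             # 1,3,4-thiadiazole
  "c1cnon1",             # 1,2,5-type oxadiazole
  "c1ccc2ccccc2c1",      # naphthalene
  "c1ccc2[nH]ccc2c1",    # indole
  "c1ccc2occc2c1",       # benzofuran
  "c1ccc2sccc2c1",       # benzothiophene
  "c1ccc2[nH]ncc2c1",    # indazole (1H)
  "c1ccc2[nH]cnc2c1",    # benzimidazole
  "c1ccc2ocnc2c1",       # benzoxazole
  "c1ccc2scnc2c1",       # benzothiazole
  "c1ccc2ncccc2c1",      # quinoline
  "c1ccc2cnccc2c1",      # isoquinoline
  "c1ccc2ncncc2c1",      # quinazoline
  "c1ccc2nccnc2c1",      # quinoxaline
  "c1ccc2nnccc2c1",      # cinnoline
  "c1cnc2[nH]cnc2n1",    # purine (9H)
  "c1nc2nc[nH]c2cn1",    # purine (7H-type tautomer)
  "c1ncc2cc[nH]c2n1",    # 7-deazapurine
  "c1ccn2ccnc2c1",       # imidazo[1,2-a]pyridine
  "c1ccn2cccc2c1",       # indolizine
  "c1ccn2cncc2c1",       # imidazo[1,5-a]pyridine
  "c1ccn2nccc2c1",       # pyrazolo[1,5-a]pyridine
  "c1ccn2nccc2n1",       # pyrazolo[1,5-a]pyrimidine
  "c1cc2ccnn2cn1",       # pyrazolo[1,5-a]pyrimidine isomer
  "c1cc2nc[nH]c2cn1",    # imidazopyridine tautomer
  "c1cc2[nH]ncc2cn1",    # pyrazolopyridine
  "c1cc2cc[nH]c2cn1",    # pyrrolopyridine (7-azaindole type)
  "c1cc2[nH]ccc2cn1",    # pyrrolopyridine isomer
  "c1cnc2ccsc2c1",       # thienopyridine
  "c1cnc2ccoc2c1",       # furopyridine
  "c1cnc2cc[nH]c2c1",    # pyrrolopyridine isomer
  "c1cnc2ncccc2n1",      # naphthyridine-type diazine
  "c1cc2nccn2cn1",       # imidazo[1,2-a]pyrimidine
  "c1cn2ccnc2cn1",       # imidazo-pyrazine
  "c1cn2cnnc2cn1",       # triazolo-pyrazine
  "c1nn2ccnc2cn1",       # triazolo-pyrimidine isomer
  "c1cc2[nH]nnc2cn1",    # triazolopyridine tautomer
  "c1oc2ccoc2c1",        # furofuran 5,5-bicycle
  "c1sc2ccsc2c1",        # thienothiophene 5,5-bicycle
  "c1oc2ccsc2c1",        # thienofuran
  "c1cc2[nH]ccc2o1",     # furopyrrole-type 5,5-bicycle
  "c1cc2[nH]ccc2s1",     # thienopyrrole-type 5,5-bicycle
  "c1cc2cc[nH]c2[nH]1",  # dipyrrole-type 5,5-bicycle
  "c1cn2nccc2s1",        # pyrazolo-thiazole 5,5-bicycle
  "c1cn2cccc2o1"         # oxazolo-pyrrole-type 5,5-bicycle
)

#' Deterministic fixture library of common aromatic heterocycles
#'
#' Samples `n` distinct SMILES from a built-in catalogue of mono- and
#' bicyclic aromatic heterocycles. Intended as a self-contained stand-in for
#' an external seed collection in examples and tests.
#'
#' @param n Number of molecules (at most the catalogue size).
#' @param seed Integer seed; the same `(n, seed)` always returns the same
#'   list.
#' @return Character vector of `n` unique canonical SMILES.
#' @export
fixture_library <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  cat_can <- unique(canonical_smiles(.fixture_catalogue))
  if (n > length(cat_can)) {
    rlang::abort(
      sprintf("fixture catalogue holds %d molecules; %d requested",
              length(cat_can), n),
      class = "ringhop_size_error"
    )
  }
  withr::with_seed(seed, sample(cat_can, n))
}
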