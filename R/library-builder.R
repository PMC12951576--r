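# Virtual library enumeration: systematic functionalization of seed
# heterocycles at their exit-vectors, canonical-SMILES deduplication, and the
# stability/exit-vector/planarity filter cascade.

# Internal: all products of attaching every compatible substituent at every
# exit-vector of one parsed heterocycle. Returns a tibble (possibly with
# duplicate canonical SMILES; callers deduplicate at their own scope).
functionalize_once <- function(het, subs) {
  ev <- enumerate_exit_vectors(het)
  if (nrow(ev) == 0) {
    return(tibble::tibble(
      smiles = character(), parent = character(),
      ring_atom = integer(), element_class = character(), substituent = character()
    ))
  }
  mol2_blocks <- character()
  meta <- list()
  for (k in seq_len(nrow(ev))) {
    set <- if (ev$element_class[k] == "C") subs$c_substituents else subs$n_substituents
    for (nm in names(set)) {
      prod <- attach_substituent(het, ev$h_atom[k], set[[nm]])
      mol2_blocks <- c(mol2_blocks, write_mol2(prod))
      meta[[length(meta) + 1]] <- tibble::tibble(
        parent = het$smiles, ring_atom = ev$ring_atom[k],
        element_class = ev$element_class[k], substituent = nm
      )
    }
  }
  out <- ChemmineOB::convertFormat("MOL2", "CAN", paste(mol2_blocks, collapse = ""),
                                   options = ob_options())
  can <- strsplit(out, "\n", fixed = TRUE)[[1]]
  can <- trimws(sub("\t.*$", "", can))
  can <- can[nzchar(can)]
  if (length(can) != length(meta)) {
    rlang::abort("substituent attachment produced an unparseable product",
      class = "ringhop_config_error"
    )
  }
  dplyr::bind_cols(tibble::tibble(smiles = can), dplyr::bind_rows(meta))
}

#' Monofunctionalize a heterocycle
#'
#' Attaches every compatible substituent at every exit-vector: carbon
#' substituents at aromatic C-H positions and nitrogen substituents at
#' pyrrole-like N-H positions. Symmetry-equivalent products collapse to a
#' single entry via canonical-SMILES deduplication.
#'
#' @param het A `heterocycle` object or SMILES string.
#' @param subs A substituent set as returned by [default_substituents()].
#' @return A tibble of unique products with columns `smiles`, `parent`,
#'   `ring_atom`, `element_class`, `substituent` (first attachment route
#'   kept for each product).
#' @examples
#' \donttest{
#' nrow(monofunctionalize("c1ccc2[nH]ccc2c1"))  # 44 for indole
#' }
#' @export
monofunctionalize <- function(het, subs = default_substituents()) {
  if (is.character(het)) het <- parse_heterocycle(het, library_mode = TRUE)
  validate_substituent_set(subs)
  prods <- functionalize_once(het, subs)
  dplyr::distinct(prods, .data$smiles, .keep_all = TRUE)
}

#' Bifunctionalize a set of monofunctionalized heterocycles
#'
#' Repeats the functionalization step on each monofunctionalized molecule at
#' its remaining exit-vectors (the substituted position has consumed its
#' hydrogen and is no longer available). Products are deduplicated globally
#' and against the supplied exclusion set, so a disubstituted molecule
#' reachable through two addition orders appears once.
#'
#' @param monos Character vector of monofunctionalized SMILES.
#' @param subs A substituent set as returned by [default_substituents()].
#' @param exclude Canonical SMILES to drop from the output (typically the
#'   seeds and the monofunctionalized set).
#' @return A tibble of unique products (`smiles`, `parent`, ...).
#' @export
bifunctionalize <- function(monos, subs = default_substituents(),
                            exclude = character()) {
  if (length(monos) == 0) {
    rlang::abort("bifunctionalize needs at least one input molecule",
      class = "ringhop_config_error"
    )
  }
  validate_substituent_set(subs)
  prods <- purrr::map(monos, function(s) {
    # products may carry halogen substituents; the seed-only element rule
    # does not apply here
    het <- parse_heterocycle(s)
    functionalize_once(het, subs)
  })
  prods <- dplyr::bind_rows(prods)
  prods <- dplyr::distinct(prods, .data$smiles, .keep_all = TRUE)
  dplyr::filter(prods, !.data$smiles %in% exclude)
}
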