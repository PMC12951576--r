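#' Fragment-level physicochemical descriptors
#'
#' Molecular weight, atom-contribution log P, topological polar surface area
#' and hydrogen-bond donor/acceptor counts (OpenBabel implementations of the
#' standard fragment-contribution methods), plus the heavy-atom elemental
#' composition.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with one row per input: `smiles`, `mw`, `clogp`, `tpsa`,
#'   `hba`, `hbd`, `composition` (list column of named element counts).
#' @export
fragment_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  rows <- purrr::map(smiles, function(s) {
    het <- parse_heterocycle(s, require_aromatic = FALSE)
    props <- ChemmineOB::forEachMol("SMILES", s, function(x) {
      ChemmineOB::prop_OB(list(x))
    })[[1]]
    heavy <- het$atoms$element[het$atoms$element != "H"]
    tibble::tibble(
      smiles = s,
      mw = as.numeric(props$MW),
      clogp = as.numeric(props$logP),
      tpsa = as.numeric(props$TPSA),
      hba = as.integer(props$HBA2),
      hbd = as.integer(props$HBD),
      composition = list(table(heavy))
    )
  })
  dplyr::bind_rows(rows)
}

#' Physicochemical property shift of a replacement
#'
#' Differences (probe minus query) in the numeric fragment descriptors: the
#' property change incurred by swapping the query heterocycle for the probe
#' within a parent molecule.
#'
#' @param query,probe SMILES strings.
#' @return A one-row tibble with `d_mw`, `d_clogp`, `d_tpsa`, `d_hba`,
#'   `d_hbd`.
#' @export
delta_profile <- function(query, probe) {
  q <- fragment_descriptors(query)
  p <- fragment_descriptors(probe)
  tibble::tibble(
    d_mw = p$mw - q$mw,
    d_clogp = p$clogp - q$clogp,
    d_tpsa = p$tpsa - q$tpsa,
    d_hba = p$hba - q$hba,
    d_hbd = p$hbd - q$hbd
  )
}
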