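#' Parse an aromatic heterocycle from SMILES
#'
#' Parses and sanitizes a SMILES string, perceives aromaticity, and returns a
#' `heterocycle` object holding the canonical SMILES and the hydrogen-explicit
#' molecular graph. Atom indices in the graph follow the heavy-atom order of
#' the *input* SMILES (hydrogens appended), so exit-vector atom indices given
#' by a user refer to their own input.
#'
#' @param smiles A single SMILES string.
#' @param reg_id Optional integer registry identifier (RegID).
#' @param library_mode If `TRUE`, restrict elements to C, N, O, S, H (the
#'   composition of the searchable library); other elements raise an error.
#' @param require_aromatic If `TRUE` (default) the molecule must contain at
#'   least one aromatic ring.
#' @return An object of class `heterocycle`: a list with elements `smiles`
#'   (canonical), `input_smiles`, `reg_id`, `atoms`, `bonds`, `aromatic`
#'   (logical per atom) and `formal_charge`.
#' @examples
#' \donttest{
#' het <- parse_heterocycle("c1ccncc1")
#' het$smiles
#' }
#' @export
parse_heterocycle <- function(smiles, reg_id = NA_integer_,
                              library_mode = FALSE, require_aromatic = TRUE) {
  if (!smiles_lexical_ok(smiles)) {
    rlang::abort(
      paste0("cannot parse SMILES: ", deparse(smiles)),
      class = "ringhop_parse_error"
    )
  }
  can <- canonical_smiles(smiles)
  if (is.na(can)) {
    rlang::abort(
      paste0("cannot parse SMILES: ", deparse(smiles)),
      class = "ringhop_parse_error"
    )
  }
  graph <- smiles_to_graph(smiles)
  if (is.null(graph)) {
    rlang::abort(
      paste0("cannot parse SMILES: ", deparse(smiles)),
      class = "ringhop_parse_error"
    )
  }
  aromatic <- mol_aromatic_atoms(graph)
  if (require_aromatic && !any(aromatic)) {
    rlang::abort(
      paste0("no aromatic ring in ", smiles),
      class = "ringhop_parse_error"
    )
  }
  if (library_mode) {
    bad <- setdiff(unique(graph$atoms$element), c("C", "N", "O", "S", "H"))
    if (length(bad)) {
      rlang::abort(
        paste0(
          "library molecules may contain only C, N, O, S, H; found ",
          paste(bad, collapse = ", "), " in ", smiles
        ),
        class = "ringhop_element_error"
      )
    }
  }
  structure(
    list(
      smiles = can,
      input_smiles = smiles,
      reg_id = as.integer(reg_id),
      atoms = graph$atoms,
      bonds = graph$bonds,
      aromatic = aromatic,
      formal_charge = smiles_formal_charge(smiles)
    ),
    class = "heterocycle"
  )
}

#' @export
print.heterocycle <- function(x, ...) {
  nh <- sum(x$atoms$element != "H")
  cat(
    "<heterocycle> ", x$smiles,
    if (!is.na(x$reg_id)) paste0(" (RegID ", x$reg_id, ")") else "",
    "\n  ", nh, " heavy atoms, ", sum(x$aromatic), " aromatic\n",
    sep = ""
  )
  invisible(x)
}

#' Enumerate exit-vectors of a heterocycle
#'
#' An exit-vector is an aromatic C-H or N-H bond: a position where a
#' substituent can be attached and whose direction defines how functionality
#' projects from the ring. One row is returned per aromatic carbon or
#' nitrogen bearing exactly one hydrogen, in ascending atom-index order.
#'
#' @param het A `heterocycle` or `conformer3d` object.
#' @return A tibble with columns `ring_atom` (atom index), `h_atom` (index of
#'   the attached hydrogen) and `element_class` (`"C"` or `"N"`, the latter
#'   for pyrrole-like nitrogens).
#' @export
enumerate_exit_vectors <- function(het) {
  atoms <- het$atoms
  aromatic <- het$aromatic
  el <- atoms$element
  rows <- list()
  for (i in which(aromatic & el %in% c("C", "N"))) {
    nb <- mol_neighbours(het, i)
    h <- nb[el[nb] == "H"]
    if (length(h) == 1) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        ring_atom = i, h_atom = h, element_class = el[i]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      ring_atom = integer(), h_atom = integer(), element_class = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$ring_atom)
}

#' Generate a single 3D conformer
#'
#' Embeds one low-energy conformer: rule-based 3D structure generation
#' followed by MMFF94 force-field refinement (the OpenBabel `gen3d`
#' operation). The heterocycles in scope are rigid aromatics, so a single
#' conformer represents the molecule well. The build is deterministic: the
#' same molecule always yields the same coordinates; `seed` is recorded on
#' the result for provenance.
#'
#' @param het A `heterocycle` object (or a SMILES string).
#' @param seed Integer seed recorded with the conformer.
#' @return A `conformer3d` object: the heterocycle fields plus 3D coordinates
#'   in the `atoms` tibble, `seed` and `charge_model` (initially `"none"`).
#' @export
embed_conformer <- function(het, seed = 42L) {
  if (is.character(het)) het <- parse_heterocycle(het)
  stopifnot(inherits(het, "heterocycle"))
  out <- smiles_to_mol2_3d(het$input_smiles, titles = "q")
  mols <- parse_mol2(out)
  if (length(mols) != 1) {
    rlang::abort(
      paste0("3D embedding failed for ", het$input_smiles),
      class = "ringhop_embed_error"
    )
  }
  conf <- conformer_from_mol(mols[[1]], het, seed)
  if (is.null(conf)) {
    rlang::abort(
      paste0("3D embedding failed for ", het$input_smiles),
      class = "ringhop_embed_error"
    )
  }
  conf
}

# Shared assembly of a conformer3d from an embedded mol2 record. Returns NULL
# when the embedding is unusable (atom mismatch or collapsed coordinates).
conformer_from_mol <- function(mol, het, seed) {
  if (nrow(mol$atoms) != nrow(het$atoms) ||
      !identical(mol$atoms$element, het$atoms$element)) {
    return(NULL)
  }
  X <- mol_coords(mol)
  if (max(apply(X, 2, function(v) diff(range(v)))) < 0.5) return(NULL)
  out <- het
  out$atoms$x <- mol$atoms$x
  out$atoms$y <- mol$atoms$y
  out$atoms$z <- mol$atoms$z
  out$atoms$charge <- NA_real_
  out$seed <- as.integer(seed)
  out$charge_model <- "none"
  class(out) <- c("conformer3d", "heterocycle")
  out
}

# Batch variant: embed many SMILES in one OpenBabel pass. Returns a list of
# conformer3d (NULL where embedding failed), named by `titles`.
embed_conformers <- function(smiles, seed = 42L) {
  if (length(smiles) == 0) return(list())
  out <- smiles_to_mol2_3d(smiles, titles = seq_along(smiles))
  mols <- parse_mol2(out)
  res <- vector("list", length(smiles))
  got <- suppressWarnings(as.integer(vapply(mols, `[[`, "", "name")))
  for (k in seq_along(mols)) {
    i <- got[k]
    if (is.na(i) || i < 1 || i > length(smiles)) next
    het <- tryCatch(parse_heterocycle(smiles[i]), error = function(e) NULL)
    if (is.null(het)) next
    res[[i]] <- conformer_from_mol(mols[[k]], het, seed)
  }
  res
}

#' Assign per-atom partial charges to a conformer
#'
#' The default model is the iterative partial equalization of orbital
#' electronegativity (PEOE) scheme of Gasteiger and Marsili, implemented in
#' [peoe_charges()] with the original published parameters. Externally
#' computed charges (e.g. RESP or AM1-BCC) can be imported with
#' `model = "external"`.
#'
#' @param conf A `conformer3d` object.
#' @param model `"gasteiger"` (default) or `"external"`.
#' @param charges Numeric vector of per-atom charges (hydrogens included, in
#'   atom order), required when `model = "external"`.
#' @return The conformer with its `atoms$charge` column filled in and
#'   `charge_model` set.
#' @export
assign_partial_charges <- function(conf, model = "gasteiger", charges = NULL) {
  stopifnot(inherits(conf, "conformer3d"))
  if (model == "gasteiger") {
    conf$atoms$charge <- peoe_charges(conf)
  } else if (model == "external") {
    if (is.null(charges) || !is.numeric(charges)) {
      rlang::abort("external model requires a numeric charge vector",
        class = "ringhop_charge_error"
      )
    }
    if (length(charges) != nrow(conf$atoms)) {
      rlang::abort(
        sprintf(
          "external charge list has %d entries but the molecule has %d atoms",
          length(charges), nrow(conf$atoms)
        ),
        class = "ringhop_charge_error"
      )
    }
    if (abs(sum(charges) - conf$formal_charge) > 1e-3) {
      rlang::abort(
        sprintf(
          "external charges sum to %.4f but the formal charge is %d",
          sum(charges), conf$formal_charge
        ),
        class = "ringhop_charge_error"
      )
    }
    conf$atoms$charge <- charges
  } else {
    rlang::abort(paste0("unknown charge model: ", model),
      class = "ringhop_config_error"
    )
  }
  conf$charge_model <- model
  conf
}

#' Read external charges from a two-column text file
#'
#' The file holds one `atom_index charge` pair per line (whitespace- or
#' comma-separated); indices are 1-based and must cover every atom once.
#'
#' @param path Path to the charge file.
#' @param n_atoms Expected number of atoms.
#' @return Numeric charge vector in atom order.
#' @export
read_charge_file <- function(path, n_atoms) {
  tab <- utils::read.table(path, col.names = c("idx", "charge"), sep = "",
                           comment.char = "#")
  if (nrow(tab) != n_atoms || !setequal(tab$idx, seq_len(n_atoms))) {
    rlang::abort(
      sprintf("charge file must cover atoms 1..%d exactly once", n_atoms),
      class = "ringhop_charge_error"
    )
  }
  tab$charge[order(tab$idx)]
}

#' Check ring planarity of a conformer
#'
#' Fits a least-squares plane through the given ring atoms and tests the
#' maximum out-of-plane deviation against a threshold. Heterocycles that
#' pucker after force-field refinement lack aromatic character and are
#' dropped from the searchable library.
#'
#' @param conf A `conformer3d` object.
#' @param ring_atom_indices Atom indices to test; defaults to all aromatic
#'   atoms.
#' @param threshold Maximum tolerated deviation in Angstrom (default 0.3).
#' @return `TRUE` if the maximum deviation is `<= threshold`.
#' @export
planarity_check <- function(conf, ring_atom_indices = NULL, threshold = 0.3) {
  if (is.null(ring_atom_indices)) ring_atom_indices <- which(conf$aromatic)
  if (length(ring_atom_indices) < 4) {
    rlang::abort("planarity check needs at least 4 ring atoms",
      class = "ringhop_geometry_error"
    )
  }
  X <- mol_coords(conf)[ring_atom_indices, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  normal <- svd(Xc)$v[, 3]
  max(abs(Xc %*% normal)) <= threshold
}

# Least-squares plane normal over a set of atoms (unit vector).
plane_normal <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  svd(Xc)$v[, 3]
}
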