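# Conversion layer over OpenBabel (via ChemmineOB) plus a minimal TRIPOS mol2
# reader/writer. mol2 is the interchange format used internally because it
# carries aromaticity annotations on both atoms and bonds, explicit hydrogens,
# and 3D coordinates in a single block.

ob_options <- function(...) {
  opts <- c(...)
  if (length(opts) == 0) {
    return(data.frame(names = character(), args = character()))
  }
  data.frame(names = names(opts), args = unname(opts), stringsAsFactors = FALSE)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form. Used throughout the package as
#' the molecular identity key for deduplication.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where conversion failed.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character())
  inp <- paste0(paste(smiles, seq_along(smiles)), "\n", collapse = "")
  out <- ChemmineOB::convertFormat("SMILES", "CAN", inp, options = ob_options())
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  res <- rep(NA_character_, length(smiles))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    idx <- as.integer(vapply(parts, function(p) trimws(p[length(p)]), ""))
    can <- vapply(parts, function(p) trimws(p[1]), "")
    ok <- !is.na(idx) & idx >= 1 & idx <= length(smiles)
    res[idx[ok]] <- can[ok]
  }
  res[!nzchar(res) | is.na(res)] <- NA_character_
  res
}

# Quick lexical screen applied before handing SMILES to OpenBabel, which
# silently drops trailing garbage such as an unclosed branch.
smiles_lexical_ok <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(FALSE)
  }
  s <- strsplit(smiles, "")[[1]]
  depth_round <- cumsum((s == "(") - (s == ")"))
  depth_square <- cumsum((s == "[") - (s == "]"))
  all(depth_round >= 0) && all(depth_square >= 0) &&
    utils::tail(depth_round, 1) == 0 && utils::tail(depth_square, 1) == 0
}

# Parse a (possibly multi-molecule) mol2 string into a list of molecule
# records: list(name, atoms = tibble(element, type, x, y, z, charge),
# bonds = tibble(a1, a2, order)).
parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(starts) == 0) return(list())
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    blk <- lines[starts[k]:ends[k]]
    counts <- suppressWarnings(scan(text = blk[3], quiet = TRUE))
    na <- as.integer(counts[1])
    nb <- as.integer(counts[2])
    ai <- grep("^@<TRIPOS>ATOM", blk)[1]
    bi <- grep("^@<TRIPOS>BOND", blk)[1]
    at <- utils::read.table(
      text = blk[(ai + 1):(ai + na)], stringsAsFactors = FALSE, fill = TRUE,
      col.names = c("idx", "name", "x", "y", "z", "type", "subst", "res", "charge")
    )
    bd <- if (nb > 0) {
      utils::read.table(
        text = blk[(bi + 1):(bi + nb)], stringsAsFactors = FALSE,
        col.names = c("idx", "a1", "a2", "order"),
        colClasses = c("integer", "integer", "integer", "character")
      )
    } else {
      data.frame(a1 = integer(), a2 = integer(), order = character())
    }
    if (!"charge" %in% names(at) || all(is.na(at$charge))) at$charge <- NA_real_
    list(
      name = trimws(blk[2]),
      atoms = tibble::tibble(
        element = sub("\\..*$", "", at$type),
        type = at$type,
        x = at$x, y = at$y, z = at$z,
        charge = as.numeric(at$charge)
      ),
      bonds = tibble::tibble(
        a1 = as.integer(bd$a1), a2 = as.integer(bd$a2),
        order = as.character(bd$order)
      )
    )
  })
}

# Serialize a molecule record (atoms/bonds tibbles) back to mol2 text.
# Aromatic bonds keep their "ar" order so OpenBabel re-perceives aromaticity.
write_mol2 <- function(mol) {
  at <- mol$atoms
  bd <- mol$bonds
  charge <- if (all(is.na(at$charge))) rep(0, nrow(at)) else at$charge
  paste0(
    "@<TRIPOS>MOLECULE\n", if (is.null(mol$name)) "mol" else mol$name, "\n ",
    nrow(at), " ", nrow(bd), " 0 0 0\nSMALL\nUSER_CHARGES\n@<TRIPOS>ATOM\n",
    paste(sprintf(
      "%7d %-4s %9.4f %9.4f %9.4f %-7s %3d UNL %9.4f",
      seq_len(nrow(at)), at$element, at$x, at$y, at$z, at$type, 1L, charge
    ), collapse = "\n"),
    "\n@<TRIPOS>BOND\n",
    paste(sprintf(
      "%6d %5d %5d %4s", seq_len(nrow(bd)), bd$a1, bd$a2, bd$order
    ), collapse = "\n"),
    "\n"
  )
}

# SMILES -> molecule graph with explicit hydrogens (no coordinates).
smiles_to_graph <- function(smiles) {
  out <- ChemmineOB::convertFormat(
    "SMILES", "MOL2", paste0(smiles, "\n"), options = ob_options(h = "")
  )
  mols <- parse_mol2(out)
  if (length(mols) != 1) return(NULL)
  mols[[1]]
}

# SMILES -> single 3D conformer mol2 block(s). Uses the OpenBabel gen3d
# operation: rule-based structure generation followed by MMFF94 force-field
# refinement. The build is deterministic for a given input.
smiles_to_mol2_3d <- function(smiles, titles = seq_along(smiles)) {
  inp <- paste0(paste(smiles, titles), "\n", collapse = "")
  ChemmineOB::convertFormat("SMILES", "MOL2", inp, options = ob_options(gen3d = ""))
}

# mol2 text -> SDF (V2000) text via OpenBabel, used for aligned-pose export.
mol2_to_sdf <- function(mol2_txt) {
  ChemmineOB::convertFormat("MOL2", "SDF", mol2_txt, options = ob_options())
}

# Atom-level helpers ---------------------------------------------------------

# indices of neighbours of atom i
mol_neighbours <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

# logical vector: atom participates in at least one aromatic bond
mol_aromatic_atoms <- function(mol) {
  n <- nrow(mol$atoms)
  ar <- logical(n)
  arb <- mol$bonds[mol$bonds$order == "ar", , drop = FALSE]
  ar[unique(c(arb$a1, arb$a2))] <- TRUE
  ar | grepl("\\.ar$", mol$atoms$type)
}

mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

# net formal charge read off bracket atoms of a SMILES string
smiles_formal_charge <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  if (length(brackets) == 0) return(0L)
  chg <- vapply(brackets, function(b) {
    plus <- regmatches(b, regexpr("\\+[0-9]*", b))
    minus <- regmatches(b, regexpr("-[0-9]*", b))
    v <- 0L
    if (length(plus)) v <- v + max(1L, suppressWarnings(as.integer(sub("\\+", "", plus))), na.rm = TRUE)
    if (length(minus)) v <- v - max(1L, abs(suppressWarnings(as.integer(minus))), na.rm = TRUE)
    v
  }, integer(1))
  sum(chg)
}
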