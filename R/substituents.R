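# Substituent fragments attachable at exit-vectors. Each fragment is a small
# hydrogen-explicit graph whose first atom is the attachment point; attaching
# one replaces the exit-vector hydrogen with a single bond to that atom.

substituent_fragment <- function(name, atoms, bonds = NULL) {
  atoms$x <- atoms$y <- atoms$z <- 0
  atoms$charge <- NA_real_
  atoms$element <- sub("\\..*$", "", atoms$type)
  b <- if (is.null(bonds)) {
    tibble::tibble(a1 = integer(), a2 = integer(), order = character())
  } else {
    tibble::tibble(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                   order = as.character(bonds$order))
  }
  list(name = name,
       atoms = tibble::as_tibble(atoms[, c("element", "type", "x", "y", "z", "charge")]),
       bonds = b)
}

.h_atoms <- function(n) data.frame(type = rep("H", n))

#' Default substituent sets for library functionalization
#'
#' Seven substituents for aromatic carbon positions and two for pyrrole-like
#' nitrogen positions. The carbon set spans electron-donating and
#' electron-withdrawing groups with minimal conformational flexibility
#' (methyl, fluoro, chloro, cyano, methoxy, amino, trifluoromethyl); the
#' nitrogen set holds methyl and acetyl. Both sets are replaceable: supply
#' any named list of fragments built the same way.
#'
#' @return A list with elements `c_substituents` and `n_substituents`, each a
#'   named list of attachment fragments.
#' @export
default_substituents <- function() {
  list(
    c_substituents = list(
      methyl = substituent_fragment("methyl",
        rbind(data.frame(type = "C.3"), .h_atoms(3)),
        data.frame(a1 = c(1, 1, 1), a2 = 2:4, order = "1")
      ),
      fluoro = substituent_fragment("fluoro", data.frame(type = "F")),
      chloro = substituent_fragment("chloro", data.frame(type = "Cl")),
      cyano = substituent_fragment("cyano",
        data.frame(type = c("C.1", "N.1")),
        data.frame(a1 = 1, a2 = 2, order = "3")
      ),
      methoxy = substituent_fragment("methoxy",
        rbind(data.frame(type = c("O.3", "C.3")), .h_atoms(3)),
        data.frame(a1 = c(1, 2, 2, 2), a2 = c(2, 3, 4, 5), order = "1")
      ),
      amino = substituent_fragment("amino",
        rbind(data.frame(type = "N.pl3"), .h_atoms(2)),
        data.frame(a1 = c(1, 1), a2 = c(2, 3), order = "1")
      ),
      trifluoromethyl = substituent_fragment("trifluoromethyl",
        data.frame(type = c("C.3", "F", "F", "F")),
        data.frame(a1 = c(1, 1, 1), a2 = c(2, 3, 4), order = "1")
      )
    ),
    n_substituents = list(
      methyl = substituent_fragment("methyl",
        rbind(data.frame(type = "C.3"), .h_atoms(3)),
        data.frame(a1 = c(1, 1, 1), a2 = 2:4, order = "1")
      ),
      acetyl = substituent_fragment("acetyl",
        rbind(data.frame(type = c("C.2", "O.2", "C.3")), .h_atoms(3)),
        data.frame(a1 = c(1, 1, 3, 3, 3), a2 = c(2, 3, 4, 5, 6),
                   order = c("2", "1", "1", "1", "1"))
      )
    )
  )
}

validate_substituent_set <- function(subs) {
  ok <- function(fr) {
    is.list(fr) && all(c("atoms", "bonds") %in% names(fr)) && nrow(fr$atoms) >= 1
  }
  if (!all(vapply(subs$c_substituents, ok, TRUE)) ||
      !all(vapply(subs$n_substituents, ok, TRUE))) {
    rlang::abort("each substituent needs an atoms table with one attachment atom",
      class = "ringhop_config_error"
    )
  }
  invisible(subs)
}

# Replace hydrogen h_idx of `mol` with substituent fragment `sub` (single
# bond to the fragment's first atom). Pure graph surgery; coordinates are
# irrelevant because products are re-canonicalized / re-embedded from SMILES.
attach_substituent <- function(mol, h_idx, sub) {
  at <- mol$atoms
  bd <- mol$bonds
  ring <- setdiff(unique(c(bd$a1[bd$a1 == h_idx | bd$a2 == h_idx],
                           bd$a2[bd$a1 == h_idx | bd$a2 == h_idx])), h_idx)
  at <- at[-h_idx, , drop = FALSE]
  keep <- !(bd$a1 == h_idx | bd$a2 == h_idx)
  bd <- bd[keep, , drop = FALSE]
  remap <- function(i) ifelse(i > h_idx, i - 1L, i)
  bd$a1 <- remap(bd$a1)
  bd$a2 <- remap(bd$a2)
  ring <- remap(ring)
  n0 <- nrow(at)
  at2 <- dplyr::bind_rows(at, sub$atoms)
  new_bonds <- tibble::tibble(a1 = ring, a2 = n0 + 1L, order = "1")
  if (nrow(sub$bonds)) {
    new_bonds <- dplyr::bind_rows(new_bonds, tibble::tibble(
      a1 = n0 + sub$bonds$a1, a2 = n0 + sub$bonds$a2, order = sub$bonds$order
    ))
  }
  list(name = "sub", atoms = at2, bonds = dplyr::bind_rows(bd, new_bonds))
}
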