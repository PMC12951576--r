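# Stability filter: removes "potentially explosive or bonkers" (PEB)
# enumerated heterocycles - motifs too unstable or reactive to be useful in a
# medicinal-chemistry context. Nine rules; a molecule is retained only if it
# violates none. Rules over ring membership are SMARTS substructure counts
# (OpenBabel SMARTS); rules over "atoms bonded together" are connected
# components of the induced subgraph of the named atom class, which covers
# both linear and branched arrangements.

.peb_smarts <- list(
  # more than three ring nitrogens bonded together: a path of four, or a
  # branched star of four (ring membership rather than perceived aromaticity,
  # which differs between toolkits for extreme rings such as pentazole)
  r2a = "[#7;R]~[#7;R]~[#7;R]~[#7;R]",
  r2b = "[#7;R](~[#7;R])(~[#7;R])~[#7;R]",
  # three or more exocyclic carbonyls (ring carbon, terminal double-bond O)
  r4 = "[#6;R]=[OX1]",
  # cyclic acid anhydride
  r5 = "[#6;R](=[OX1])[#8;R][#6;R]=[OX1]",
  # cyclic thioester
  r6 = "[#6;R](=[OX1])[#16;R]",
  # two nitrogens bridging a fused ring system (both ring-fusion atoms are N)
  r7 = "[#7;R2][#7;R2]",
  # two or more sulfurs within one six-membered ring (1,2 / 1,3 / 1,4)
  r8a = "[#16]~1~[#16]~[*]~[*]~[*]~[*]~1",
  r8b = "[#16]~1~[*]~[#16]~[*]~[*]~[*]~1",
  r8c = "[#16]~1~[*]~[*]~[#16]~[*]~[*]~1",
  # two cyclic esters whose carbonyl carbons are directly bonded
  r9 = "[#8;R][#6;R](=[OX1])[#6;R](=[OX1])[#8;R]"
)

# sizes of connected components of the induced subgraph on `keep` atoms
component_sizes <- function(mol, keep) {
  idx <- which(keep)
  if (length(idx) == 0) return(integer())
  comp <- stats::setNames(seq_along(idx), idx)
  b <- mol$bonds
  sel <- b$a1 %in% idx & b$a2 %in% idx
  edges <- b[sel, c("a1", "a2")]
  if (nrow(edges)) {
    repeat {
      changed <- FALSE
      for (e in seq_len(nrow(edges))) {
        c1 <- comp[[as.character(edges$a1[e])]]
        c2 <- comp[[as.character(edges$a2[e])]]
        if (c1 != c2) {
          comp[comp == max(c1, c2)] <- min(c1, c2)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  as.integer(table(comp))
}

smarts_counts <- function(smiles, patterns) {
  res <- ChemmineOB::forEachMol("SMILES", smiles, function(x) {
    vapply(patterns, function(p) {
      as.numeric(ChemmineOB::smartsSearch_OB(list(x), p, uniqueMatches = TRUE)[[1]])
    }, numeric(1))
  })
  res[[1]]
}

# exact structures exempt from the PEB rules: the annular tautomers of
# tetrazole, which the rule set would otherwise discard despite tetrazole
# being an established, stable pharmacophore
peb_whitelist <- function() {
  canonical_smiles(c("c1nnn[nH]1", "c1nn[nH]n1"))
}

#' Stability (PEB) filter for enumerated heterocycles
#'
#' Evaluates the nine-rule filter that removes chemically unstable or
#' implausible enumerated heterocycles: (1) fewer than 20% of heavy atoms are
#' carbon; (2) more than three aromatic nitrogens bonded together; (3) four
#' or more heteroatoms bonded together; (4) three or more exocyclic
#' carbonyls; (5) a cyclic acid anhydride; (6) a cyclic thioester; (7) two
#' nitrogens bridging a fused ring system; (8) two or more sulfurs within a
#' six-membered ring; (9) two cyclic esters with directly bonded carbonyl
#' carbons. Tetrazole (either annular tautomer) is exempted as an exact
#' structure.
#'
#' @param het A `heterocycle` object or SMILES string.
#' @return A list with `retain` (logical) and `violated` (character vector of
#'   rule identifiers `"r1"`..`"r9"`, empty when retained).
#' @export
peb_filter <- function(het) {
  if (is.character(het)) het <- parse_heterocycle(het, require_aromatic = FALSE)
  if (het$smiles %in% peb_whitelist()) {
    return(list(retain = TRUE, violated = character()))
  }
  el <- het$atoms$element
  heavy <- el != "H"
  violated <- character()

  if (sum(heavy & el == "C") < 0.2 * sum(heavy)) violated <- c(violated, "r1")
  cnt <- smarts_counts(het$smiles, .peb_smarts)
  if (cnt[["r2a"]] + cnt[["r2b"]] > 0) violated <- c(violated, "r2")
  if (max(c(0L, component_sizes(het, heavy & el != "C"))) >= 4) {
    violated <- c(violated, "r3")
  }
  if (cnt[["r4"]] >= 3) violated <- c(violated, "r4")
  if (cnt[["r5"]] > 0) violated <- c(violated, "r5")
  if (cnt[["r6"]] > 0) violated <- c(violated, "r6")
  if (cnt[["r7"]] > 0) violated <- c(violated, "r7")
  if (cnt[["r8a"]] + cnt[["r8b"]] + cnt[["r8c"]] > 0) violated <- c(violated, "r8")
  if (cnt[["r9"]] > 0) violated <- c(violated, "r9")

  list(retain = length(violated) == 0, violated = violated)
}
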