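# Shape and electrostatic similarity of an aligned probe/query pair.
#
# Shape: each atom is a spherical Gaussian with amplitude p = 2.7 and width
# chosen so the Gaussian integrates to the hard-sphere volume of the atom's
# van der Waals radius; the molecular overlap is the analytic sum of
# first-order atom-pair product integrals.
#
# Electrostatics: the Coulomb potential of each atomic point charge is
# approximated by a three-Gaussian expansion of 1/r; the field overlap of two
# charge distributions then reduces to a double sum over atom pairs with the
# kernel self-convolution evaluated at the interatomic distance.

# Bondi-type van der Waals radii (Angstrom)
.vdw_radii <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)

.gauss_p <- 2.7

# Three-Gaussian expansion of 1/r, least-squares/minimax fitted over
# r in [0.5, 10] Angstrom (max relative error 4.7%). Regenerate with
# scripts/fit_esp_kernel.R.
.esp_kernel <- list(
  a = c(0.2243105287, 0.5447418393, 1.800075673),
  b = c(0.00855802138, 0.1554314282, 1.746819462)
)

#' Three-Gaussian Coulomb kernel
#'
#' Evaluates the packaged three-Gaussian approximation of `1/r`.
#'
#' @param r Distances in Angstrom.
#' @return Approximate `1/r` values.
#' @export
esp_kernel <- function(r) {
  k <- .esp_kernel
  colSums(k$a * exp(-outer(k$b, r^2)))
}

atom_alphas <- function(elements) {
  r <- .vdw_radii[elements]
  if (anyNA(r)) {
    rlang::abort(
      paste0("no van der Waals radius for element ",
             paste(unique(elements[is.na(r)]), collapse = ", ")),
      class = "ringhop_domain_error"
    )
  }
  pi * (3 * .gauss_p / (4 * pi * r^3))^(2 / 3)
}

pair_dist2 <- function(XA, XB) {
  outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
}

#' Analytic Gaussian volume overlap of two conformers
#'
#' First-order (atom-pair) Gaussian product integrals summed over all atom
#' pairs, hydrogens included. If an alignment is supplied it is applied to
#' `B` first.
#'
#' @param A,B `conformer3d` objects.
#' @param alignment Optional `ringhop_alignment` applied to `B`.
#' @return Overlap volume (Angstrom^3), symmetric in its arguments.
#' @export
gaussian_volume_overlap <- function(A, B, alignment = NULL) {
  if (nrow(A$atoms) == 0 || nrow(B$atoms) == 0) {
    rlang::abort("empty conformer", class = "ringhop_domain_error")
  }
  if (!is.null(alignment)) B <- apply_alignment(B, alignment)
  XA <- mol_coords(A); XB <- mol_coords(B)
  aA <- atom_alphas(A$atoms$element)
  aB <- atom_alphas(B$atoms$element)
  S <- outer(aA, aB, "+")
  D2 <- pair_dist2(XA, XB)
  sum(.gauss_p^2 * (pi / S)^1.5 * exp(-outer(aA, aB) / S * D2))
}

#' Shape Tanimoto similarity of an aligned pair
#'
#' `T = O_AB / (O_AA + O_BB - O_AB)` over analytic Gaussian volume overlaps:
#' 1 for identical perfectly aligned molecules, near 0 for disjoint shapes.
#'
#' @inheritParams gaussian_volume_overlap
#' @return Similarity in \[0, 1\].
#' @export
shape_tanimoto <- function(A, B, alignment = NULL) {
  if (!is.null(alignment)) B <- apply_alignment(B, alignment)
  oaa <- gaussian_volume_overlap(A, A)
  obb <- gaussian_volume_overlap(B, B)
  oab <- gaussian_volume_overlap(A, B)
  den <- oaa + obb - oab
  if (den <= 0) {
    rlang::abort("degenerate shape overlap denominator",
      class = "ringhop_domain_error"
    )
  }
  oab / den
}

# Field overlap E_AB = sum_ij q_i q_j L(d_ij), L = kernel self-convolution.
esp_field_overlap <- function(XA, qA, XB, qB) {
  k <- .esp_kernel
  D2 <- pair_dist2(XA, XB)
  L <- 0
  for (i in 1:3) for (j in 1:3) {
    s <- k$b[i] + k$b[j]
    L <- L + k$a[i] * k$a[j] * (pi / s)^1.5 * exp(-(k$b[i] * k$b[j] / s) * D2)
  }
  as.numeric(t(qA) %*% L %*% qB)
}

#' Electrostatic potential similarity of an aligned pair
#'
#' Tanimoto index over analytic charge-field overlap integrals computed with
#' the three-Gaussian Coulomb kernel. The raw Tanimoto lies in \[-1/3, 1\]
#' (negative when positive potential aligns with negative); the default
#' normalization maps it linearly onto \[0, 1\], the convention of
#' Gaussian-field ESP comparison methods, so that an identical aligned
#' charge distribution scores 1 and a sign-inverted one scores 0.
#'
#' @inheritParams gaussian_volume_overlap
#' @param normalize `"linear"` (default), or `"raw"` for the untransformed
#'   Tanimoto.
#' @return Similarity score.
#' @export
esp_similarity <- function(A, B, alignment = NULL,
                           normalize = c("linear", "raw")) {
  normalize <- match.arg(normalize)
  if (anyNA(A$atoms$charge) || anyNA(B$atoms$charge)) {
    rlang::abort("conformers must carry partial charges; run assign_partial_charges()",
      class = "ringhop_charge_error"
    )
  }
  if (!is.null(alignment)) B <- apply_alignment(B, alignment)
  XA <- mol_coords(A); XB <- mol_coords(B)
  eaa <- esp_field_overlap(XA, A$atoms$charge, XA, A$atoms$charge)
  ebb <- esp_field_overlap(XB, B$atoms$charge, XB, B$atoms$charge)
  eab <- esp_field_overlap(XA, A$atoms$charge, XB, B$atoms$charge)
  raw <- eab / (eaa + ebb - eab)
  if (normalize == "raw") raw else (3 * raw + 1) / 4
}

#' Weighted total similarity score
#'
#' `total = w_shape * shape + w_esp * esp`. With the default unit weights the
#' total lies in \[0, 2\]; weights summing to 1 give a \[0, 1\] score.
#'
#' @param shape,esp Component similarity scores.
#' @param w_shape,w_esp Nonnegative weights (default 1, 1).
#' @return Weighted total.
#' @export
total_score <- function(shape, esp, w_shape = 1, w_esp = 1) {
  if (any(c(w_shape, w_esp) < 0)) {
    rlang::abort("weights must be nonnegative", class = "ringhop_config_error")
  }
  w_shape * shape + w_esp * esp
}

# One aligned probe scored against a prepared query (precomputed self
# overlaps avoid rescoring the query for every probe).
score_alignment <- function(query_prep, probe, alignment, w_shape = 1, w_esp = 1) {
  B <- apply_alignment(probe, alignment)
  XB <- mol_coords(B)
  aB <- atom_alphas(B$atoms$element)
  S <- outer(query_prep$alphas, aB, "+")
  D2 <- pair_dist2(query_prep$X, XB)
  oab <- sum(.gauss_p^2 * (pi / S)^1.5 * exp(-outer(query_prep$alphas, aB) / S * D2))
  obb <- gaussian_volume_overlap(B, B)
  shape <- oab / (query_prep$oaa + obb - oab)
  ebb <- esp_field_overlap(XB, B$atoms$charge, XB, B$atoms$charge)
  eab <- esp_field_overlap(query_prep$X, query_prep$charges, XB, B$atoms$charge)
  esp_raw <- eab / (query_prep$eaa + ebb - eab)
  esp <- (3 * esp_raw + 1) / 4
  tibble::tibble(
    shape = shape, esp = esp, esp_raw = esp_raw,
    total = total_score(shape, esp, w_shape, w_esp)
  )
}

prepare_query_scoring <- function(query) {
  X <- mol_coords(query)
  list(
    X = X,
    alphas = atom_alphas(query$atoms$element),
    charges = query$atoms$charge,
    oaa = gaussian_volume_overlap(query, query),
    eaa = esp_field_overlap(X, query$atoms$charge, X, query$atoms$charge)
  )
}
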