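# Rigid-body alignment of a probe heterocycle onto a query through their
# exit-vectors, and the distance/angle hash used to pre-screen exit-vector
# pairs in two-vector searches.

#' Kabsch-Umeyama rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of point set
#' `P` onto point set `Q` (correspondence by row). Reflections are excluded
#' by the determinant correction.
#'
#' @param P,Q Numeric matrices of matching dimension (n x 3, n >= 3).
#' @return A list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd`; the transform maps `P` onto `Q` as `P %*% t(rotation) +
#'   translation`.
#' @export
kabsch_umeyama <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || nrow(P) < 3 || ncol(P) != 3) {
    rlang::abort("point sets must match and contain at least 3 points in 3D",
      class = "ringhop_geometry_error"
    )
  }
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  if (sum(P0^2) < 1e-12 || sum(Q0^2) < 1e-12) {
    rlang::abort("degenerate (coincident) point set",
      class = "ringhop_geometry_error"
    )
  }
  H <- t(P0) %*% Q0
  s <- svd(H)
  # collinear point sets leave a free rotation about the line: reject
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    rlang::abort("collinear point set; rotation is not determined",
      class = "ringhop_geometry_error"
    )
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  aligned <- P %*% t(R) + matrix(tr, nrow(P), 3, byrow = TRUE)
  list(
    rotation = R,
    translation = tr,
    rmsd = sqrt(mean(rowSums((aligned - Q)^2)))
  )
}

# Correspondence points for a single exit-vector: the ring atom, the hydrogen
# terminal, and a unit ring-normal anchor off the ring atom. The anchor pins
# the ring plane without degeneracy (ring atom, H and ring centroid are
# nearly collinear); negating the normal realises the 180-degree flip about
# the vector axis.
vector_correspondence <- function(conf, ring_atom, h_atom, flip = FALSE) {
  X <- mol_coords(conf)
  nrm <- plane_normal(X[conf$aromatic, , drop = FALSE])
  if (flip) nrm <- -nrm
  xhat <- X[h_atom, ] - X[ring_atom, ]
  xhat <- xhat / sqrt(sum(xhat^2))
  z <- nrm - sum(nrm * xhat) * xhat
  z <- z / sqrt(sum(z^2))
  rbind(X[ring_atom, ], X[h_atom, ], X[ring_atom, ] + z)
}

new_alignment <- function(fit, probe_vector_ids, flip) {
  structure(
    list(
      rotation = fit$rotation, translation = fit$translation,
      probe_vector_ids = probe_vector_ids, flip = flip, rmsd = fit$rmsd
    ),
    class = "ringhop_alignment"
  )
}

#' Align a probe onto a query through one exit-vector
#'
#' Superposes the probe exit-vector (ring atom, hydrogen terminal, ring-plane
#' anchor) onto the query exit-vector by Kabsch-Umeyama. The two-fold
#' ambiguity about the vector axis is explored with `flip`: `TRUE` applies an
#' additional 180-degree rotation about the aligned exit-vector before
#' scoring.
#'
#' @param query,probe `conformer3d` objects.
#' @param qvec,pvec Exit-vector rows (any list/row with `ring_atom` and
#'   `h_atom`).
#' @param flip Logical flip state.
#' @return A `ringhop_alignment`: rotation, translation, probe vector ids,
#'   flip flag, and the RMSD over the correspondence set.
#' @export
align_one_vector <- function(query, qvec, probe, pvec, flip = FALSE) {
  Q <- vector_correspondence(query, qvec$ring_atom, qvec$h_atom, flip = FALSE)
  P <- vector_correspondence(probe, pvec$ring_atom, pvec$h_atom, flip = flip)
  fit <- kabsch_umeyama(P, Q)
  new_alignment(fit, probe_vector_ids = pvec$ring_atom, flip = flip)
}

#' Align a probe onto a query through a pair of exit-vectors
#'
#' The correspondence set is (ring atom 1, terminal 1, ring atom 2,
#' terminal 2) of the probe pair mapped onto the query pair. `order = TRUE`
#' maps the probe pair in the opposite order, the pair-search analogue of the
#' one-vector 180-degree flip.
#'
#' @param query,probe `conformer3d` objects.
#' @param qpair,ppair Two-row exit-vector tables (columns `ring_atom`,
#'   `h_atom`).
#' @param order Logical; `TRUE` swaps the probe pair before aligning.
#' @return A `ringhop_alignment`.
#' @export
align_two_vector <- function(query, qpair, probe, ppair, order = FALSE) {
  stopifnot(nrow(qpair) == 2, nrow(ppair) == 2)
  if (order) ppair <- ppair[2:1, ]
  XQ <- mol_coords(query); XP <- mol_coords(probe)
  Q <- XQ[c(qpair$ring_atom[1], qpair$h_atom[1],
            qpair$ring_atom[2], qpair$h_atom[2]), ]
  P <- XP[c(ppair$ring_atom[1], ppair$h_atom[1],
            ppair$ring_atom[2], ppair$h_atom[2]), ]
  fit <- kabsch_umeyama(P, Q)
  new_alignment(fit, probe_vector_ids = ppair$ring_atom, flip = order)
}

#' Apply an alignment to a conformer
#'
#' @param conf A `conformer3d`.
#' @param alignment A `ringhop_alignment`.
#' @return The conformer with transformed coordinates.
#' @export
apply_alignment <- function(conf, alignment) {
  X <- mol_coords(conf) %*% t(alignment$rotation)
  X <- sweep(X, 2, alignment$translation, "+")
  conf$atoms$x <- X[, 1]; conf$atoms$y <- X[, 2]; conf$atoms$z <- X[, 3]
  conf
}

# Geometry hashing ------------------------------------------------------------

#' Exit-vector pair geometry
#'
#' Distance between the two ring atoms and the angle between the two C,N-H
#' bond direction vectors, plus the packed 8-bit hash.
#'
#' @param conf A `conformer3d`.
#' @param pair Two-row exit-vector table.
#' @param n_dist_bins,n_angle_bins,dist_range Binning configuration passed to
#'   [distance_bin()] / [angle_bin()].
#' @return A list with `d` (Angstrom), `alpha_v` (degrees) and `hash`.
#' @export
vector_pair_geometry <- function(conf, pair, n_dist_bins = 18L,
                                 n_angle_bins = 6L, dist_range = c(1.2, 7.5)) {
  X <- mol_coords(conf)
  r1 <- X[pair$ring_atom[1], ]; r2 <- X[pair$ring_atom[2], ]
  v1 <- X[pair$h_atom[1], ] - r1
  v2 <- X[pair$h_atom[2], ] - r2
  d <- sqrt(sum((r2 - r1)^2))
  cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  alpha <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  list(
    d = d, alpha_v = alpha,
    hash = pair_hash(
      distance_bin(d, n_bins = n_dist_bins, range = dist_range),
      angle_bin(alpha, n_bins = n_angle_bins)
    )
  )
}

#' Distance and angle binning for the pair hash
#'
#' Distances are assigned to uniform bins over `range` (default 18 bins over
#' 1.2-7.5 Angstrom), ordered smallest to largest; values outside the range
#' clamp to the first or last bin. Angles use uniform bins over 0-180
#' degrees.
#'
#' @param d Distance in Angstrom (> 0).
#' @param alpha Angle in degrees within \[0, 180\].
#' @param n_bins Number of bins.
#' @param range Distance range spanned by the bins.
#' @return Integer bin index, zero-based.
#' @export
distance_bin <- function(d, n_bins = 18L, range = c(1.2, 7.5)) {
  if (any(d <= 0)) {
    rlang::abort("distances must be positive", class = "ringhop_domain_error")
  }
  width <- diff(range) / n_bins
  pmin(pmax(floor((d - range[1]) / width), 0L), n_bins - 1L)
}

#' @rdname distance_bin
#' @export
angle_bin <- function(alpha, n_bins = 6L) {
  if (any(alpha < 0 | alpha > 180)) {
    rlang::abort("angles must lie in [0, 180] degrees",
      class = "ringhop_domain_error"
    )
  }
  pmin(floor(alpha / (180 / n_bins)), n_bins - 1L)
}

#' Pack distance and angle bins into the 8-bit pair hash
#'
#' The high five bits hold the distance bin, the low three bits the angle
#' bin; two exit-vector pairs share a hash exactly when both bins agree.
#'
#' @param dist_bin,angle_bin Zero-based bin indices.
#' @return Integer in \[0, 255\].
#' @export
pair_hash <- function(dist_bin, angle_bin) {
  bitwOr(bitwShiftL(as.integer(dist_bin), 3L), as.integer(angle_bin))
}

#' Precompute the exit-vector pair hash index of a library
#'
#' Hashes every unordered exit-vector pair of every retained library entry.
#' A two-vector search then aligns only entries sharing the query pair's
#' hash.
#'
#' @param library A `ringhop_library` tibble.
#' @param conformers Optional named list of `conformer3d` objects keyed by
#'   `reg_id`; missing ones are embedded on the fly.
#' @param seed Embedding seed.
#' @inheritParams vector_pair_geometry
#' @return A tibble of class `ringhop_hash_index` with columns `hash`,
#'   `reg_id`, `atom_1`, `h_1`, `atom_2`, `h_2`, `d`, `alpha_v`.
#' @export
build_hash_index <- function(library, conformers = NULL, seed = 42L,
                             n_dist_bins = 18L, n_angle_bins = 6L,
                             dist_range = c(1.2, 7.5)) {
  lib <- library[library$retained & library$exit_vector_count >= 2, , drop = FALSE]
  if (is.null(conformers)) {
    confs <- embed_conformers(lib$smiles, seed = seed)
    names(confs) <- as.character(lib$reg_id)
  } else {
    confs <- conformers
  }
  rows <- list()
  for (k in seq_len(nrow(lib))) {
    conf <- confs[[as.character(lib$reg_id[k])]]
    if (is.null(conf)) {
      rlang::abort(
        paste0("no conformer for RegID ", lib$reg_id[k]),
        class = "ringhop_index_error"
      )
    }
    ev <- enumerate_exit_vectors(conf)
    if (nrow(ev) < 2) next
    cmb <- utils::combn(nrow(ev), 2)
    for (c_i in seq_len(ncol(cmb))) {
      pr <- ev[cmb[, c_i], ]
      g <- vector_pair_geometry(conf, pr, n_dist_bins, n_angle_bins, dist_range)
      rows[[length(rows) + 1]] <- tibble::tibble(
        hash = g$hash, reg_id = lib$reg_id[k],
        atom_1 = pr$ring_atom[1], h_1 = pr$h_atom[1],
        atom_2 = pr$ring_atom[2], h_2 = pr$h_atom[2],
        d = g$d, alpha_v = g$alpha_v
      )
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    hash = integer(), reg_id = integer(), atom_1 = integer(), h_1 = integer(),
    atom_2 = integer(), h_2 = integer(), d = numeric(), alpha_v = numeric()
  )
  structure(out, class = c("ringhop_hash_index", class(out)),
            config = list(n_dist_bins = n_dist_bins, n_angle_bins = n_angle_bins,
                          dist_range = dist_range))
}

#' Look up a hash in a pair index
#'
#' @param index A `ringhop_hash_index`.
#' @param hash Integer hash value.
#' @return The matching index rows (zero rows when the hash is absent).
#' @export
lookup_hash <- function(index, hash) {
  index[index$hash == hash, , drop = FALSE]
}
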