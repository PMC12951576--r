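# Shared fixtures and independent oracles for the test suite. Conformers are
# cached per SMILES because embedding is deterministic.

.conf_cache <- new.env(parent = emptyenv())

charged_conf <- function(smiles, seed = 42L) {
  key <- paste0(smiles, "#", seed)
  if (!is.null(.conf_cache[[key]])) return(.conf_cache[[key]])
  conf <- assign_partial_charges(embed_conformer(smiles, seed = seed))
  .conf_cache[[key]] <- conf
  conf
}

conf_coords <- function(conf) as.matrix(conf$atoms[, c("x", "y", "z")])

# small seed-only library around a fixed molecule set
tiny_library <- function(seeds) {
  build_library(seeds, functionalize = "none")
}

# independent least-squares plane fit (principal components), used as the
# oracle against the packaged planarity machinery
oracle_plane_dev <- function(X) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  max(abs(pc$x[, 3]))
}

# random rigid transform
random_rigid <- function() {
  M <- matrix(stats::rnorm(9), 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = stats::rnorm(3, sd = 2))
}

transform_conf <- function(conf, R, t) {
  X <- conf_coords(conf) %*% t(R)
  X <- sweep(X, 2, t, "+")
  conf$atoms$x <- X[, 1]; conf$atoms$y <- X[, 2]; conf$atoms$z <- X[, 3]
  conf
}

# brute-force voxel integration of the Gaussian volume overlap of two
# conformers (same atomic Gaussian model, numerical quadrature)
grid_volume_overlap <- function(A, B, spacing = 0.2, pad = 3.5) {
  vdw <- c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80, F = 1.47, Cl = 1.75)
  p <- 2.7
  alpha <- function(el) pi * (3 * p / (4 * pi * vdw[el]^3))^(2 / 3)
  XA <- conf_coords(A); XB <- conf_coords(B)
  lo <- pmin(apply(XA, 2, min), apply(XB, 2, min)) - pad
  hi <- pmax(apply(XA, 2, max), apply(XB, 2, max)) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  # product integral: evaluate both densities on the grid slab by slab
  aA <- alpha(A$atoms$element); aB <- alpha(B$atoms$element)
  total <- 0
  for (z in gz) {
    rhoA <- matrix(0, length(gx), length(gy))
    rhoB <- matrix(0, length(gx), length(gy))
    for (i in seq_len(nrow(XA))) {
      rhoA <- rhoA + p * exp(-aA[i] * (outer((gx - XA[i, 1])^2,
                                             (gy - XA[i, 2])^2, "+") +
                                         (z - XA[i, 3])^2))
    }
    for (i in seq_len(nrow(XB))) {
      rhoB <- rhoB + p * exp(-aB[i] * (outer((gx - XB[i, 1])^2,
                                             (gy - XB[i, 2])^2, "+") +
                                         (z - XB[i, 3])^2))
    }
    total <- total + sum(rhoA * rhoB)
  }
  total * spacing^3
}

# brute-force voxel integration of the ESP field overlap with the same
# three-Gaussian Coulomb kernel as the analytic route
grid_esp_overlap <- function(A, B, spacing = 0.25, pad = 4.5) {
  XA <- conf_coords(A); XB <- conf_coords(B)
  qA <- A$atoms$charge; qB <- B$atoms$charge
  lo <- pmin(apply(XA, 2, min), apply(XB, 2, min)) - pad
  hi <- pmax(apply(XA, 2, max), apply(XB, 2, max)) + pad
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  total <- 0
  for (z in gz) {
    phiA <- matrix(0, length(gx), length(gy))
    phiB <- matrix(0, length(gx), length(gy))
    for (i in seq_len(nrow(XA))) {
      r <- sqrt(outer((gx - XA[i, 1])^2, (gy - XA[i, 2])^2, "+") +
                  (z - XA[i, 3])^2)
      phiA <- phiA + qA[i] * matrix(esp_kernel(as.numeric(r)), nrow(r))
    }
    for (i in seq_len(nrow(XB))) {
      r <- sqrt(outer((gx - XB[i, 1])^2, (gy - XB[i, 2])^2, "+") +
                  (z - XB[i, 3])^2)
      phiB <- phiB + qB[i] * matrix(esp_kernel(as.numeric(r)), nrow(r))
    }
    total <- total + sum(phiA * phiB)
  }
  total * spacing^3
}
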