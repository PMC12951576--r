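# Rigid superposition, exit-vector alignment and geometric hashing.

test_that("Kabsch-Umeyama recovers exact transforms and rejects degenerate input", {
  withr::with_seed(5, {
    P <- matrix(rnorm(15), 5, 3)
    fit <- kabsch_umeyama(P, P)
    expect_equal(fit$rotation, diag(3), tolerance = 1e-10)
    expect_equal(fit$translation, rep(0, 3), tolerance = 1e-10)
    expect_equal(fit$rmsd, 0, tolerance = 1e-10)

    tr <- random_rigid()
    Q <- P %*% t(tr$R) + matrix(tr$t, 5, 3, byrow = TRUE)
    fit2 <- kabsch_umeyama(P, Q)
    expect_equal(fit2$rotation, tr$R, tolerance = 1e-6)
    expect_lt(fit2$rmsd, 1e-8)
    expect_equal(det(fit2$rotation), 1, tolerance = 1e-6)
  })

  expect_error(kabsch_umeyama(matrix(0, 4, 3), matrix(0, 5, 3)),
    class = "ringhop_geometry_error"
  )
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_umeyama(line, line), class = "ringhop_geometry_error")
})

test_that("Kabsch-Umeyama beats random rigid transforms on random point clouds", {
  withr::with_seed(17, {
    for (inst in 1:3) {
      P <- matrix(rnorm(15), 5, 3)
      Q <- matrix(rnorm(15), 5, 3)
      fit <- kabsch_umeyama(P, Q)
      best_random <- Inf
      for (k in 1:10000) {
        tr <- random_rigid()
        Pk <- P %*% t(tr$R) + matrix(tr$t, 5, 3, byrow = TRUE)
        best_random <- min(best_random, sqrt(mean(rowSums((Pk - Q)^2))))
      }
      expect_lte(fit$rmsd, best_random)
    }
  })
})

test_that("Kabsch rmsd is optimal at the given correspondence", {
  withr::with_seed(23, {
    P <- matrix(rnorm(15), 5, 3)
    Q <- P %*% t(random_rigid()$R) + matrix(rnorm(15, sd = 0.1), 5, 3)
    base <- kabsch_umeyama(P, Q)$rmsd
    for (k in 1:20) {
      perm <- sample(5)
      if (identical(perm, 1:5)) next
      expect_gte(kabsch_umeyama(P[perm, ], Q)$rmsd, base - 1e-9)
    }
  })
})

test_that("one-vector alignment is exact on self and explores both flip states", {
  fur <- charged_conf("c1ccoc1")
  ev <- enumerate_exit_vectors(fur)
  al <- align_one_vector(fur, ev[1, ], fur, ev[1, ], flip = FALSE)
  expect_equal(al$rmsd, 0, tolerance = 1e-8)

  # furan's in-plane mirror symmetry maps vector 1 onto vector 2 and vector 3
  # onto vector 4; the flip state accounts exactly for that asymmetry, so
  # score(v, no flip) equals score(mirror(v), flip)
  oxa <- charged_conf("c1cnco1")
  ev_o <- enumerate_exit_vectors(oxa)
  score_vf <- function(v, f) {
    shape_tanimoto(fur, fur, align_one_vector(fur, ev[1, ], fur, ev[v, ], f))
  }
  expect_equal(score_vf(1, FALSE), score_vf(2, TRUE), tolerance = 1e-4)
  expect_equal(score_vf(3, FALSE), score_vf(4, TRUE), tolerance = 1e-4)

  # exhaustive two-state scan: the retained state is the max of the two
  for (v in seq_len(nrow(ev_o))) {
    t0 <- shape_tanimoto(fur, oxa, align_one_vector(fur, ev[1, ], oxa, ev_o[v, ], FALSE)) +
      esp_similarity(fur, oxa, align_one_vector(fur, ev[1, ], oxa, ev_o[v, ], FALSE))
    t1 <- shape_tanimoto(fur, oxa, align_one_vector(fur, ev[1, ], oxa, ev_o[v, ], TRUE)) +
      esp_similarity(fur, oxa, align_one_vector(fur, ev[1, ], oxa, ev_o[v, ], TRUE))
    expect_true(max(t0, t1) >= t0 && max(t0, t1) >= t1)
  }

  # aligned exit-vectors are parallel
  al2 <- align_one_vector(fur, ev[1, ], oxa, ev_o[2, ], flip = TRUE)
  moved <- apply_alignment(oxa, al2)
  vq <- conf_coords(fur)[ev$h_atom[1], ] - conf_coords(fur)[ev$ring_atom[1], ]
  vp <- conf_coords(moved)[ev_o$h_atom[2], ] - conf_coords(moved)[ev_o$ring_atom[2], ]
  ang <- acos(sum(vq * vp) / sqrt(sum(vq^2) * sum(vp^2))) * 180 / pi
  expect_lt(ang, 5)
})

test_that("two-vector alignment honours pair order and symmetry", {
  thio <- charged_conf("c1ccsc1")
  ev <- enumerate_exit_vectors(thio)
  el <- thio$atoms$element
  s_nb <- which(vapply(seq_len(nrow(ev)), function(k) {
    any(el[ringhop:::mol_neighbours(thio, ev$ring_atom[k])] == "S")
  }, TRUE))
  pair <- ev[s_nb, ] # the 2,5-pair flanking sulfur
  expect_equal(nrow(pair), 2)

  a0 <- align_two_vector(thio, pair, thio, pair, order = FALSE)
  expect_equal(a0$rmsd, 0, tolerance = 1e-8)
  # C2v symmetry: the swapped order self-aligns equally well
  a1 <- align_two_vector(thio, pair, thio, pair, order = TRUE)
  expect_equal(a1$rmsd, 0, tolerance = 1e-4)

  # asymmetric probe: best-of-orders is no worse than either single order
  thia <- charged_conf("c1cncs1")
  ev_t <- enumerate_exit_vectors(thia)
  ppair <- ev_t[1:2, ]
  r0 <- align_two_vector(thio, pair, thia, ppair, FALSE)$rmsd
  r1 <- align_two_vector(thio, pair, thia, ppair, TRUE)$rmsd
  expect_lte(min(r0, r1), r0)
  expect_lte(min(r0, r1), r1)
})

test_that("alignment rmsd is invariant to rigid pre-transformation of the probe", {
  pyr <- charged_conf("c1ccncc1")
  thio <- charged_conf("c1ccsc1")
  qv <- enumerate_exit_vectors(pyr)[1, ]
  pv <- enumerate_exit_vectors(thio)[2, ]
  base <- align_one_vector(pyr, qv, thio, pv, FALSE)$rmsd
  withr::with_seed(31, {
    for (k in 1:5) {
      tr <- random_rigid()
      moved <- transform_conf(thio, tr$R, tr$t)
      expect_equal(align_one_vector(pyr, qv, moved, pv, FALSE)$rmsd, base,
        tolerance = 1e-6
      )
    }
  })
})

test_that("distance and angle bins clamp, saturate and stay monotone", {
  expect_equal(distance_bin(0.1), 0L)
  expect_equal(distance_bin(100), 17L)
  expect_equal(angle_bin(0), 0L)
  expect_equal(angle_bin(180), 5L)
  expect_error(distance_bin(-1), class = "ringhop_domain_error")
  expect_error(angle_bin(190), class = "ringhop_domain_error")

  d <- seq(0.01, 9, by = 0.01)
  bins <- distance_bin(d)
  expect_true(all(diff(bins) >= 0))
  expect_equal(sort(unique(bins)), 0:17)
  a_bins <- angle_bin(seq(0, 180, by = 0.5))
  expect_true(all(diff(a_bins) >= 0))
  expect_equal(sort(unique(a_bins)), 0:5)
})

test_that("the pair hash packs 5+3 bits and tolerates sub-bin perturbation", {
  expect_equal(pair_hash(0, 0), 0L)
  expect_equal(pair_hash(17, 5), 141L)
  expect_true(all(pair_hash(0:17, 5) <= 255))

  thio <- charged_conf("c1ccsc1")
  ev <- enumerate_exit_vectors(thio)
  pair <- ev[c(1, nrow(ev)), ]
  g <- vector_pair_geometry(thio, pair)
  # perturb d and alpha by less than half a bin width about the bin centre
  w_d <- (7.5 - 1.2) / 18
  centre_d <- 1.2 + (distance_bin(g$d) + 0.5) * w_d
  centre_a <- (angle_bin(g$alpha_v) + 0.5) * 30
  for (eps in c(-0.45, 0.45)) {
    expect_equal(distance_bin(centre_d + eps * w_d), distance_bin(g$d))
    expect_equal(angle_bin(centre_a + eps * 30), angle_bin(g$alpha_v))
  }
})

test_that("the hash index stores every unordered pair exactly once", {
  lib <- tiny_library(c("c1ccsc1", "c1ccncc1", "c1cc[nH]c1", "c1ccc2[nH]ccc2c1"))
  idx <- build_hash_index(lib)
  expected_pairs <- sum(choose(lib$exit_vector_count[lib$retained], 2))
  expect_equal(nrow(idx), expected_pairs)
  # self-retrieval: every entry appears under each of its own hashes
  for (rid in unique(idx$reg_id)) {
    for (h in idx$hash[idx$reg_id == rid]) {
      expect_true(rid %in% lookup_hash(idx, h)$reg_id)
    }
  }
  absent <- setdiff(0:255, idx$hash)[1]
  expect_equal(nrow(lookup_hash(idx, absent)), 0)
})

test_that("pair hashes are stable across re-embedding with the same seed", {
  thio1 <- embed_conformer("c1ccsc1", seed = 42L)
  thio2 <- embed_conformer("c1ccsc1", seed = 42L)
  ev1 <- enumerate_exit_vectors(thio1)
  ev2 <- enumerate_exit_vectors(thio2)
  g1 <- vector_pair_geometry(thio1, ev1[1:2, ])
  g2 <- vector_pair_geometry(thio2, ev2[1:2, ])
  expect_identical(g1$hash, g2$hash)
  expect_identical(g1$d, g2$d)
})
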