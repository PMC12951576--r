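# Parsing, exit-vector enumeration, conformer embedding, charge assignment
# and planarity checks.

test_that("parsing perceives structure and rejects bad input", {
  pyr <- parse_heterocycle("c1ccncc1")
  expect_equal(sum(pyr$atoms$element != "H"), 6)
  expect_equal(sum(pyr$aromatic), 6)
  expect_equal(pyr$formal_charge, 0)

  ind <- parse_heterocycle("c1ccc2[nH]ccc2c1")
  expect_equal(sum(ind$atoms$element != "H"), 9)
  expect_equal(sum(ind$atoms$element == "N"), 1)
  expect_equal(sum(ind$aromatic), 9)

  expect_error(parse_heterocycle("c1ccncc1("), class = "ringhop_parse_error")
  expect_error(parse_heterocycle(""), class = "ringhop_parse_error")
  expect_error(parse_heterocycle("CC(F)C"), class = "ringhop_parse_error") # no aromatic ring
  expect_error(
    parse_heterocycle("c1ccc(B(O)O)cc1", library_mode = TRUE),
    class = "ringhop_element_error"
  )
})

test_that("exit-vector enumeration matches a brute-force aromatic-H scan", {
  cases <- list(
    list(smiles = "c1ccncc1", c_type = 5, n_type = 0),   # pyridine
    list(smiles = "c1ccc2[nH]ccc2c1", c_type = 6, n_type = 1), # indole
    list(smiles = "c1ccccc1", c_type = 6, n_type = 0),
    list(smiles = "Cc1c(C)c(C)c(C)c(C)c1C", c_type = 0, n_type = 0) # fully substituted
  )
  for (cs in cases) {
    het <- parse_heterocycle(cs$smiles)
    ev <- enumerate_exit_vectors(het)
    expect_equal(sum(ev$element_class == "C"), cs$c_type, info = cs$smiles)
    expect_equal(sum(ev$element_class == "N"), cs$n_type, info = cs$smiles)
    expect_equal(ev$ring_atom, sort(ev$ring_atom))
    # oracle: scan every aromatic C/N and count attached hydrogens directly
    for (i in seq_len(nrow(het$atoms))) {
      if (het$aromatic[i] && het$atoms$element[i] %in% c("C", "N")) {
        nb <- c(het$bonds$a2[het$bonds$a1 == i], het$bonds$a1[het$bonds$a2 == i])
        n_h <- sum(het$atoms$element[nb] == "H")
        expect_equal(i %in% ev$ring_atom, n_h == 1, info = cs$smiles)
      }
    }
  }
})

test_that("embedding is deterministic and gives chemically sane geometry", {
  c1 <- embed_conformer("c1ccncc1", seed = 42L)
  c2 <- embed_conformer("c1ccncc1", seed = 42L)
  expect_identical(conf_coords(c1), conf_coords(c2))

  benz <- embed_conformer("c1ccccc1")
  ring <- which(benz$aromatic)
  expect_lt(oracle_plane_dev(conf_coords(benz)[ring, ]), 0.05)

  # pyridine ring C-C bonds near the force-field aromatic equilibrium length
  pyr <- embed_conformer("c1ccncc1")
  X <- conf_coords(pyr)
  el <- pyr$atoms$element
  ar <- pyr$bonds[pyr$bonds$order == "ar", ]
  cc <- ar[el[ar$a1] == "C" & el[ar$a2] == "C", ]
  lens <- sqrt(rowSums((X[cc$a1, , drop = FALSE] - X[cc$a2, , drop = FALSE])^2))
  expect_true(all(lens > 1.35 & lens < 1.45))
})

# Reference charges computed with an independent PEOE implementation
# (RDKit's ComputeGasteigerCharges), frozen at its printed precision.
.ref_charges <- list(
  "c1ccncc1" = c(-0.0592, -0.0438, 0.0267, -0.2647, 0.0267, -0.0438,
                 0.0624, 0.0639, 0.0840, 0.0840, 0.0639),
  "c1ccsc1" = c(-0.0515, -0.0515, -0.0093, -0.1525, -0.0093,
                0.0631, 0.0631, 0.0739, 0.0739),
  "c1ccoc1" = c(-0.0239, -0.0239, 0.0902, -0.4726, 0.0902,
                0.0657, 0.0657, 0.1043, 0.1043),
  "c1cc[nH]c1" = c(-0.0447, -0.0447, 0.0005, -0.3676, 0.0005,
                   0.0639, 0.0639, 0.0815, 0.1653, 0.0815),
  "COc1ccccn1" = c(0.0792, -0.4810, 0.2124, 0.0003, -0.0554, -0.0435,
                   0.0308, -0.2221, 0.0669, 0.0669, 0.0669, 0.0680,
                   0.0625, 0.0639, 0.0841),
  "Nc1ccsc1" = c(-0.3981, 0.0422, -0.0284, -0.0072, -0.1502, 0.0137,
                 0.1562, 0.1562, 0.0653, 0.0740, 0.0762),
  "CC(=O)n1cccc1" = c(0.0157, 0.2269, -0.2745, -0.2949, 0.0116, -0.0440,
                      -0.0440, 0.0116, 0.0331, 0.0331, 0.0331, 0.0823,
                      0.0639, 0.0639, 0.0823),
  "O=c1cc[nH]cc1" = c(-0.2898, 0.1810, 0.0015, 0.0043, -0.3674, 0.0043,
                      0.0015, 0.0679, 0.0817, 0.1653, 0.0817, 0.0679)
)

test_that("PEOE charges match an independent reference implementation", {
  for (smi in names(.ref_charges)) {
    conf <- charged_conf(smi)
    expect_equal(conf$atoms$charge, .ref_charges[[smi]],
      tolerance = 1e-3, info = smi
    )
  }
})

test_that("charge assignment respects symmetry and conserves total charge", {
  benz <- charged_conf("c1ccccc1")
  qc <- benz$atoms$charge[benz$atoms$element == "C"]
  expect_lt(diff(range(qc)), 1e-6)
  expect_lt(abs(sum(benz$atoms$charge)), 1e-3)

  pyr <- charged_conf("c1ccncc1")
  heavy <- pyr$atoms$element != "H"
  expect_equal(
    which.min(replace(pyr$atoms$charge, !heavy, Inf)),
    which(pyr$atoms$element == "N")
  )

  for (smi in fixture_library(12, seed = 4)) {
    conf <- charged_conf(smi)
    expect_lt(abs(sum(conf$atoms$charge) - conf$formal_charge), 1e-3)
  }
})

test_that("external charges validate length, total and model label", {
  conf <- embed_conformer("c1ccncc1")
  n <- nrow(conf$atoms)
  good <- rep(0, n)
  out <- assign_partial_charges(conf, "external", charges = good)
  expect_equal(out$charge_model, "external")
  expect_error(
    assign_partial_charges(conf, "external", charges = rep(0, n - 1)),
    class = "ringhop_charge_error"
  )
  expect_error(
    assign_partial_charges(conf, "external", charges = rep(0.1, n)),
    class = "ringhop_charge_error"
  )
  expect_error(
    assign_partial_charges(conf, "mulliken"),
    class = "ringhop_config_error"
  )
})

test_that("charge files round-trip through the import hook", {
  conf <- embed_conformer("c1ccsc1")
  q <- peoe_charges(conf)
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(seq_along(q), q), path)
  expect_equal(read_charge_file(path, length(q)), q)
  expect_error(read_charge_file(path, length(q) + 1),
    class = "ringhop_charge_error"
  )
})

test_that("planarity verdicts follow the least-squares plane and are rigid-motion invariant", {
  hexagon <- embed_conformer("c1ccccc1")
  expect_true(planarity_check(hexagon, threshold = 0.3))

  # constructed pucker: alternate ring atoms displaced +/- 0.25 A out of plane
  puckered <- hexagon
  ring <- which(hexagon$aromatic)
  puckered$atoms$z[ring] <- puckered$atoms$z[ring] +
    rep(c(0.25, -0.25), length.out = length(ring))
  expect_false(planarity_check(puckered, threshold = 0.1))

  # boundary convention: deviation exactly at the threshold passes
  flat <- hexagon
  flat$atoms$x[ring] <- cos(seq(0, 5) * pi / 3)
  flat$atoms$y[ring] <- sin(seq(0, 5) * pi / 3)
  flat$atoms$z[ring] <- 0
  dev <- 0.2
  flat$atoms$z[ring[1]] <- dev
  d_max <- oracle_plane_dev(conf_coords(flat)[ring, ])
  expect_true(planarity_check(flat, ring, threshold = d_max))
  expect_false(planarity_check(flat, ring, threshold = d_max - 1e-6))

  withr::with_seed(11, {
    for (k in 1:5) {
      tr <- random_rigid()
      moved <- transform_conf(puckered, tr$R, tr$t)
      expect_equal(
        planarity_check(moved, threshold = 0.1),
        planarity_check(puckered, threshold = 0.1)
      )
    }
  })

  expect_error(planarity_check(hexagon, ring_atom_indices = 1:3),
    class = "ringhop_geometry_error"
  )
})
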