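# One- and two-vector search orchestration and ranked output.

search_fixture <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) {
      lib <<- tiny_library(c(
        "c1ccncc1", "c1ccsc1", "c1ccoc1", "c1cc[nH]c1", "c1ccccc1",
        "c1cncnc1", "c1c[nH]cn1", "c1cnco1", "c1ccc2[nH]ccc2c1", "c1ccn2nccc2c1"
      ))
    }
    lib
  }
})

test_that("one-vector search returns the query at rank 1 with total 2", {
  lib <- search_fixture()
  res <- search_one_vector(lib, "c1ccncc1", vector_atom = 3)
  expect_s3_class(res, "ringhop_results")
  expect_equal(nrow(res), sum(lib$retained))
  expect_true(res$is_query[1])
  expect_equal(res$total[1], 2, tolerance = 1e-4)
  expect_equal(res$shape[1], 1, tolerance = 1e-4)
  expect_equal(res$esp[1], 1, tolerance = 1e-4)
  # ranking is by non-increasing total with rank 1 first
  expect_true(all(diff(res$total) <= 1e-12))
  expect_equal(res$rank, seq_len(nrow(res)))
})

test_that("one-vector search equals the brute-force loop over vectors and flips", {
  lib <- search_fixture()
  qsmiles <- "c1ccncc1"
  res <- search_one_vector(lib, qsmiles, vector_atom = 3, descriptors = FALSE)

  query <- charged_conf(qsmiles)
  qvec <- enumerate_exit_vectors(query)
  qvec <- qvec[qvec$ring_atom == 3, ]
  qprep <- ringhop:::prepare_query_scoring(query)
  for (i in seq_len(nrow(lib))) {
    if (!lib$retained[i]) next
    probe <- charged_conf(lib$smiles[i])
    ev <- enumerate_exit_vectors(probe)
    best <- -Inf
    for (v in seq_len(nrow(ev))) {
      for (flip in c(FALSE, TRUE)) {
        al <- align_one_vector(query, qvec, probe, ev[v, ], flip)
        sc <- ringhop:::score_alignment(qprep, probe, al, 1, 1)
        best <- max(best, sc$total)
      }
    }
    expect_equal(res$total[res$reg_id == lib$reg_id[i]], best,
      tolerance = 1e-9, info = lib$smiles[i]
    )
  }
})

test_that("search weights rescale the ranking score", {
  lib <- search_fixture()
  res_s <- search_one_vector(lib, "c1ccncc1", 3, w_shape = 1, w_esp = 0,
                             descriptors = FALSE)
  expect_equal(res_s$total, res_s$shape, tolerance = 1e-12)
  res_h <- search_one_vector(lib, "c1ccncc1", 3, w_shape = 0.5, w_esp = 0.5,
                             descriptors = FALSE)
  expect_true(all(res_h$total <= 1 + 1e-9))
  expect_error(
    search_one_vector(lib, "c1ccncc1", 3, w_shape = -1),
    class = "ringhop_config_error"
  )
  expect_error(
    search_one_vector(lib, "c1ccncc1", 4), # the N, not an exit-vector
    class = "ringhop_input_error"
  )
})

test_that("two-vector search retrieves the query and honours the hash gate", {
  lib <- search_fixture()
  res <- search_two_vector(lib, "c1ccsc1", vector_atoms = c(3, 5))
  expect_true(res$is_query[1])
  expect_equal(res$total[1], 2, tolerance = 1e-4)

  # scored entries are exactly the reg_ids in the query's hash bucket
  idx <- build_hash_index(lib)
  query <- charged_conf("c1ccsc1")
  qev <- enumerate_exit_vectors(query)
  qpair <- qev[qev$ring_atom %in% c(3, 5), ]
  g <- vector_pair_geometry(query, qpair)
  bucket_ids <- sort(unique(lookup_hash(idx, g$hash)$reg_id))
  expect_equal(sort(res$reg_id), bucket_ids)

  # a probe whose only pair hash differs is absent
  absent <- setdiff(lib$reg_id[lib$retained & lib$exit_vector_count >= 2],
                    bucket_ids)
  if (length(absent)) {
    expect_false(any(absent %in% res$reg_id))
  }
})

test_that("with bins collapsed to one the hash-gated search equals exhaustive pairing", {
  lib <- search_fixture()
  res1 <- search_two_vector(lib, "c1ccsc1", c(3, 5), descriptors = FALSE,
                            n_dist_bins = 1L, n_angle_bins = 1L)
  # exhaustive: every entry with >= 2 exit-vectors, every pair, both orders
  query <- charged_conf("c1ccsc1")
  qev <- enumerate_exit_vectors(query)
  qpair <- qev[qev$ring_atom %in% c(3, 5), ]
  qprep <- ringhop:::prepare_query_scoring(query)
  manual <- list()
  for (i in which(lib$retained & lib$exit_vector_count >= 2)) {
    probe <- charged_conf(lib$smiles[i])
    ev <- enumerate_exit_vectors(probe)
    cmb <- utils::combn(nrow(ev), 2)
    best <- -Inf
    for (c_i in seq_len(ncol(cmb))) {
      for (ord in c(FALSE, TRUE)) {
        al <- align_two_vector(query, qpair, probe, ev[cmb[, c_i], ], ord)
        best <- max(best, ringhop:::score_alignment(qprep, probe, al, 1, 1)$total)
      }
    }
    manual[[as.character(lib$reg_id[i])]] <- best
  }
  expect_setequal(res1$reg_id, as.integer(names(manual)))
  for (rid in res1$reg_id) {
    expect_equal(res1$total[res1$reg_id == rid], manual[[as.character(rid)]],
      tolerance = 1e-9
    )
  }
})

test_that("results round-trip through CSV and SDF output", {
  lib <- search_fixture()
  res <- search_one_vector(lib, "c1ccncc1", 3)
  dir <- withr::local_tempdir()
  paths <- write_results(res, dir, top_n = 50)

  csv <- readr::read_csv(paths$csv, show_col_types = FALSE)
  expect_equal(csv$rank, res$rank)
  expect_equal(csv$smiles, res$smiles)
  expect_equal(csv$total, res$total, tolerance = 1e-12)

  sdf_lines <- readLines(paths$sdf)
  expect_equal(sum(sdf_lines == "$$$$"), min(50, nrow(res)))

  # rank-1 self-match coordinates coincide with the query conformer (the
  # library entry uses canonical atom order, so compare as point sets)
  first_block <- sdf_lines[seq_len(which(sdf_lines == "$$$$")[1])]
  natoms <- as.integer(substr(first_block[4], 1, 3))
  coords <- as.matrix(utils::read.table(
    text = paste(first_block[5:(4 + natoms)], collapse = "\n")
  )[, 1:3])
  qX <- conf_coords(charged_conf("c1ccncc1"))
  expect_equal(natoms, nrow(qX))
  for (i in seq_len(nrow(qX))) {
    d <- sqrt(rowSums(sweep(coords, 2, qX[i, ])^2))
    expect_lt(min(d), 0.01)
  }

  small <- res[1:10, ]
  paths2 <- write_results(small, withr::local_tempdir(), top_n = 50)
  expect_equal(sum(readLines(paths2$sdf) == "$$$$"), 10)
})

test_that("runtime grows roughly linearly with library size", {
  sizes <- c(8, 16, 32)
  times <- vapply(sizes, function(n) {
    lib <- tiny_library(fixture_library(n, seed = 2))
    as.numeric(system.time(
      search_one_vector(lib, "c1ccncc1", 3, descriptors = FALSE)
    )["elapsed"])
  }, numeric(1))
  # trend check only: doubling the library should not quadruple the time
  expect_lt(times[3] / max(times[1], 0.05), 16)
})
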