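# Retrospective analysis of shape/ESP weighting against bioactivity, and
# enrichment-factor evaluation of ranked retrieval.

#' Pearson product-moment correlation with input validation
#'
#' Thin wrapper over [stats::cor()] that enforces the preconditions used
#' throughout the series analysis (equal lengths of at least 3, nonzero
#' variance in both variables).
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("need equal-length vectors with at least 3 observations",
      class = "ringhop_stats_error"
    )
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    rlang::abort("zero variance input", class = "ringhop_stats_error")
  }
  stats::cor(x, y)
}

weight_objective <- function(w, records) {
  combo <- w * records$shape + (1 - w) * records$esp
  if (stats::var(combo) == 0) return(-Inf)
  stats::cor(combo, records$pic50)
}

#' Optimize shape/ESP weights against bioactivity
#'
#' Finds the convex weighting `(w_shape, w_esp)` with `w_shape + w_esp = 1`
#' that maximizes the Pearson correlation between the weighted total score
#' and pIC50 across a ligand series. The one-dimensional constrained problem
#' is solved by bounded gradient-based optimization from multiple starts,
#' with the equal-weight point always included as a candidate so the
#' optimized correlation never falls below the equal-weight correlation; if
#' the gradient-based solve fails, an exhaustive 0.001-step grid is used.
#'
#' @param records A data frame with numeric columns `shape`, `esp` (scores in
#'   \[0, 1\] against the series reference) and `pic50`.
#' @return An object of class `weight_fit` with elements `w_shape`, `w_esp`,
#'   `r` (achieved Pearson correlation), `r_equal` (correlation at equal
#'   weights), `n`, and the input `records`. [generics::tidy()] and
#'   [generics::glance()] methods are provided.
#' @export
optimize_weights <- function(records) {
  stopifnot(all(c("shape", "esp", "pic50") %in% names(records)))
  if (nrow(records) < 3) {
    rlang::abort("need at least 3 series records", class = "ringhop_stats_error")
  }
  if (stats::var(records$pic50) == 0) {
    rlang::abort("pIC50 values have zero variance", class = "ringhop_stats_error")
  }
  if (any(records$shape < 0 | records$shape > 1 |
          records$esp < 0 | records$esp > 1)) {
    rlang::abort("shape and esp scores must lie in [0, 1]",
      class = "ringhop_stats_error"
    )
  }
  candidates <- c(0, 0.5, 1)
  for (start in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    fit <- tryCatch(
      stats::optim(start, function(w) -weight_objective(w, records),
        method = "L-BFGS-B", lower = 0, upper = 1
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) candidates <- c(candidates, fit$par)
  }
  if (length(candidates) == 3) {
    candidates <- c(candidates, seq(0, 1, by = 0.001))
  }
  vals <- vapply(candidates, weight_objective, numeric(1), records = records)
  w <- candidates[which.max(vals)]
  structure(
    list(
      w_shape = w, w_esp = 1 - w,
      r = max(vals),
      r_equal = weight_objective(0.5, records),
      n = nrow(records),
      records = tibble::as_tibble(records)
    ),
    class = "weight_fit"
  )
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf(
    "<weight_fit> w_shape = %.3f, w_esp = %.3f, r = %.3f (equal-weight r = %.3f, n = %d)\n",
    x$w_shape, x$w_esp, x$r, x$r_equal, x$n
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.weight_fit <- function(x, ...) {
  tibble::tibble(
    term = c("w_shape", "w_esp"),
    estimate = c(x$w_shape, x$w_esp)
  )
}

#' @export
glance.weight_fit <- function(x, ...) {
  tibble::tibble(
    pearson_r = x$r, r_equal_weights = x$r_equal, n = x$n
  )
}

#' Enrichment factors of a ranked retrieval
#'
#' For each cutoff (a top-N count if > 1, a top fraction if <= 1) the
#' enrichment factor is the proportion of known actives recovered in the
#' cutoff relative to the proportion expected from a random draw:
#' `EF = (retrieved / cutoff_size) / (n_actives / n_ranked)`. An EF of 1 is
#' chance performance; the EF at the 100% cutoff is exactly 1 for any
#' ranking.
#'
#' @param ranked_ids Vector of identifiers in rank order (best first).
#' @param active_ids Identifiers of the known actives (must all appear in
#'   `ranked_ids`).
#' @param cutoffs Numeric vector of cutoffs (counts > 1, fractions <= 1).
#' @return An `enrichment_table` tibble with columns `cutoff`, `cutoff_size`,
#'   `retrieved`, `ef`.
#' @export
enrichment_factor <- function(ranked_ids, active_ids,
                              cutoffs = c(10, 25, 50, 100, 0.10, 0.25, 0.50,
                                          0.75, 1.00)) {
  if (length(active_ids) == 0) {
    rlang::abort("no actives supplied", class = "ringhop_stats_error")
  }
  if (!all(active_ids %in% ranked_ids)) {
    rlang::abort("all actives must appear in the ranked list",
      class = "ringhop_stats_error"
    )
  }
  n <- length(ranked_ids)
  n_act <- length(unique(active_ids))
  rows <- purrr::map(cutoffs, function(ct) {
    size <- if (ct <= 1) as.integer(floor(ct * n)) else as.integer(ct)
    size <- min(size, n)
    retrieved <- sum(ranked_ids[seq_len(size)] %in% active_ids)
    tibble::tibble(
      cutoff = if (ct <= 1) paste0(round(100 * ct), "%") else paste0("top ", ct),
      cutoff_size = size,
      retrieved = retrieved,
      ef = (retrieved / size) / (n_act / n)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("enrichment_table", class(out)))
}

#' Train/test stability of optimized weights
#'
#' Repeatedly splits the series records into train/test partitions, fits the
#' shape/ESP weighting on the training part and evaluates the Pearson
#' correlation of the weighted score with pIC50 on the held-out part.
#'
#' @param records As in [optimize_weights()] (at least 6 rows).
#' @param n_splits Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.8).
#' @param seed RNG seed; results are deterministic for a fixed seed.
#' @return A tibble with one row per split: `split`, `w_shape`, `w_esp`,
#'   `r_train`, `r_test`; mean and standard deviation of `r_test` are stored
#'   in `attr(x, "summary")`.
#' @export
train_test_stability <- function(records, n_splits = 100L, train_frac = 0.8,
                                 seed = 1L) {
  if (nrow(records) < 6) {
    rlang::abort("need at least 6 records for train/test splitting",
      class = "ringhop_stats_error"
    )
  }
  n <- nrow(records)
  n_train <- max(3L, floor(train_frac * n))
  if (n - n_train < 3) n_train <- n - 3L
  rows <- withr::with_seed(seed, {
    purrr::map(seq_len(n_splits), function(s) {
      idx <- sample(n, n_train)
      fit <- optimize_weights(records[idx, , drop = FALSE])
      test <- records[-idx, , drop = FALSE]
      combo <- fit$w_shape * test$shape + fit$w_esp * test$esp
      r_test <- if (stats::var(combo) == 0 || stats::var(test$pic50) == 0) {
        NA_real_
      } else {
        stats::cor(combo, test$pic50)
      }
      tibble::tibble(
        split = s, w_shape = fit$w_shape, w_esp = fit$w_esp,
        r_train = fit$r, r_test = r_test
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "summary") <- tibble::tibble(
    mean_r_test = mean(out$r_test, na.rm = TRUE),
    sd_r_test = stats::sd(out$r_test, na.rm = TRUE)
  )
  out
}

#' Score a ligand series against its reference fragment
#'
#' Convenience wrapper producing [optimize_weights()] input from raw series
#' data: each variable fragment is aligned to the reference fragment (the
#' most potent ligand's fragment) through the designated exit-vector and
#' scored for shape and ESP similarity.
#'
#' @param series A data frame with columns `smiles` and `pic50`.
#' @param reference Reference fragment SMILES (the series query).
#' @param vector_atom Exit-vector ring atom index on the reference.
#' @param seed Embedding seed.
#' @return A tibble with columns `smiles`, `shape`, `esp`, `pic50`.
#' @export
score_series <- function(series, reference, vector_atom, seed = 42L) {
  stopifnot(all(c("smiles", "pic50") %in% names(series)))
  lib <- tibble::tibble(
    reg_id = seq_len(nrow(series)),
    smiles = canonical_smiles(series$smiles),
    generation = "seed",
    exit_vector_count = NA_integer_,
    filter_flags = replicate(nrow(series), character(), simplify = FALSE),
    retained = TRUE
  )
  res <- search_one_vector(lib, reference, vector_atom, seed = seed,
                           descriptors = FALSE)
  m <- match(res$reg_id, lib$reg_id)
  tibble::tibble(
    smiles = series$smiles[m],
    shape = res$shape,
    esp = res$esp,
    pic50 = series$pic50[m]
  )
}
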