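make_raw <- function(nl, nh, L, M, seed, gamma = NULL, noise = 0.2,
                     msa_obj = NULL) {
  if (is.null(msa_obj)) {
    msa_obj <- withr::with_seed(seed,
      msa(matrix(sample.int(4L, M * L, replace = TRUE), M, L),
          alphabet = LETTERS[1:4]))
  }
  spec <- surrogate_spec(n_layers = nl, n_heads = nh, gamma = gamma,
                         noise_scale = noise, seed = seed + 1L)
  list(msa = msa_obj, raw = surrogate_attentions(msa_obj, spec))
}

test_that("aggregation averages symmetrized maps over all columns including BOS", {
  ## all columns equal to one symmetric row-stochastic matrix S -> output S
  M <- 5
  S <- matrix(1 / M, M, M)
  tensor <- array(0, dim = c(1, 1, 4, M, M))
  for (j in 1:4) tensor[1, 1, j, , ] <- S
  stack <- aggregate_attentions(column_attention_set(tensor))
  expect_equal(stack$matrices[1, 1, , ], S)

  ## asymmetric maps contribute only their symmetric part
  withr::with_seed(3, A <- matrix(runif(M * M), M, M))
  A <- A / rowSums(A)
  t2 <- array(0, dim = c(1, 1, 2, M, M))
  t2[1, 1, 1, , ] <- A
  t2[1, 1, 2, , ] <- A
  st2 <- aggregate_attentions(column_attention_set(t2))
  expect_equal(st2$matrices[1, 1, , ], (A + t(A)) / 2)

  ## random tensor vs naive summation oracle
  x <- make_raw(2, 2, 3, 4, seed = 11)
  st <- aggregate_attentions(x$raw)
  for (l in 1:2) for (h in 1:2) {
    acc <- matrix(0, 4, 4)
    for (j in 1:4) {
      Aj <- x$raw$tensor[l, h, j, , ]
      acc <- acc + Aj + t(Aj)
    }
    expect_equal(st$matrices[l, h, , ], acc / (2 * 4), tolerance = 1e-12)
  }
})

test_that("pair features are raster-ordered, symmetric, and reject self-pairs", {
  x <- make_raw(3, 4, 5, 6, seed = 21)
  st <- aggregate_attentions(x$raw)
  f <- pair_features(st, 2, 5)
  expect_length(f, 12)
  expect_equal(f, pair_features(st, 5, 2))
  expect_equal(f[(2 - 1) * 4 + 3], st$matrices[2, 3, 2, 5])  # (l=2, h=3)
  expect_error(pair_features(st, 3, 3), "self-pairs")

  one <- attention_stack(array(matrix(0.5, 2, 2), dim = c(1, 1, 2, 2)))
  expect_equal(pair_features(one, 1, 2), 0.5)
})

test_that("fractional logit recovers closed forms and planted parameters", {
  ## zero features: intercept-only closed form logit(mean y)
  y <- c(0.1, 0.3, 0.5, 0.2, 0.4)
  f0 <- fit_fractional_logit(matrix(0, 5, 0), y)
  expect_equal(f0$intercept, qlogis(mean(y)), tolerance = 1e-8)

  ## constant y = 0.5: all coefficients vanish
  withr::with_seed(31, F1 <- matrix(rnorm(40), 20, 2))
  f1 <- fit_fractional_logit(F1, rep(0.5, 20))
  expect_equal(f1$intercept, 0, tolerance = 1e-8)
  expect_equal(f1$coefficients, c(0, 0), tolerance = 1e-8)

  ## noiseless planted parameters are recovered
  withr::with_seed(32, {
    F2 <- matrix(rnorm(600), 200, 3)
    beta <- c(0.8, -1.2, 0.4)
    y2 <- plogis(-0.3 + F2 %*% beta)
  })
  f2 <- fit_fractional_logit(F2, as.vector(y2))
  expect_equal(f2$intercept, -0.3, tolerance = 1e-3)
  expect_equal(f2$coefficients, beta, tolerance = 1e-3)

  ## responses at exactly 0 (duplicate sequences) are legal
  f3 <- fit_fractional_logit(F2[1:50, ], c(rep(0, 10), as.vector(y2)[11:50]))
  expect_true(is.finite(f3$intercept))

  ## perfectly collinear features are an error
  F4 <- cbind(1:10, 2 * (1:10))
  expect_error(fit_fractional_logit(F4, runif(10)), "collinear")
})

test_that("predicted distance matrices respect the link function and symmetry", {
  x <- make_raw(2, 2, 4, 5, seed = 41)
  st <- aggregate_attentions(x$raw)
  zero_model <- structure(list(intercept = 0, coefficients = rep(0, 4)),
                          class = "fractional_logit")
  P <- predict_distances(zero_model, st)
  expect_equal(P[upper.tri(P)], rep(0.5, 10))
  expect_equal(diag(P), rep(0, 5))

  low <- structure(list(intercept = -30, coefficients = rep(0, 4)),
                   class = "fractional_logit")
  expect_lt(max(predict_distances(low, st)), 1e-10)

  ## hand scalar case: sigma(b0 + b1 * a)
  one <- attention_stack(array(matrix(0.5, 2, 2), dim = c(1, 1, 2, 2)))
  m1 <- structure(list(intercept = 0.2, coefficients = 1.4),
                  class = "fractional_logit")
  expect_equal(predict_distances(m1, one)[1, 2], plogis(0.2 + 1.4 * 0.5))
})

test_that("split protocol partitions rows and pairs as documented", {
  sp <- split_protocol(10, 0.7, seed = 51)
  expect_length(sp$train_rows, 7)
  expect_length(sp$test_rows, 3)
  expect_equal(nrow(sp$train_pairs), choose(7, 2))
  expect_equal(nrow(sp$test_pairs), choose(3, 2))
  expect_length(intersect(sp$train_rows, sp$test_rows), 0)
  expect_error(split_protocol(10, 1.0), "fewer than 2")
  expect_identical(split_protocol(10, 0.7, seed = 51), sp)
})

test_that("r_squared and slope_diagnostic match their closed forms", {
  y <- c(0.2, 0.5, 0.9)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(y, rep(mean(y), 3)), 0)
  pred <- c(0.1, 0.6, 0.7)
  expect_equal(r_squared(y, pred),
               1 - sum((y - pred)^2) / sum((y - mean(y))^2))
  expect_error(r_squared(rep(0.3, 3), pred), "constant")

  expect_equal(slope_diagnostic(y, y), 1)
  expect_equal(slope_diagnostic(y, y / 2), 2)
  withr::with_seed(61, {
    p <- runif(50)
    t <- 0.3 + 0.7 * p + rnorm(50, sd = 0.05)
  })
  expect_equal(slope_diagnostic(t, p), cov(t, p) / var(p), tolerance = 1e-10)
  expect_equal(slope_diagnostic(t, p), unname(coef(lm(t ~ p))[2]),
               tolerance = 1e-10)
  expect_error(slope_diagnostic(y, rep(0.4, 3)), "constant")
})

test_that("cross-MSA fit pools within-MSA pairs and matches single-MSA fits", {
  x <- make_raw(2, 2, 6, 10, seed = 71, noise = 0.1)
  st <- aggregate_attentions(x$raw)
  single <- cross_msa_fit(list(x$msa), list(st))
  pairs <- phylopotts:::row_pairs(1:10)
  direct <- fit_fractional_logit(phylopotts:::feature_matrix(st, pairs),
                                 hamming_matrix(x$msa)[pairs])
  expect_equal(single$coefficients, direct$coefficients, tolerance = 1e-8)

  ## k copies of the same MSA share the optimum of one copy
  twice <- cross_msa_fit(list(x$msa, x$msa), list(st, st))
  expect_equal(twice$coefficients, single$coefficients, tolerance = 1e-6)
  expect_equal(twice$intercept, single$intercept, tolerance = 1e-6)

  y <- make_raw(3, 2, 6, 10, seed = 72)
  expect_error(cross_msa_fit(list(x$msa, y$msa),
                             list(st, aggregate_attentions(y$raw))),
               "same")
})

test_that("per-column predictions symmetrize single columns and degenerate to the aggregate", {
  ## all columns carrying identical attentions: per-column = aggregate
  M <- 5
  withr::with_seed(81, A <- matrix(runif(M * M) + 0.1, M, M))
  A <- A / rowSums(A)
  tensor <- array(0, dim = c(1, 1, 3, M, M))
  for (j in 1:3) tensor[1, 1, j, , ] <- A
  raw <- column_attention_set(tensor)
  st <- aggregate_attentions(raw)
  model <- structure(list(intercept = -0.5, coefficients = 2),
                     class = "fractional_logit")
  for (j in 0:2) {
    expect_equal(per_column_predict(model, raw, j),
                 predict_distances(model, st), tolerance = 1e-12)
  }
  expect_error(per_column_predict(model, raw, 7), "0..")

  ## antisymmetric perturbations leave per-column predictions unchanged
  eps <- matrix(0, M, M)
  eps[1, 2] <- 0.01
  eps[2, 1] <- -0.01
  t2 <- tensor
  t2[1, 1, 2, , ] <- A + eps
  raw2 <- column_attention_set(t2, check = FALSE)
  expect_equal(per_column_predict(model, raw2, 1),
               per_column_predict(model, raw, 1), tolerance = 1e-12)
})

test_that("signal surrogates give high held-out R2; noise surrogates give none", {
  gen <- planted_potts(planted_spec(L = 18, q = 6, n_contacts = 3,
                                    coupling_scale = 2.5, field_scale = 0.3,
                                    seed = 91))
  tr <- random_tree(60, "yule", height = 0.6, seed = 92)
  ms <- sample_along_tree(gen$model, tr, mcmc_config(seed = 93))
  D <- hamming_matrix(ms)
  sp <- split_protocol(60, 0.7, seed = 94)

  sig <- surrogate_attentions(ms, surrogate_spec(4, 4, noise_scale = 0.25,
                                                 seed = 95))
  st <- aggregate_attentions(sig)
  fit <- fit_fractional_logit(phylopotts:::feature_matrix(st, sp$train_pairs),
                              D[sp$train_pairs])
  ev <- evaluate_distance_model(fit, ms, st, sp$test_pairs)
  expect_gt(ev$r2, 0.8)
  expect_gt(ev$pearson, 0.9)

  noise <- surrogate_attentions(ms, surrogate_spec(4, 4, gamma = matrix(0, 4, 4),
                                                   noise_scale = 0.25, seed = 96))
  stn <- aggregate_attentions(noise)
  fitn <- fit_fractional_logit(phylopotts:::feature_matrix(stn, sp$train_pairs),
                               D[sp$train_pairs])
  evn <- evaluate_distance_model(fitn, ms, stn, sp$test_pairs)
  expect_lt(abs(evn$r2), 0.15)
})

test_that("monotonicity: raising a positively weighted feature raises the prediction", {
  st <- attention_stack(array(matrix(0.3, 3, 3) + diag(3) * 0.1,
                              dim = c(1, 1, 3, 3)))
  model <- structure(list(intercept = -1, coefficients = 2.5),
                     class = "fractional_logit")
  base <- predict_distances(model, st)[1, 2]
  bumped <- st
  bumped$matrices[1, 1, 1, 2] <- bumped$matrices[1, 1, 2, 1] <-
    bumped$matrices[1, 1, 1, 2] + 0.2
  expect_gt(predict_distances(model, bumped)[1, 2], base)
})
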