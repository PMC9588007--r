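test_that("roc_auc matches exhaustive pair counting and handles ties by midrank", {
  L <- 12
  S <- matrix(0, L, L)
  truth <- rbind(c(1, 7), c(2, 8))
  S[1, 7] <- S[7, 1] <- 5
  S[2, 8] <- S[8, 2] <- 4
  expect_equal(roc_auc(S, truth), 1)           # truth strictly on top
  S2 <- -S
  expect_equal(roc_auc(S2, truth), 0)          # reversed ranking

  ## 4 candidate pairs, one tie between a truth and a non-truth pair
  el <- rbind(c(1, 7), c(2, 8), c(3, 9), c(4, 10))
  S3 <- matrix(0, L, L)
  S3[1, 7] <- S3[7, 1] <- 3
  S3[2, 8] <- S3[8, 2] <- 1
  S3[3, 9] <- S3[9, 3] <- 1
  S3[4, 10] <- S3[10, 4] <- 0
  tr3 <- rbind(c(1, 7), c(2, 8))
  ## enumeration: (1,7) beats both negatives; (2,8) ties (3,9), beats (4,10)
  manual <- (1 + 1 + 0.5 + 1) / 4
  expect_equal(roc_auc(S3, tr3, eligible = el), manual)

  ## independent oracle: pROC on the same labels/scores
  lab <- c(1, 1, 0, 0)
  sc <- c(3, 1, 1, 0)
  expect_equal(roc_auc(S3, tr3, eligible = el),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))))

  expect_error(roc_auc(S3, matrix(numeric(), 0, 2), eligible = el), "empty")
  expect_error(roc_auc(S3, el, eligible = el), "equals")
})

test_that("roc_auc is invariant under strictly increasing transforms and centered at 1/2 for noise", {
  withr::with_seed(5, {
    L <- 15
    el <- phylopotts:::eligible_pairs(L, 4)
    truth <- el[sample.int(nrow(el), 8), ]
    S <- matrix(0, L, L)
    v <- runif(nrow(el))
    S[el] <- v
    S[el[, 2:1]] <- v
    a1 <- roc_auc(S, truth)
    S2 <- matrix(0, L, L)
    S2[el] <- exp(3 * v)
    S2[el[, 2:1]] <- exp(3 * v)
    expect_equal(roc_auc(S2, truth), a1)

    aucs <- replicate(500, {
      Sr <- matrix(0, L, L)
      vr <- runif(nrow(el))
      Sr[el] <- vr
      Sr[el[, 2:1]] <- vr
      roc_auc(Sr, truth)
    })
    se <- sd(aucs) / sqrt(length(aucs))
    expect_lt(abs(mean(aucs) - 0.5), 3 * se + 0.01)
  })
})

test_that("phylogeny impact reproduces the published arithmetic", {
  expect_equal(phylogeny_impact(0.7, 0.7), 0)
  expect_equal(round(phylogeny_impact(0.87, 0.58), 2), 0.33)
  expect_equal(round(phylogeny_impact(0.81, 0.82), 2), -0.01)
  expect_error(phylogeny_impact(0, 0.5), "auc_eq")
  ## sign property
  expect_gt(phylogeny_impact(0.9, 0.8), 0)
  expect_lt(phylogeny_impact(0.8, 0.9), 0)
})

test_that("subsample-averaged scores equal the mean of the per-subsample matrices", {
  withr::with_seed(7, m <- msa(matrix(sample.int(3L, 40 * 6, replace = TRUE), 40, 6),
                               alphabet = LETTERS[1:3]))
  ## toy scorer: column-mean outer product (fast, deterministic)
  scorer <- function(sub) {
    v <- colMeans(sub$matrix)
    S <- outer(v, v)
    diag(S) <- 0
    (S + t(S)) / 2
  }
  res <- subsample_average_scores(m, scorer, n_sub = 5, m_sub = 20, seed = 8)
  mats <- attr(res, "subsample_scores")
  expect_length(mats, 5)
  expect_equal(res$scores, Reduce(`+`, mats) / 5, tolerance = 1e-12)
  rows <- attr(res, "subsample_rows")
  expect_true(all(vapply(rows, length, integer(1)) == 20))

  ## n_sub = 1, m_sub = M reduces to direct scoring
  res1 <- subsample_average_scores(m, scorer, n_sub = 1, m_sub = 40, seed = 9)
  expect_equal(res1$scores, {
    S <- scorer(m)
    S
  }, tolerance = 1e-12)

  ## constant scorer returns its constant
  const <- function(sub) matrix(0.3, 6, 6) - diag(6) * 0.3
  resc <- subsample_average_scores(m, const, n_sub = 3, m_sub = 10, seed = 10)
  expect_equal(resc$scores, matrix(0.3, 6, 6) - diag(6) * 0.3)

  expect_error(subsample_average_scores(m, scorer, m_sub = 41), "exceeds")
  ## auto-reduction for shallow MSAs: floor(0.8 * 40) = 32 rows
  res_auto <- subsample_average_scores(m, scorer, n_sub = 2, seed = 11)
  expect_true(all(vapply(attr(res_auto, "subsample_rows"), length,
                         integer(1)) == 32))
})

test_that("ground-truth pairs are the generator's own top APC couplings", {
  pl <- planted_potts(planted_spec(L = 30, q = 4, n_contacts = 8,
                                   coupling_scale = 2, seed = 13))
  gt <- ground_truth_pairs(pl$model, 8)
  expect_equal(gt[order(gt$i, gt$j), c("i", "j")],
               pl$pairs[order(pl$pairs$i, pl$pairs$j), ], ignore_attr = TRUE)
  expect_equal(nrow(ground_truth_pairs(pl$model, 2 * 30)), 60)
  manual <- top_pairs(apc(frobenius_scores(pl$model)), 8)
  expect_identical(ground_truth_pairs(pl$model, 8), manual)
})

test_that("distance matrix correlation matches the direct formula on upper triangles", {
  withr::with_seed(17, {
    M <- 10
    d1 <- matrix(runif(M * M), M, M)
    d1 <- (d1 + t(d1)) / 2
    diag(d1) <- 0
  })
  expect_equal(distance_matrix_correlation(d1, d1), 1)
  expect_equal(distance_matrix_correlation(d1, max(d1) - d1 - diag(max(d1), M)),
               -1, tolerance = 1e-12)
  withr::with_seed(18, {
    d2 <- matrix(runif(M * M), M, M)
    d2 <- (d2 + t(d2)) / 2
    diag(d2) <- 0
  })
  ut <- upper.tri(d1)
  expect_equal(distance_matrix_correlation(d1, d2), cor(d1[ut], d2[ut]),
               tolerance = 1e-12)
  expect_error(distance_matrix_correlation(matrix(0, 3, 3), d1[1:3, 1:3]),
               "constant|shape")
})

test_that("the disentangling driver is seed-deterministic and self-consistent", {
  gen <- planted_potts(planted_spec(L = 12, q = 3, n_contacts = 3,
                                    coupling_scale = 2.5, field_scale = 0.3,
                                    seed = 19))
  tr <- random_tree(120, "yule", height = 0.6, seed = 20)
  cfg <- plm_config(tol = 1e-5, max_iter = 500)
  r1 <- run_disentangling_experiment(gen$model, tr, n_truth = 3, plm = cfg,
                                     mcmc = mcmc_config(seed = 21))
  r2 <- run_disentangling_experiment(gen$model, tr, n_truth = 3, plm = cfg,
                                     mcmc = mcmc_config(seed = 21))
  expect_identical(r1$auc, r2$auc)
  ## delta always equals the hand formula on the stored AUCs
  expect_equal(r1$auc$delta,
               (r1$auc$auc_eq - r1$auc$auc_tree) / r1$auc$auc_eq)
  expect_equal(nrow(r1$auc), 2)
  expect_equal(r1$auc$k, c(3, 24))
})

test_that("benchmark AUC table loads with the expected shape", {
  tab <- pfam_benchmark_aucs()
  expect_equal(nrow(tab), 60)
  expect_equal(sort(unique(tab$method)), c("msa_transformer", "plmdca"))
  expect_equal(sort(unique(tab$cutoff)), c("2L", "N"))
  expect_equal(length(unique(tab$family)), 15)
  expect_true(all(tab$auc_eq > 0 & tab$auc_eq <= 1))
})
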