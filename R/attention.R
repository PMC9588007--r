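## Fractional-logit regression of pairwise Hamming distances on column
## attentions.
##
## Raw column attentions form a tensor indexed (layer l, head h, column j,
## sequence i, sequence i'), j = 0..L where j = 0 is the column of the
## prepended beginning-of-sequence (BOS) token; every M x M slice is
## row-stochastic.  Aggregated per-head features are the symmetrized,
## column-averaged matrices
##   A^(l,h) = 1 / (2 (L + 1)) * sum_j (A_j + A_j^T),
## and the Hamming distance y between sequences i and i' is modelled as
##   E[y | a] = sigma(beta_0 + a beta^T)
## with a the vector of A^(l,h)[i, i'] entries in layer-major raster order,
## fitted by Bernoulli quasi-maximum likelihood (a GLM with binomial
## family, logit link, and responses in [0, 1]).

#' Construct a column-attention tensor object
#'
#' @param tensor 5-d numeric array with dimensions
#'   `(n_layers, n_heads, L + 1, M, M)`; slice `[l, h, j, , ]` is the
#'   row-stochastic attention matrix of head `(l, h)` at column `j - 1`
#'   (the first slice, `j = 1`, is the BOS column).
#' @param check Validate row-stochasticity within `1e-6` (default TRUE).
#' @return Object of class `"column_attention_set"`.
#' @export
column_attention_set <- function(tensor, check = TRUE) {
  d <- dim(tensor)
  if (length(d) != 5L || d[4L] != d[5L]) {
    stop("`tensor` must be a (n_layers, n_heads, L + 1, M, M) array")
  }
  if (d[3L] < 2L) stop("tensor must include the BOS column plus at least one site")
  if (check) {
    if (any(tensor < 0)) stop("attention entries must be >= 0")
    rs <- apply(tensor, c(1L, 2L, 3L, 4L), sum)
    if (max(abs(rs - 1)) > 1e-6) {
      stop("every attention row must sum to 1 (max deviation ",
           signif(max(abs(rs - 1)), 3), ")")
    }
  }
  structure(list(tensor = tensor, n_layers = d[1L], n_heads = d[2L],
                 L = d[3L] - 1L, M = d[4L]),
            class = "column_attention_set")
}

#' Aggregate raw column attentions into symmetric per-head matrices
#'
#' Averages the symmetrized attention maps over all columns including the
#' BOS column: `A^(l,h) = 1/(2(L+1)) sum_{j=0}^{L} (A_j + A_j^T)`.
#'
#' @param raw A [column_attention_set].
#' @return An `"attention_stack"`: list with `matrices` (array
#'   `(n_layers, n_heads, M, M)`, each slice symmetric), `n_layers`,
#'   `n_heads`, `M`.
#' @export
aggregate_attentions <- function(raw) {
  stopifnot(inherits(raw, "column_attention_set"))
  nl <- raw$n_layers
  nh <- raw$n_heads
  M <- raw$M
  ncol_j <- raw$L + 1L
  out <- array(0, dim = c(nl, nh, M, M))
  for (l in seq_len(nl)) {
    for (h in seq_len(nh)) {
      acc <- matrix(0, M, M)
      for (j in seq_len(ncol_j)) {
        Aj <- raw$tensor[l, h, j, , ]
        acc <- acc + Aj + t(Aj)
      }
      out[l, h, , ] <- acc / (2 * ncol_j)
    }
  }
  attention_stack(out)
}

#' Construct an attention stack from symmetric per-head matrices
#'
#' @param matrices Array `(n_layers, n_heads, M, M)` of symmetric slices.
#' @return An `"attention_stack"` object.
#' @export
attention_stack <- function(matrices) {
  d <- dim(matrices)
  if (length(d) != 4L || d[3L] != d[4L]) {
    stop("`matrices` must be a (n_layers, n_heads, M, M) array")
  }
  for (l in seq_len(d[1L])) {
    for (h in seq_len(d[2L])) {
      if (max(abs(matrices[l, h, , ] - t(matrices[l, h, , ]))) > 1e-9) {
        stop("attention stack slices must be symmetric (layer ", l,
             ", head ", h, ")")
      }
    }
  }
  structure(list(matrices = matrices, n_layers = d[1L], n_heads = d[2L],
                 M = d[3L]),
            class = "attention_stack")
}

#' Per-pair feature vector from an attention stack
#'
#' Entries `A^(l,h)[i, i']` in layer-major raster order (`k = (l-1) *
#' n_heads + h`); symmetric in `(i, i')`.
#'
#' @param stack An `"attention_stack"`.
#' @param i,ip Distinct sequence indices.
#' @return Numeric vector of length `n_layers * n_heads`.
#' @export
pair_features <- function(stack, i, ip) {
  stopifnot(inherits(stack, "attention_stack"))
  if (i == ip) stop("self-pairs (i == i') are not regression observations")
  as.vector(t(stack$matrices[, , i, ip]))
}

## Feature matrix for a set of unordered pairs (2-column index matrix).
feature_matrix <- function(stack, pairs) {
  nl <- stack$n_layers
  nh <- stack$n_heads
  K <- nl * nh
  F <- matrix(0, nrow(pairs), K)
  for (l in seq_len(nl)) {
    for (h in seq_len(nh)) {
      slice <- stack$matrices[l, h, , ]
      F[, (l - 1L) * nh + h] <- slice[pairs]
    }
  }
  F
}

## All unordered pairs among `rows`, as a 2-column matrix (i < i').
row_pairs <- function(rows) {
  rows <- sort(rows)
  if (length(rows) < 2L) stop("need at least 2 rows to form pairs")
  t(utils::combn(rows, 2L))
}

#' Fit a fractional logit model
#'
#' Maximizes the summed Bernoulli quasi-log-likelihood
#' `y log G + (1 - y) log(1 - G)` with `G = sigma(beta0 + a beta^T)` over
#' responses `y` in `[0, 1]`.  This is the quasi-binomial GLM with logit
#' link; the objective is concave, so the IRLS optimum is unique.
#' Perfectly collinear feature columns are an error.
#'
#' @param features Numeric matrix, one row per (unordered) sequence pair.
#' @param y Responses in `[0, 1]` (normalized Hamming distances).
#' @return Object of class `"fractional_logit"` with elements `intercept`,
#'   `coefficients`, and bookkeeping fields.
#' @export
fit_fractional_logit <- function(features, y) {
  features <- as.matrix(features)
  if (length(y) != nrow(features)) stop("length(y) must match nrow(features)")
  if (any(!is.finite(features))) stop("features must be finite")
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  if (nrow(features) < ncol(features) + 1L) {
    stop("need at least ", ncol(features) + 1L, " pairs to fit ",
         ncol(features), " coefficients plus an intercept")
  }
  Xd <- cbind(1, features)
  if (qr(Xd)$rank < ncol(Xd)) {
    stop("feature matrix is rank-deficient (perfectly collinear columns)")
  }
  fit <- glm.fit(Xd, y, family = quasibinomial("logit"),
                 control = list(epsilon = 1e-10, maxit = 100))
  cf <- fit$coefficients
  structure(list(intercept = unname(cf[1L]),
                 coefficients = unname(cf[-1L]),
                 converged = fit$converged,
                 n_obs = nrow(features)),
            class = "fractional_logit")
}

#' @export
print.fractional_logit <- function(x, ...) {
  cat(sprintf("fractional logit: %d coefficients, intercept %.4f (fit on %d pairs)\n",
              length(x$coefficients), x$intercept, x$n_obs))
  invisible(x)
}

#' Predict a pairwise distance matrix from an attention stack
#'
#' Applies `sigma(beta0 + a beta^T)` to the feature vector of every pair;
#' the diagonal is reported as 0 by convention.
#'
#' @param model A `"fractional_logit"`.
#' @param stack An `"attention_stack"` whose head count matches the model.
#' @return Symmetric M x M matrix with entries in `(0, 1)` off the diagonal.
#' @export
predict_distances <- function(model, stack) {
  stopifnot(inherits(model, "fractional_logit"), inherits(stack, "attention_stack"))
  K <- stack$n_layers * stack$n_heads
  if (length(model$coefficients) != K) {
    stop("model has ", length(model$coefficients), " coefficients but stack has ",
         K, " heads")
  }
  M <- stack$M
  pairs <- row_pairs(seq_len(M))
  eta <- model$intercept + feature_matrix(stack, pairs) %*% model$coefficients
  P <- matrix(0, M, M)
  P[pairs] <- plogis(eta)
  P <- P + t(P)
  diag(P) <- 0
  P
}

#' Train/test split over MSA rows
#'
#' Partitions the sequence indices at random; training observations are all
#' unordered pairs within the training rows, test observations all pairs
#' within the test rows.  Cross pairs are unused.
#'
#' @param M Number of sequences (or an [msa] object).
#' @param frac Fraction of rows assigned to training (default 0.7).
#' @param seed Optional integer seed for a reproducible split.
#' @return List with `train_rows`, `test_rows`, `train_pairs`, `test_pairs`.
#' @export
split_protocol <- function(M, frac = 0.7, seed = NULL) {
  if (inherits(M, "msa")) M <- nrow(M$matrix)
  if (M < 4L) stop("need at least 4 sequences to split")
  n_train <- floor(frac * M)
  if (n_train < 2L || M - n_train < 2L) {
    stop("split leaves fewer than 2 rows on one side (frac = ", frac, ")")
  }
  train_rows <- sort(with_seed(seed, sample.int(M, n_train)))
  test_rows <- setdiff(seq_len(M), train_rows)
  list(train_rows = train_rows, test_rows = test_rows,
       train_pairs = row_pairs(train_rows), test_pairs = row_pairs(test_rows))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` of predictions against ground truth.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_true` must vary.
#' @return A single number (1 for perfect prediction, 0 for the mean
#'   predictor, negative when worse than the mean).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("`y_true` is constant; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Slope of truth regressed on prediction
#'
#' Ordinary least-squares slope of `y_true ~ y_pred`; 1 for calibrated
#' predictions, > 1 when predictions are compressed toward the mean.
#'
#' @param y_true,y_pred Equal-length numeric vectors; `y_pred` must vary.
#' @return The OLS slope.
#' @export
slope_diagnostic <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) < 2L) stop("need at least 2 observations")
  if (sd(y_pred) == 0) stop("constant predictions; slope undefined")
  stats::cov(y_true, y_pred) / stats::var(y_pred)
}

#' Fit one fractional logit model across several MSAs
#'
#' Pools all within-MSA pairs (never cross-MSA pairs) from the training
#' MSAs into a single quasi-likelihood fit, mirroring the "universal
#' model" protocol: one set of coefficients shared across families.
#'
#' @param msas List of [msa] objects.
#' @param stacks List of matching `"attention_stack"` objects (identical
#'   `(n_layers, n_heads)` across entries).
#' @return A `"fractional_logit"`.
#' @export
cross_msa_fit <- function(msas, stacks) {
  stopifnot(length(msas) >= 1L, length(msas) == length(stacks))
  shapes <- vapply(stacks, function(s) c(s$n_layers, s$n_heads), integer(2L))
  if (any(shapes[1L, ] != shapes[1L, 1L]) || any(shapes[2L, ] != shapes[2L, 1L])) {
    stop("all stacks must share the same (n_layers, n_heads)")
  }
  feats <- list()
  ys <- list()
  for (k in seq_along(msas)) {
    pairs <- row_pairs(seq_len(nrow(msas[[k]]$matrix)))
    feats[[k]] <- feature_matrix(stacks[[k]], pairs)
    D <- hamming_matrix(msas[[k]])
    ys[[k]] <- D[pairs]
  }
  fit_fractional_logit(do.call(rbind, feats), unlist(ys))
}

#' Evaluate a distance model on one MSA
#'
#' @param model A `"fractional_logit"`.
#' @param msa An [msa]; ground-truth distances are its Hamming matrix.
#' @param stack Matching `"attention_stack"`.
#' @param pairs Optional 2-column matrix of pairs to evaluate (default:
#'   all unordered pairs).
#' @return List with `r2`, `pearson`, `slope`, and the `truth`/`predicted`
#'   vectors.
#' @export
evaluate_distance_model <- function(model, msa, stack, pairs = NULL) {
  if (is.null(pairs)) pairs <- row_pairs(seq_len(nrow(msa$matrix)))
  truth <- hamming_matrix(msa)[pairs]
  pred <- as.vector(plogis(model$intercept +
                             feature_matrix(stack, pairs) %*% model$coefficients))
  list(r2 = r_squared(truth, pred),
       pearson = cor(truth, pred),
       slope = slope_diagnostic(truth, pred),
       truth = truth, predicted = pred)
}

## Symmetrized single-column attention stack for column j (0 = BOS).
single_column_stack <- function(raw, j) {
  stopifnot(inherits(raw, "column_attention_set"))
  if (j < 0L || j > raw$L) stop("column index must lie in 0..", raw$L)
  nl <- raw$n_layers
  nh <- raw$n_heads
  M <- raw$M
  out <- array(0, dim = c(nl, nh, M, M))
  for (l in seq_len(nl)) {
    for (h in seq_len(nh)) {
      Aj <- raw$tensor[l, h, j + 1L, , ]
      out[l, h, , ] <- (Aj + t(Aj)) / 2
    }
  }
  attention_stack(out)
}

#' Predict distances from a single column's attentions
#'
#' Uses a model trained on aggregated features, but feeds it the
#' symmetrized attention matrices of one column only.
#'
#' @param model A `"fractional_logit"` trained on aggregated features.
#' @param raw A [column_attention_set].
#' @param j Column index, `0` (BOS) to `L`.
#' @return Symmetric M x M prediction matrix.
#' @export
per_column_predict <- function(model, raw, j) {
  predict_distances(model, single_column_stack(raw, j))
}

#' Standard deviation of per-column prediction errors
#'
#' For each alignment column, predicts all pairwise distances from that
#' column's attentions alone and reports the standard deviation of
#' (prediction - truth) over the given pairs.  Conserved (low-entropy)
#' columns are expected to yield the most stable predictions.
#'
#' @param model A `"fractional_logit"`.
#' @param raw A [column_attention_set].
#' @param truth Symmetric M x M matrix of ground-truth distances.
#' @param pairs Optional 2-column pair matrix (default: all pairs).
#' @param columns Columns to evaluate (default `1..L`, skipping BOS).
#' @return Named numeric vector of error standard deviations per column.
#' @export
error_std_by_column <- function(model, raw, truth, pairs = NULL,
                                columns = seq_len(raw$L)) {
  if (is.null(pairs)) pairs <- row_pairs(seq_len(raw$M))
  y <- truth[pairs]
  vapply(columns, function(j) {
    pred <- per_column_predict(model, raw, j)[pairs]
    sd(pred - y)
  }, numeric(1L))
}
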