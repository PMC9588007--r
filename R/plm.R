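## Pseudo-likelihood inference of Potts models from MSAs.
##
## For every site r, the conditional distribution of its state given the
## rest of the sequence is multinomial-logistic with logits
##   z_r(a | x) = h_r(a) + sum_{j != r} e_rj(a, x_j).
## The (asymmetric) pseudo-likelihood objective is the weighted sum over
## sequences and sites of -log P(x_r | x_-r), normalized by the effective
## depth, plus l2 penalties on fields and couplings.  It is smooth and
## convex, so a quasi-Newton optimizer reaches the unique optimum from any
## start; the two estimates of e_ij obtained from the conditionals at i and
## at j are averaged afterwards (symmetrization).  All sites are fitted
## jointly in one L-BFGS run so that the heavy lifting is a pair of dense
## matrix products per objective evaluation.

#' Pseudo-likelihood fit configuration
#'
#' @param lambda_fields,lambda_couplings l2 regularization strengths
#'   (default `1e-2` each, the standard choice for contact inference).
#' @param delta Reweighting threshold for [sequence_weights()] (default 0.2).
#' @param tol Convergence tolerance on the projected gradient norm
#'   (per-component, default `1e-5`).
#' @param max_iter Maximum L-BFGS iterations (default 500).
#' @return Object of class `"plm_config"`.
#' @export
plm_config <- function(lambda_fields = 1e-2, lambda_couplings = 1e-2,
                       delta = 0.2, tol = 1e-5, max_iter = 500L) {
  stopifnot(lambda_fields >= 0, lambda_couplings >= 0, delta > 0,
            tol > 0, max_iter >= 1)
  structure(list(lambda_fields = lambda_fields,
                 lambda_couplings = lambda_couplings,
                 delta = delta, tol = tol, max_iter = as.integer(max_iter)),
            class = "plm_config")
}

#' Fit a Potts model by penalized pseudo-likelihood
#'
#' @param msa An [msa] object with at least 2 sequences and 2 sites.
#' @param config A [plm_config].
#' @param weights Optional precomputed [sequence_weights()] result; by
#'   default weights are recomputed at `config$delta`.
#' @return A [potts_model] with symmetrized couplings.
#' @export
fit_plm <- function(msa, config = plm_config(), weights = NULL) {
  stopifnot(inherits(msa, "msa"))
  M <- nrow(msa$matrix)
  L <- ncol(msa$matrix)
  q <- length(msa$alphabet)
  if (M < 2L || L < 2L) stop("pseudo-likelihood fitting needs M >= 2 and L >= 2")
  if (is.null(weights)) weights <- sequence_weights(msa, config$delta)
  w <- weights$weights
  b_eff <- sum(w)

  X <- one_hot(msa$matrix, q)                      # M x Lq, site-major columns
  K <- L * q
  n_par <- K + K * K

  ## indices of the diagonal (self-coupling) blocks inside the K x K matrix
  diag_mask <- matrix(FALSE, K, K)
  for (i in seq_len(L)) {
    idx <- seq.int((i - 1L) * q + 1L, i * q)
    diag_mask[idx, idx] <- TRUE
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return()
    hv <- par[seq_len(K)]
    Jm <- matrix(par[-seq_len(K)], K, K)
    Z <- X %*% Jm
    Z <- sweep(Z, 2L, hv, "+")
    Z3 <- array(Z, dim = c(M, q, L))
    mx <- Z3[, 1L, , drop = TRUE]
    if (L == 1L) mx <- matrix(mx, M, 1L)
    for (a in seq.int(2L, q)) mx <- pmax(mx, Z3[, a, , drop = TRUE])
    Ssum <- matrix(0, M, L)
    P <- array(0, dim = c(M, q, L))
    for (a in seq_len(q)) {
      Ea <- exp(Z3[, a, , drop = TRUE] - mx)
      P[, a, ] <- Ea
      Ssum <- Ssum + Ea
    }
    for (a in seq_len(q)) P[, a, ] <- P[, a, ] / Ssum
    obs <- rowSums(X * Z)                          # sum_i z(x_i) per sequence
    ll <- sum(w * obs) - sum(w * rowSums(mx + log(Ssum)))
    Pm <- matrix(P, M, K)                          # back to site-major columns
    R <- (Pm - X) * w                              # row-scaled residuals
    gJ <- crossprod(X, R) / b_eff + 2 * config$lambda_couplings * Jm
    gJ[diag_mask] <- 0
    gH <- colSums(R) / b_eff + 2 * config$lambda_fields * hv
    cache$par <- par
    cache$value <- -ll / b_eff +
      config$lambda_fields * sum(hv^2) +
      config$lambda_couplings * sum(Jm[!diag_mask]^2)
    cache$grad <- c(gH, as.vector(gJ))
    invisible()
  }
  fn <- function(par) { evaluate(par); cache$value }
  gr <- function(par) { evaluate(par); cache$grad }

  fit <- optim(rep(0, n_par), fn, gr, method = "L-BFGS-B",
               control = list(maxit = config$max_iter, pgtol = config$tol,
                              factr = 1e7))
  if (fit$convergence == 1L) {
    gnorm <- max(abs(gr(fit$par)))
    stop("pseudo-likelihood fit did not converge in ", config$max_iter,
         " iterations (max |gradient| = ", signif(gnorm, 3), ")")
  }

  hv <- fit$par[seq_len(K)]
  Jm <- matrix(fit$par[-seq_len(K)], K, K)
  Jms <- (Jm + t(Jm)) / 2                          # symmetrization
  fields <- matrix(hv, nrow = q)                   # q x L, column i = h_i(.)
  J <- array(0, dim = c(L, L, q, q))
  for (i in seq_len(L - 1L)) {
    ri <- seq.int((i - 1L) * q + 1L, i * q)
    for (j in seq.int(i + 1L, L)) {
      rj <- seq.int((j - 1L) * q + 1L, j * q)
      J[i, j, , ] <- Jms[ri, rj]
      J[j, i, , ] <- t(Jms[ri, rj])
    }
  }
  potts_model(t(fields), J, alphabet = msa$alphabet)
}

#' Coupling scores from an MSA
#'
#' The standard DCA contact-scoring pipeline: fit fields and couplings by
#' penalized pseudo-likelihood, move to the zero-sum gauge, take
#' Frobenius norms of the coupling blocks, and apply the average product
#' correction.
#'
#' @inheritParams fit_plm
#' @return A `coupling_scores` object with `apc = TRUE`.
#' @export
coupling_scores <- function(msa, config = plm_config(), weights = NULL) {
  model <- fit_plm(msa, config, weights)
  apc(frobenius_scores(model))
}
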