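## Potts models: Hamiltonian, exact Boltzmann distribution on small
## instances, zero-sum gauge, Frobenius-norm coupling scores and the
## average product correction.
##
## A Potts model over sequences of length L with q states per site is
## parameterized by per-site fields h_i(a) and pairwise couplings
## e_ij(a, b); its Hamiltonian is
##   H(x) = - sum_i h_i(x_i) - sum_{i<j} e_ij(x_i, x_j),
## and sequence probabilities follow the Boltzmann law P(x) = exp(-H)/Z.
## Couplings are stored as a full L x L x q x q array with the symmetry
## J[j, i, b, a] == J[i, j, a, b] enforced, each unordered pair entering
## H exactly once.

#' Construct a Potts model
#'
#' @param fields Numeric L x q matrix of fields `h_i(a)`.
#' @param couplings Numeric L x L x q x q array; entry `[i, j, a, b]` is
#'   `e_ij(a, b)`.  Only the blocks with `i < j` are read; the symmetric
#'   counterparts and zero diagonal blocks are filled in.  May be `NULL`
#'   for an independent-site model.
#' @param alphabet Optional symbol vector of length q (defaults to
#'   [aa_alphabet()] when q = 21, otherwise the first q letters).
#'
#' @return Object of class `"potts_model"` with elements `fields`
#'   (L x q), `couplings` (L x L x q x q), `L`, `q`.
#' @export
potts_model <- function(fields, couplings = NULL, alphabet = NULL) {
  fields <- as.matrix(fields)
  L <- nrow(fields)
  q <- ncol(fields)
  if (!all(is.finite(fields))) stop("fields must be finite")
  J <- array(0, dim = c(L, L, q, q))
  if (!is.null(couplings)) {
    if (!identical(dim(couplings), as.integer(c(L, L, q, q)))) {
      stop("`couplings` must be an L x L x q x q array")
    }
    if (!all(is.finite(couplings))) stop("couplings must be finite")
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        blk <- couplings[i, j, , ]
        if (all(blk == 0) && any(couplings[j, i, , ] != 0)) {
          blk <- t(couplings[j, i, , ])
        }
        J[i, j, , ] <- blk
        J[j, i, , ] <- t(blk)
      }
    }
  }
  if (is.null(alphabet)) {
    alphabet <- if (q == 21L) aa_alphabet() else LETTERS[seq_len(q)]
  }
  stopifnot(length(alphabet) == q)
  structure(list(fields = fields, couplings = J, L = L, q = q,
                 alphabet = alphabet),
            class = "potts_model")
}

#' @export
print.potts_model <- function(x, ...) {
  nz <- coupled_pairs(x)
  cat(sprintf("Potts model: L = %d sites, q = %d states, %d non-zero coupling block(s)\n",
              x$L, x$q, nrow(nz)))
  invisible(x)
}

## Unordered pairs (i < j) whose coupling block is not identically zero.
coupled_pairs <- function(model, tol = 0) {
  L <- model$L
  out <- NULL
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      if (max(abs(model$couplings[i, j, , ])) > tol) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) out <- matrix(integer(), 0, 2)
  colnames(out) <- c("i", "j")
  out
}

#' Potts Hamiltonian of a sequence
#'
#' `H(x) = - sum_i h_i(x_i) - sum_{i<j} e_ij(x_i, x_j)`.
#'
#' @param model A [potts_model].
#' @param x Integer vector of length L with codes in `1..q`.
#' @return The energy, a single number.
#' @export
hamiltonian <- function(model, x) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L
  q <- model$q
  x <- as.integer(x)
  if (length(x) != L) stop("sequence length must equal L = ", L)
  if (any(x < 1L | x > q)) stop("sequence codes must lie in 1..q")
  e <- -sum(model$fields[cbind(seq_len(L), x)])
  if (L > 1L) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        e <- e - model$couplings[i, j, x[i], x[j]]
      }
    }
  }
  e
}

## Energy difference for changing site `site` from state a to state b,
## computed incrementally from the couplings touching that site.
hamiltonian_delta <- function(model, x, site, new_state) {
  a <- x[site]
  b <- new_state
  d <- -(model$fields[site, b] - model$fields[site, a])
  others <- setdiff(seq_len(model$L), site)
  if (length(others)) {
    xo <- x[others]
    d <- d - sum(model$couplings[cbind(site, others, b, xo)] -
                 model$couplings[cbind(site, others, a, xo)])
  }
  d
}

#' Exact Boltzmann distribution of a small Potts model
#'
#' Enumerates all `q^L` sequences and returns their normalized Boltzmann
#' probabilities.  Intended for testing samplers and gauge transforms on
#' enumerable instances.
#'
#' @param model A [potts_model].
#' @param limit Maximum number of states to enumerate (default `1e6`).
#' @return A list with `states` (q^L x L integer matrix) and `prob`
#'   (probabilities summing to 1).
#' @export
exact_distribution <- function(model, limit = 1e6) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L
  q <- model$q
  n <- q^L
  if (n > limit) {
    stop("q^L = ", n, " exceeds the enumeration limit (", limit,
         "); use the MCMC sampler instead")
  }
  states <- as.matrix(do.call(expand.grid, rep(list(seq_len(q)), L)))
  dimnames(states) <- NULL
  storage.mode(states) <- "integer"
  H <- numeric(n)
  for (i in seq_len(L)) H <- H - model$fields[i, states[, i]]
  if (L > 1L) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        blk <- model$couplings[i, j, , ]
        H <- H - blk[cbind(states[, i], states[, j])]
      }
    }
  }
  w <- exp(-(H - min(H)))
  list(states = states, prob = w / sum(w))
}

#' Transform a Potts model to the zero-sum gauge
#'
#' Re-parameterizes the model so that every coupling block has zero row
#' and column means (and every field vector zero mean), without changing
#' the Boltzmann distribution: the removed coupling means are absorbed
#' into the fields, and constant offsets into the normalization.
#'
#' @param model A [potts_model].
#' @return A [potts_model] in the zero-sum gauge.
#' @export
zero_sum_gauge <- function(model) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L
  q <- model$q
  J <- model$couplings
  h <- model$fields
  h2 <- h
  J2 <- array(0, dim = dim(J))
  if (L > 1L) {
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        if (i == j) next
        blk <- J[i, j, , ]                       # e_ij(a, b), a indexes site i
        rm <- rowMeans(blk)                      # mean over b for each a
        gm <- mean(blk)
        ## field at i absorbs the b-averaged coupling (counted once per pair)
        h2[i, ] <- h2[i, ] + (rm - gm)
      }
    }
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        blk <- J[i, j, , ]
        blk2 <- sweep(sweep(blk, 1L, rowMeans(blk)), 2L, colMeans(blk)) + mean(blk)
        J2[i, j, , ] <- blk2
        J2[j, i, , ] <- t(blk2)
      }
    }
  }
  h2 <- sweep(h2, 1L, rowMeans(h2))
  out <- potts_model(h2, J2, alphabet = model$alphabet)
  out
}

#' Frobenius-norm coupling scores
#'
#' Transforms the model to the zero-sum gauge and returns, for every pair
#' of sites, the Frobenius norm of the coupling block over all q states
#' (gap included).
#'
#' @param model A [potts_model].
#' @return A `coupling_scores` object: list with `scores` (symmetric L x L,
#'   zero diagonal), `gauge = "zero_sum"` and `apc = FALSE`.
#' @export
frobenius_scores <- function(model) {
  g <- zero_sum_gauge(model)
  L <- g$L
  S <- matrix(0, L, L)
  if (L > 1L) {
    for (i in seq_len(L - 1L)) {
      for (j in seq.int(i + 1L, L)) {
        S[i, j] <- S[j, i] <- sqrt(sum(g$couplings[i, j, , ]^2))
      }
    }
  }
  coupling_scores_matrix(S, gauge = "zero_sum", apc = FALSE)
}

#' Construct a coupling-score matrix object
#'
#' @param scores Symmetric numeric matrix with zero diagonal.
#' @param gauge,apc Metadata flags recording how the scores were produced.
#' @return Object of class `"coupling_scores"`.
#' @export
coupling_scores_matrix <- function(scores, gauge = NA_character_, apc = FALSE) {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) stop("`scores` must be square")
  if (max(abs(scores - t(scores))) > 1e-8) stop("`scores` must be symmetric")
  diag(scores) <- 0
  structure(list(scores = scores, gauge = gauge, apc = apc),
            class = "coupling_scores")
}

#' @export
print.coupling_scores <- function(x, ...) {
  cat(sprintf("coupling scores: %d x %d (gauge: %s, APC: %s)\n",
              nrow(x$scores), ncol(x$scores), x$gauge, x$apc))
  invisible(x)
}

#' Average product correction (APC)
#'
#' Subtracts the product of row and column means divided by the grand mean
#' from each score, removing multiplicative per-site background before
#' contact ranking: `E_ij = F_ij - F_i. * F_.j / F..`.
#'
#' @param scores A `coupling_scores` object or a symmetric matrix.
#' @param diag Whether the means are taken over off-diagonal entries only
#'   (`"exclude"`, the convention used in the coupling-score pipeline) or
#'   over full rows (`"include"`, under which a genuinely rank-one matrix
#'   `u u^T` is annihilated exactly).
#' @return A `coupling_scores` object with `apc = TRUE`.
#' @export
apc <- function(scores, diag = c("exclude", "include")) {
  diag <- match.arg(diag)
  obj <- if (inherits(scores, "coupling_scores")) scores else
    coupling_scores_matrix(scores)
  S <- if (inherits(scores, "coupling_scores")) scores$scores else as.matrix(scores)
  if (max(abs(S - t(S))) > 1e-8) stop("APC input must be symmetric")
  L <- nrow(S)
  if (diag == "exclude") {
    So <- S
    base::diag(So) <- NA
    rm <- rowMeans(So, na.rm = TRUE)
    gm <- mean(So, na.rm = TRUE)
  } else {
    rm <- rowMeans(S)
    gm <- mean(S)
  }
  E <- if (gm == 0) matrix(0, L, L) else S - outer(rm, rm) / gm
  base::diag(E) <- 0
  coupling_scores_matrix((E + t(E)) / 2, gauge = obj$gauge, apc = TRUE)
}

#' Top-scoring site pairs
#'
#' Returns the `k` highest-scoring unordered pairs `(i, j)` with
#' `|i - j| > min_separation`, ranked by score with deterministic
#' lexicographic tie-breaking on `(i, j)`.
#'
#' @param scores A `coupling_scores` object or symmetric matrix.
#' @param k Number of pairs to return.
#' @param min_separation Minimum `|i - j|` exclusion (default 4: pairs
#'   with `|i - j| <= 4` are discarded).
#' @return Data frame with columns `i`, `j`, `score`, ordered by
#'   decreasing score.
#' @export
top_pairs <- function(scores, k, min_separation = 4L) {
  S <- if (inherits(scores, "coupling_scores")) scores$scores else as.matrix(scores)
  L <- nrow(S)
  el <- eligible_pairs(L, min_separation)
  if (k > nrow(el)) {
    stop("k = ", k, " exceeds the ", nrow(el), " eligible pairs")
  }
  sc <- S[el]
  ord <- order(-sc, el[, 1L], el[, 2L])
  sel <- ord[seq_len(k)]
  data.frame(i = el[sel, 1L], j = el[sel, 2L], score = sc[sel])
}

## All unordered pairs i < j with j - i > min_separation, as a 2-column matrix.
eligible_pairs <- function(L, min_separation = 4L) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] > min_separation, , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}

#' Serialize a Potts model to JSON
#'
#' Plain-text container with named entries (`L`, `q`, `alphabet`, `fields`,
#' `couplings`), round-tripping at full double precision.
#'
#' @param model A [potts_model].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_potts <- function(model, path) {
  stopifnot(inherits(model, "potts_model"))
  obj <- list(L = model$L, q = model$q, alphabet = model$alphabet,
              fields = model$fields,
              couplings = as.vector(model$couplings))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a Potts model from JSON
#'
#' @param path Path written by [write_potts()].
#' @return A [potts_model].
#' @export
read_potts <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- obj$L
  q <- obj$q
  J <- array(obj$couplings, dim = c(L, L, q, q))
  potts_model(matrix(unlist(obj$fields), L, q), J, alphabet = obj$alphabet)
}
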