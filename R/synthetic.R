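## Synthetic-data generators: planted Potts models, random phylogenies,
## surrogate attention tensors with a known Hamming-distance link, and a
## small deterministic fixture suite.  These give every pipeline stage a
## fully self-contained test surface.

#' Specification of a planted Potts model
#'
#' @param L,q Sequence length and alphabet size.
#' @param n_contacts Number of coupled site pairs to plant.
#' @param coupling_scale Frobenius norm of each planted coupling block
#'   (after zero-sum projection).
#' @param field_scale Standard deviation of the i.i.d. Gaussian fields.
#' @param min_separation Planted pairs satisfy `|i - j| > min_separation - 1`
#'   (default 5, i.e. `|i - j| >= 5`, matching the `|i - j| <= 4` exclusion
#'   used in contact ranking).
#' @param seed Optional integer seed.
#' @return Object of class `"planted_spec"`.
#' @export
planted_spec <- function(L, q, n_contacts, coupling_scale = 1,
                         field_scale = 0.5, min_separation = 5L, seed = NULL) {
  stopifnot(L >= 2, q >= 2, n_contacts >= 0, coupling_scale >= 0,
            field_scale >= 0)
  structure(list(L = L, q = q, n_contacts = n_contacts,
                 coupling_scale = coupling_scale, field_scale = field_scale,
                 min_separation = as.integer(min_separation), seed = seed),
            class = "planted_spec")
}

#' Generate a Potts model with planted couplings
#'
#' Draws `n_contacts` site pairs uniformly among pairs separated by at
#' least `min_separation`, gives each a random coupling block projected to
#' the zero-sum gauge and rescaled to Frobenius norm `coupling_scale`, sets
#' all other couplings to zero, and draws fields i.i.d. Gaussian.  The
#' planted pairs are therefore exactly the top coupling scores of the
#' generator.
#'
#' @param spec A [planted_spec].
#' @return List with `model` (a [potts_model]) and `pairs` (data frame of
#'   planted pairs `i < j`).
#' @export
planted_potts <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  L <- spec$L
  q <- spec$q
  el <- eligible_pairs(L, spec$min_separation - 1L)
  if (spec$n_contacts > nrow(el)) {
    stop("cannot plant ", spec$n_contacts, " contacts: only ", nrow(el),
         " pairs with |i - j| >= ", spec$min_separation)
  }
  with_seed(spec$seed, {
    fields <- matrix(stats::rnorm(L * q, sd = spec$field_scale), L, q)
    J <- array(0, dim = c(L, L, q, q))
    sel <- el[sample.int(nrow(el), spec$n_contacts), , drop = FALSE]
    sel <- sel[order(sel[, 1L], sel[, 2L]), , drop = FALSE]
    for (r in seq_len(nrow(sel))) {
      blk <- matrix(stats::rnorm(q * q), q, q)
      blk <- sweep(sweep(blk, 1L, rowMeans(blk)), 2L, colMeans(blk)) + mean(blk)
      nrm <- sqrt(sum(blk^2))
      if (nrm > 0) blk <- blk * (spec$coupling_scale / nrm)
      J[sel[r, 1L], sel[r, 2L], , ] <- blk
    }
    list(model = potts_model(fields, J),
         pairs = data.frame(i = sel[, 1L], j = sel[, 2L]))
  })
}

#' Random phylogeny
#'
#' Either a Yule (pure-birth) tree with exponential waiting times, or a
#' complete balanced binary topology with uniform branch lengths.  Branch
#' lengths are finally rescaled so that the mean root-to-leaf path length
#' equals `height` (expected substitutions per site).
#'
#' @param n_leaves Number of leaves (a power of two for `kind = "balanced"`).
#' @param kind `"yule"` or `"balanced"`.
#' @param height Target mean root-to-leaf path length (default 0.75).
#' @param birth_rate Birth rate of the Yule process before rescaling
#'   (default 1; affects topology-relative branch lengths only).
#' @param seed Optional integer seed.
#' @return An `ape` `phylo` object with `n_leaves` tips.
#' @export
random_tree <- function(n_leaves, kind = c("yule", "balanced"), height = 0.75,
                        birth_rate = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(n_leaves >= 2, height >= 0)
  tr <- with_seed(seed, {
    if (kind == "yule") {
      ape::rphylo(n_leaves, birth = birth_rate, death = 0)
    } else {
      if (abs(log2(n_leaves) - round(log2(n_leaves))) > 1e-9) {
        stop("`n_leaves` must be a power of two for a balanced tree")
      }
      t0 <- ape::stree(n_leaves, type = "balanced")
      t0$edge.length <- rep(1, nrow(t0$edge))
      t0
    }
  })
  depths <- ape::node.depth.edgelength(tr)
  mean_depth <- mean(depths[seq_len(n_leaves)])
  if (mean_depth > 0) tr$edge.length <- tr$edge.length * (height / mean_depth)
  tr$tip.label <- paste0("t", seq_len(n_leaves))
  tr
}

#' Specification of surrogate attention tensors
#'
#' @param n_layers,n_heads Tensor shape (defaults 12 x 12).
#' @param gamma `n_layers x n_heads` matrix of signal strengths: the
#'   pre-softmax logit of head `(l, h)` at column `j` is
#'   `gamma[l, h] * match_j(i, i') + noise`, where `match_j` indicates
#'   equal residues at column `j`.  Zero entries give pure-noise heads;
#'   negative entries make the head attend to similar sequences.  The
#'   default plants two positive and two negative signal heads in the
#'   early layers, echoing the mixed-sign structure seen in trained
#'   MSA language models.
#' @param noise_scale Standard deviation of the centered Gaussian logit
#'   noise (default 0.25).
#' @param seed Optional integer seed.
#' @return Object of class `"surrogate_spec"`.
#' @export
surrogate_spec <- function(n_layers = 12L, n_heads = 12L, gamma = NULL,
                           noise_scale = 0.25, seed = NULL) {
  stopifnot(n_layers >= 1, n_heads >= 1, noise_scale >= 0)
  if (is.null(gamma)) {
    gamma <- matrix(0, n_layers, n_heads)
    gamma[1L, min(5L, n_heads)] <- 2
    gamma[1L, min(6L, n_heads)] <- -2
    gamma[min(2L, n_layers), min(3L, n_heads)] <- 1.5
    gamma[min(3L, n_layers), min(8L, n_heads)] <- -1.5
  }
  gamma <- as.matrix(gamma)
  if (!identical(dim(gamma), as.integer(c(n_layers, n_heads)))) {
    stop("`gamma` must be an n_layers x n_heads matrix")
  }
  structure(list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                 gamma = gamma, noise_scale = noise_scale, seed = seed),
            class = "surrogate_spec")
}

#' Generate surrogate column-attention tensors for an MSA
#'
#' Emulates the row-stochastic structure of column attentions with a
#' planted distance signal: at alignment column `j`, head `(l, h)` gets
#' pre-softmax logits `gamma[l, h] * match_j(i, i') + noise`, row-softmaxed
#' into an M x M attention matrix.  Because the mean of the match
#' indicator over columns equals `1 - d_H(i, i')`, the column-averaged
#' attentions of a signal head carry a noisy monotone image of the pairwise
#' Hamming distances.  The BOS column (j = 0) is generated as pure noise.
#'
#' @param msa An [msa].
#' @param spec A [surrogate_spec].
#' @return A [column_attention_set] with dimensions
#'   `(n_layers, n_heads, L + 1, M, M)`.
#' @export
surrogate_attentions <- function(msa, spec) {
  stopifnot(inherits(msa, "msa"), inherits(spec, "surrogate_spec"))
  M <- nrow(msa$matrix)
  L <- ncol(msa$matrix)
  nl <- spec$n_layers
  nh <- spec$n_heads
  tensor <- array(0, dim = c(nl, nh, L + 1L, M, M))
  with_seed(spec$seed, {
    for (j in seq_len(L + 1L)) {
      match_j <- if (j == 1L) {
        matrix(0, M, M)                          # BOS column: no signal
      } else {
        col <- msa$matrix[, j - 1L]
        1 * outer(col, col, `==`)
      }
      for (l in seq_len(nl)) {
        for (h in seq_len(nh)) {
          logits <- spec$gamma[l, h] * match_j
          if (spec$noise_scale > 0) {
            logits <- logits + matrix(stats::rnorm(M * M, sd = spec$noise_scale), M, M)
          }
          E <- exp(logits - apply(logits, 1L, max))
          tensor[l, h, j, , ] <- E / rowSums(E)
        }
      }
    }
  })
  column_attention_set(tensor, check = FALSE)
}

#' Deterministic fixture suite
#'
#' A small bundle of objects used across examples and tests: a 6 x 8 MSA
#' with hand-checkable pairwise distances, an enumerable planted Potts
#' model (L = 6, q = 3, 729 states), a 4-leaf tree, and a 2-layer,
#' 2-head surrogate attention tensor for the fixture MSA.
#'
#' @return Named list with `msa`, `model`, `planted_pairs`, `tree`,
#'   `attentions`.
#' @export
fixture_suite <- function() {
  chars <- rbind(
    c("A", "C", "D", "E", "F", "G", "H", "I"),
    c("A", "C", "D", "E", "F", "G", "H", "K"),
    c("A", "C", "D", "E", "-", "G", "H", "I"),
    c("W", "Y", "D", "E", "F", "G", "H", "I"),
    c("W", "Y", "V", "T", "F", "G", "H", "I"),
    c("A", "C", "D", "E", "F", "G", "H", "I"))
  fx_msa <- msa(chars, ids = paste0("fx_", 1:6))
  planted <- planted_potts(planted_spec(L = 6, q = 3, n_contacts = 1,
                                        coupling_scale = 2, field_scale = 0.4,
                                        min_separation = 5L, seed = 421L))
  tree <- parse_newick("((A:0.10,B:0.20):0.05,(C:0.15,D:0.25):0.10);")
  attn <- surrogate_attentions(fx_msa,
                               surrogate_spec(n_layers = 2L, n_heads = 2L,
                                              gamma = matrix(c(2, 0, -1, 0), 2, 2),
                                              noise_scale = 0.1, seed = 422L))
  list(msa = fx_msa, model = planted$model, planted_pairs = planted$pairs,
       tree = tree, attentions = attn)
}
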