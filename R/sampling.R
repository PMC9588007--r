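## Metropolis-Hastings sampling of sequences from a Potts model, either as
## independent equilibrium chains or along a phylogeny, plus Newick I/O.
##
## Proposals pick a site uniformly and a replacement state uniformly among
## the q - 1 other states; acceptance follows the Metropolis criterion
## p = min(1, exp(-dH)).  Along a tree, the root sequence is an equilibrium
## sample, sequences are duplicated at each branching, and each branch of
## length b (expected substitutions per site) receives a number of
## *accepted* mutations equal to the integer closest to b * L.

#' MCMC sampler configuration
#'
#' @param n_steps Number of proposed mutations per equilibrium chain.
#'   `NULL` (default) means `50 * L * q` at sampling time, an equilibration
#'   budget that is generous for the desk-scale models this package targets.
#' @param max_proposals_per_unit Safety cap: at most
#'   `max_proposals_per_unit * L` proposals are spent per accepted-mutation
#'   unit on a branch before sampling aborts with an error (default 1000).
#' @param seed Integer seed making every sample reproducible; `NULL` uses
#'   the current RNG stream to draw one.
#' @return Object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_steps = NULL, max_proposals_per_unit = 1000, seed = NULL) {
  if (!is.null(n_steps) && n_steps < 0) stop("`n_steps` must be >= 0")
  if (max_proposals_per_unit < 1) stop("`max_proposals_per_unit` must be >= 1")
  structure(list(n_steps = n_steps,
                 max_proposals_per_unit = max_proposals_per_unit,
                 seed = seed),
            class = "mcmc_config")
}

resolve_seed <- function(config) {
  if (!is.null(config$seed)) return(as.integer(config$seed))
  sample.int(.Machine$integer.max - 1L, 1L)
}

resolve_steps <- function(config, model) {
  if (!is.null(config$n_steps)) config$n_steps else 50 * model$L * model$q
}

#' One Metropolis step
#'
#' Proposes a single mutation (uniform site, uniform replacement state
#' among the `q - 1` alternatives) and accepts it with probability
#' `min(1, exp(-dH))`, where `dH` is computed incrementally from the
#' couplings touching the mutated site.  Uses the current R RNG stream.
#'
#' @param model A [potts_model].
#' @param x Integer sequence of length L, codes in `1..q`.
#' @return List with `x` (possibly updated), `accepted`, `site`,
#'   `proposal`, and `delta_h`.
#' @export
metropolis_step <- function(model, x) {
  stopifnot(inherits(model, "potts_model"))
  L <- model$L
  q <- model$q
  site <- sample.int(L, 1L)
  prop <- sample.int(q - 1L, 1L)
  if (prop >= x[site]) prop <- prop + 1L
  dH <- hamiltonian_delta(model, x, site, prop)
  accepted <- dH <= 0 || runif(1L) < exp(-dH)
  if (accepted) x[site] <- prop
  list(x = x, accepted = accepted, site = site, proposal = prop, delta_h = dH)
}

#' Sample an MSA of independent equilibrium sequences
#'
#' Runs `M` independent Metropolis chains from uniformly random start
#' sequences, each advanced by `n_steps` proposed mutations, and returns
#' the final states as an MSA.
#'
#' @param model A [potts_model].
#' @param M Number of sequences (chains).
#' @param config An [mcmc_config].
#' @return An [msa] with ids `eq_1 ... eq_M`.
#' @export
sample_equilibrium <- function(model, M, config = mcmc_config()) {
  stopifnot(inherits(model, "potts_model"), M >= 1)
  seed <- resolve_seed(config)
  n_steps <- resolve_steps(config, model)
  mat <- cpp_sample_equilibrium(model$fields, as.vector(model$couplings),
                                as.integer(M), n_steps, seed)
  msa(mat + 1L, ids = paste0("eq_", seq_len(M)), alphabet = model$alphabet)
}

#' Sample an MSA along a phylogeny
#'
#' Draws an equilibrium root sequence, then traverses the tree from the
#' root, duplicating the current sequence at each branching and evolving
#' it along each branch until the number of accepted mutations equals the
#' integer closest to `b * L` (half-up rounding).  Because the root is an
#' equilibrium draw and Metropolis dynamics satisfy detailed balance, every
#' sequence in the tree is an equilibrium sequence and the procedure is
#' invariant to root placement; the branches only add phylogenetic
#' correlations between the leaves.
#'
#' @param model A [potts_model].
#' @param tree An `ape` `phylo` tree with branch lengths in expected
#'   substitutions per site.  Unrooted trees are traversed from their
#'   basal node.
#' @param config An [mcmc_config].
#' @return An [msa] whose rows are the leaf sequences in `tree$tip.label`
#'   order.
#' @export
sample_along_tree <- function(model, tree, config = mcmc_config()) {
  stopifnot(inherits(model, "potts_model"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  L <- model$L
  seed <- resolve_seed(config)
  n_edge <- nrow(tree$edge)
  seeds <- derive_seeds(seed, n_edge + 1L)
  Jvec <- as.vector(model$couplings)

  root_chain <- cpp_run_chain(model$fields, Jvec,
                              sample_uniform_start(model, seeds[n_edge + 1L]),
                              resolve_steps(config, model), seeds[n_edge + 1L])
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root_node]] <- root_chain$x

  ## cladewise order guarantees parents are visited before children
  tree <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(n_edge)) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    b <- tree$edge.length[e]
    n_acc <- floor(b * L + 0.5)                       # integer closest to bL
    if (n_acc == 0) {
      seqs[[child]] <- seqs[[parent]]
      next
    }
    cap <- config$max_proposals_per_unit * L * n_acc
    res <- cpp_evolve_branch(model$fields, Jvec, seqs[[parent]],
                             n_acc, cap, seeds[e])
    if (!res$ok) {
      stop("accepted-mutation quota (", n_acc, ") unreachable within ", cap,
           " proposals on the branch to node ", child,
           if (child <= n_tip) paste0(" (leaf '", tree$tip.label[child], "')") else "")
    }
    seqs[[child]] <- res$x
  }
  mat <- do.call(rbind, seqs[seq_len(n_tip)]) + 1L
  msa(mat, ids = tree$tip.label, alphabet = model$alphabet)
}

sample_uniform_start <- function(model, seed) {
  with_seed(seed, sample.int(model$q, model$L, replace = TRUE) - 1L)
}

#' Parse a Newick string or file
#'
#' Thin wrapper over `ape::read.tree` with up-front structural checks that
#' report the offending position; FastTree-style internal support labels
#' are tolerated (kept as node labels) and never interpreted as lengths.
#'
#' @param text Newick string; or use `file`.
#' @param file Path to a Newick file.
#' @return An `ape` `phylo` object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("provide `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("failed to parse Newick string")
  tr
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", k)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of string")
  if (!grepl(";", text, fixed = TRUE)) {
    stop("missing ';' terminator at position ", nchar(text))
  }
  invisible(TRUE)
}

#' Serialize a tree to Newick
#'
#' @param tree An `ape` `phylo` object.
#' @param file Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}
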