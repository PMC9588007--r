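## MSA representation and sequence-level statistics.
##
## An MSA is stored as an integer matrix with M rows (sequences) and L
## columns (aligned sites), codes in 1..q indexing into a fixed alphabet.
## The gap is an ordinary 21st state, consistent with q = 21 Potts models.

#' Protein alphabet used throughout the package
#'
#' The 20 standard amino acids in fixed order followed by the alignment gap,
#' so that the gap always carries the last code (`q`).  A fixed order makes
#' integer encodings reproducible across files and runs.
#'
#' @return Character vector of length 21.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
}

#' Construct an MSA object
#'
#' @param matrix Integer matrix (M x L) of codes in `1..length(alphabet)`,
#'   or a character matrix of symbols to be encoded.
#' @param ids Character vector of M unique sequence identifiers.  Defaults
#'   to `seq_1 ... seq_M`.
#' @param alphabet Ordered symbol vector; defaults to [aa_alphabet()].
#'
#' @return An object of class `"msa"`: a list with elements `matrix`
#'   (integer M x L), `ids`, and `alphabet`.
#' @export
msa <- function(matrix, ids = NULL, alphabet = aa_alphabet()) {
  if (is.character(matrix)) {
    matrix <- encode_symbols(matrix, alphabet)
  }
  if (!is.matrix(matrix) || nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("`matrix` must be a matrix with at least one row and one column")
  }
  storage.mode(matrix) <- "integer"
  q <- length(alphabet)
  if (anyNA(matrix) || any(matrix < 1L) || any(matrix > q)) {
    stop("all codes must lie in 1..q (q = ", q, ")")
  }
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(matrix)))
  if (length(ids) != nrow(matrix)) stop("length(ids) must equal nrow(matrix)")
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  dimnames(matrix) <- NULL
  structure(list(matrix = matrix, ids = as.character(ids), alphabet = alphabet),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("MSA: %d sequences x %d sites (alphabet size %d)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$alphabet)))
  invisible(x)
}

#' @export
dim.msa <- function(x) dim(x$matrix)

## Encode a character matrix of residue symbols to integer codes.
## Non-standard residues (B, Z, X, U, O) and '.' map to the gap state.
encode_symbols <- function(chars, alphabet = aa_alphabet()) {
  chars <- toupper(chars)
  codes <- match(chars, alphabet)
  bad <- is.na(codes)
  if (any(bad)) {
    unknown <- unique(chars[bad])
    allowed <- c("B", "Z", "X", "U", "O", ".")
    if (!all(unknown %in% allowed)) {
      stop("unencodable symbols: ", paste(setdiff(unknown, allowed), collapse = ", "))
    }
    warning("mapping non-standard symbols to gap: ", paste(unknown, collapse = ", "))
    codes[bad] <- match("-", alphabet)
  }
  matrix(as.integer(codes), nrow = nrow(chars), ncol = ncol(chars))
}

## Decode an integer MSA matrix back to residue characters.
decode_symbols <- function(mat, alphabet = aa_alphabet()) {
  matrix(alphabet[mat], nrow = nrow(mat), ncol = ncol(mat))
}

#' Normalized Hamming distance between two encoded sequences
#'
#' Fraction of sites at which the two sequences differ.  The gap is an
#' ordinary symbol, so two aligned gaps count as a match.
#'
#' @param x,y Equal-length integer (or character) vectors.
#' @return A value in `[0, 1]`.
#' @export
hamming_distance <- function(x, y) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
  if (is.character(y) && length(y) == 1L) y <- strsplit(y, "")[[1]]
  if (length(x) != length(y)) stop("sequences have different lengths")
  mean(x != y)
}

#' Full pairwise Hamming distance matrix of an MSA
#'
#' Computed via a one-hot expansion and a single cross-product, so it scales
#' to thousands of sequences.
#'
#' @param msa An [msa] object.
#' @return Symmetric M x M matrix with zero diagonal.
#' @export
hamming_matrix <- function(msa) {
  stopifnot(inherits(msa, "msa"))
  X <- one_hot(msa$matrix, length(msa$alphabet))
  L <- ncol(msa$matrix)
  D <- 1 - tcrossprod(X) / L
  ## guard against tiny negative / asymmetric floating-point residue
  D <- (D + t(D)) / 2
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

## M x (L*q) one-hot encoding; column (i-1)*q + a is the indicator of
## state a at site i.
one_hot <- function(mat, q) {
  M <- nrow(mat)
  L <- ncol(mat)
  X <- matrix(0, M, L * q)
  idx <- cbind(rep(seq_len(M), L),
               (rep(seq_len(L), each = M) - 1L) * q + as.integer(mat))
  X[idx] <- 1
  X
}

#' Phylogenetic sequence weights
#'
#' Weight of sequence i is the reciprocal of the number of sequences
#' (including i itself) whose normalized Hamming distance to it is below
#' `delta`.  The sum of weights is the effective depth of the alignment.
#'
#' @param msa An [msa] object.
#' @param delta Similarity threshold in `(0, 1]`; default 0.2.
#' @return An object of class `"weight_vector"`: list with `weights`,
#'   `delta` and `m_eff`.
#' @export
sequence_weights <- function(msa, delta = 0.2) {
  stopifnot(inherits(msa, "msa"))
  if (delta <= 0) stop("`delta` must be > 0 (each sequence is its own neighbour)")
  D <- hamming_matrix(msa)
  counts <- rowSums(D < delta)
  w <- 1 / counts
  structure(list(weights = w, delta = delta, m_eff = sum(w)),
            class = "weight_vector")
}

#' Effective depth of an MSA
#'
#' Sum of the phylogenetic sequence weights; lies between 1 (all sequences
#' identical) and M (no two sequences within `delta` of one another).
#'
#' @inheritParams sequence_weights
#' @return A single number in `[1, M]`.
#' @export
effective_depth <- function(msa, delta = 0.2) {
  sequence_weights(msa, delta)$m_eff
}

#' Shannon entropy of an MSA column
#'
#' Natural-log entropy of the empirical symbol distribution in column `j`;
#' 0 for a conserved column, up to `log(q)` for a uniform one.
#'
#' @param msa An [msa] object.
#' @param j Column index in `1..L`.
#' @return Entropy in nats.
#' @export
column_entropy <- function(msa, j) {
  stopifnot(inherits(msa, "msa"))
  L <- ncol(msa$matrix)
  if (length(j) != 1L || is.na(j) || j < 1L || j > L) {
    stop("column index out of range 1..", L)
  }
  p <- tabulate(msa$matrix[, j], nbins = length(msa$alphabet))
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Read an aligned FASTA file as an MSA
#'
#' All records must have the same width.  Lowercase residues are uppercased;
#' non-standard residues (B, Z, X, U, O, '.') are mapped to the gap state
#' with a warning.
#'
#' @param path Path to an aligned FASTA file.
#' @param alphabet Symbol order used for encoding.
#' @return An [msa] object.
#' @export
read_fasta <- function(path, alphabet = aa_alphabet()) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(widths), collapse = ", "))
  }
  chars <- do.call(rbind, strsplit(as.character(seqs), ""))
  msa(encode_symbols(chars, alphabet), ids = names(seqs), alphabet = alphabet)
}

#' Write an MSA as aligned FASTA
#'
#' @param msa An [msa] object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(msa, path) {
  stopifnot(inherits(msa, "msa"))
  chars <- decode_symbols(msa$matrix, msa$alphabet)
  seqs <- Biostrings::BStringSet(apply(chars, 1L, paste, collapse = ""))
  names(seqs) <- msa$ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
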