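## Shared builders for small test objects.  Everything is generated in
## code with fixed seeds; nothing is read from disk.

toy_msa <- function() {
  ## 4 sequences: rows 1 and 2 identical, rows 3 and 4 far from everything
  chars <- rbind(c("A", "C", "D", "E", "F"),
                 c("A", "C", "D", "E", "F"),
                 c("W", "Y", "V", "T", "G"),
                 c("H", "K", "L", "M", "N"))
  msa(chars, ids = paste0("s", 1:4))
}

small_potts <- function(L = 3, q = 3, seed = 5, coupling_sd = 0.5,
                        field_sd = 0.6) {
  withr::with_seed(seed, {
    fields <- matrix(rnorm(L * q, sd = field_sd), L, q)
    J <- array(0, dim = c(L, L, q, q))
    if (L >= 3) {
      blk <- matrix(rnorm(q * q, sd = coupling_sd), q, q)
      J[1, L, , ] <- blk
      J[L, 1, , ] <- t(blk)
    }
    potts_model(fields, J)
  })
}

random_potts <- function(L, q, seed) {
  withr::with_seed(seed, {
    fields <- matrix(rnorm(L * q, sd = 0.5), L, q)
    J <- array(rnorm(L * L * q * q, sd = 0.3), dim = c(L, L, q, q))
    potts_model(fields, J)   # constructor symmetrizes from i < j blocks
  })
}

## Total-variation distance between an empirical MSA sample and the exact
## Boltzmann law of an enumerable model.
tv_to_exact <- function(msa, model) {
  ex <- exact_distribution(model)
  key <- apply(msa$matrix, 1L, paste, collapse = ",")
  lev <- apply(ex$states, 1L, paste, collapse = ",")
  emp <- as.numeric(table(factor(key, levels = lev))) / nrow(msa$matrix)
  0.5 * sum(abs(emp - ex$prob))
}
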