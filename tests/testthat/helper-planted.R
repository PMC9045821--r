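# Planted-subpopulation probability matrices shared by the clustering and
# acceptance suites.

planted_matrix <- function(n_per, templates, noise = 0.1, seed = 101,
                           samples = NULL) {
  set.seed(seed)
  rows <- list(); labs <- integer(0)
  for (g in seq_len(nrow(templates))) {
    base <- matrix(rep(templates[g, ], each = n_per), n_per)
    jit <- matrix(abs(rnorm(length(base), 0, noise)), n_per)
    probs <- abs(base - jit)            # noise pushes inward from 0/1
    rows[[g]] <- pmin(pmax(probs, 0), 1)
    labs <- c(labs, rep(g, n_per))
  }
  probs <- do.call(rbind, rows)
  m <- mod_profile_matrix(
    probs,
    data.frame(read_id = sprintf("r%04d", seq_len(nrow(probs))),
               sample = samples %||% paste0("g", labs), stringsAsFactors = FALSE),
    data.frame(contig = "c", position = seq(20, by = 10, length.out = ncol(probs)),
               stringsAsFactors = FALSE))
  list(matrix = m, labels = labs)
}
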