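# shared fixtures and small oracles used across the suite

# independent longest-common-substring oracle (enumeration over substrings
# of the shorter string); deliberately distinct from the package's DP code
lcs_oracle <- function(a, b) {
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  n <- nchar(a)
  for (len in n:1) {
    subs <- unique(substring(a, 1:(n - len + 1), len:n))
    hits <- subs[vapply(subs, function(s) grepl(s, b, fixed = TRUE),
                        logical(1))]
    if (length(hits) > 0) return(max(nchar(hits)))
  }
  0L
}

# a planted gene counts as recovered when some candidate matches it up to
# `tol` nucleotides of end extension/truncation
matches_planted <- function(candidate, gene, tol = 3) {
  l <- lcs_oracle(candidate, gene)
  l >= nchar(gene) - tol && nchar(candidate) - l <= tol
}

recovered_count <- function(candidates, genes, tol = 3) {
  sum(vapply(genes, function(g) {
    any(vapply(candidates, matches_planted, logical(1), gene = g, tol = tol))
  }, logical(1)))
}

# small planted repertoire used by several module tests
planted_repertoire <- function(n_genes = 10, n_cdr3s = 20000, rng_seed = 1,
                               len_range = c(12, 35), gene_weights = NULL) {
  genes <- random_d_genes(n_genes, len_range, rng_seed = rng_seed)
  model <- generative_model(genes, gene_weights = gene_weights)
  sim <- simulate_cdr3s(model, n_cdr3s, rng_seed = rng_seed + 1000L)
  list(genes = genes, model = model, sim = sim,
       cdr3s = cdr3_set(sim$sequence))
}
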