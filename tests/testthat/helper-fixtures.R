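# Small fixtures built in code.

# random positive expression matrix with names
rand_expr <- function(k, t, seed, prefix = "g", tissue_prefix = "t") {
  set.seed(seed)
  m <- matrix(exp(rnorm(k * t)), k, t)
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(k)),
                      sprintf("%s%02d", tissue_prefix, seq_len(t)))
  m
}

# aligned random PCM pair built from two expression matrices
rand_pcm_pair <- function(k, t, seed) {
  a <- rand_expr(k, t, seed, prefix = "a")
  b <- rand_expr(k, t, seed + 1000, prefix = "b")
  list(pa = pairwise_correlation_matrix(a),
       pb = pairwise_correlation_matrix(b))
}

rand_paired <- function(k, t_a, t_b, seed) {
  a <- rand_expr(k, t_a, seed, prefix = "a")
  b <- rand_expr(k, t_b, seed + 500, prefix = "b")
  paired_expression(a, b, data.frame(gene_a = rownames(a),
                                     gene_b = rownames(b),
                                     stringsAsFactors = FALSE))
}

expr_file <- function(m, dir = tempdir()) {
  f <- tempfile(tmpdir = dir, fileext = ".tsv")
  write_expression_table(m, f)
  f
}

# squash arbitrary reals into [-1, 1] so they are admissible EC values
clamp_unit <- function(v) pmin(1, pmax(-1, v))
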