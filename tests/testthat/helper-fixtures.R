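# Small in-code fixture builders shared across test files.

toy_expression <- function(n_genes = 6, n_samples = 4, seed = 42, mean = 8) {
  set.seed(seed)
  x <- matrix(stats::rnorm(n_genes * n_samples, mean = mean), n_genes,
              n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  attr(x, "scale") <- "log2"
  x
}

write_tsv_lines <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# two-group matrix with a planted mean shift on some genes
planted_two_group <- function(n_genes = 100, n_per_group = 10, shift = 2,
                              n_shifted = 10, noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  x <- matrix(stats::rnorm(n_genes * n, mean = 7, sd = noise_sd), n_genes, n,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  g2 <- (n_per_group + 1):n
  x[seq_len(n_shifted), g2] <- x[seq_len(n_shifted), g2] + shift
  attr(x, "scale") <- "log2"
  list(x = x, group1 = colnames(x)[seq_len(n_per_group)],
       group2 = colnames(x)[g2],
       shifted = rownames(x)[seq_len(n_shifted)])
}

# partition agreement (ARI) without depending on the implementation under test
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
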