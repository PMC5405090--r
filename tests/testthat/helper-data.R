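# Small in-code fixtures shared across test files.

toy_counts <- function() {
  m <- matrix(c(10, 20, 30, 40, 50,
                 5, 10, 15, 20, 25,
                 8, 16, 24, 32, 40),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), c(3, 4, 5, 6, 8)))
  count_matrix(m, sample_id = "toy")
}

write_toy_counts_file <- function(path, sep = "\t") {
  lines <- c(paste(c("gene_id", "3", "4", "5", "6", "8"), collapse = sep),
             paste(c("gA", 10, 20, 30, 40, 50), collapse = sep),
             paste(c("gB", 5, 10, 15, 20, 25), collapse = sep),
             paste(c("gC", 8, 16, 24, 32, 40), collapse = sep))
  writeLines(lines, path)
  path
}

random_count_matrix <- function(n_genes = 20, n_cols = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cols, 100) + 1L, nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              c(3, 4, 5, 6, 8)[seq_len(n_cols)]))
  count_matrix(m, sample_id = "rand")
}

# assignments table built directly, for network-level tests
manual_assignments <- function(df) {
  out <- data.frame(regulator = df$regulator, target = df$target,
                    h = if (is.null(df$h)) rep(0L, nrow(df)) else df$h,
                    r = if (is.null(df$r)) rep(1, nrow(df)) else df$r,
                    t_a = df$t_a, t_b = df$t_b,
                    m_value = rep(0, nrow(df)),
                    stringsAsFactors = FALSE)
  class(out) <- c("assignment_table", "data.frame")
  out
}
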