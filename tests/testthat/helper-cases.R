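# Shared builders for small test cases.

named_square <- function(v, labels = NULL) {
  n <- as.integer(sqrt(length(v)))
  if (is.null(labels)) labels <- paste0("D", seq_len(n))
  matrix(v, n, n, byrow = TRUE, dimnames = list(labels, labels))
}

# random direct-relation matrix with controlled spectral radius after
# normalisation (entries non-negative, zero diagonal)
random_Z <- function(n, max_entry = 4) {
  m <- matrix(stats::runif(n * n, 0, max_entry), n, n,
              dimnames = list(paste0("D", seq_len(n)), paste0("D", seq_len(n))))
  diag(m) <- 0
  m
}

two_expert_panel <- function(ranks = c(2, 1), cluster = "infection") {
  expert_panel(c("e1", "e2"), rep(cluster, 2), ranks)
}
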