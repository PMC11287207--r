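## small builders used across the test files

make_cm <- function(values, kind = "counts",
                    samples = sprintf("s%02d", seq_len(nrow(values))),
                    taxa = sprintf("t%02d", seq_len(ncol(values)))) {
  dimnames(values) <- list(samples, taxa)
  community_matrix(values, kind)
}

random_counts <- function(n_samples, n_taxa, lambda = 20, seed = 1) {
  commcoal:::with_seed(seed, {
    m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa)
    m[1L, 1L] <- m[1L, 1L] + 1L # guard against an all-zero first sample
    make_cm(m)
  })
}

## Dirichlet rows with common concentration vector
rdirichlet_rows <- function(n, alpha) {
  t(vapply(seq_len(n), function(i) {
    g <- stats::rgamma(length(alpha), shape = alpha)
    g / sum(g)
  }, numeric(length(alpha))))
}

## brute-force BH step-up, used as the oracle for bh_adjust
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(o == i) # rank of p[i] (stable for ties via order())
    adj[i] <- min(1, min(m * p[o][k:m] / (k:m)))
  }
  adj
}
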