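# shared small fixtures, built in code

# tiny replicated linear-scale expression matrix with known structure
tiny_replicated <- function() {
  m <- matrix(c(10, 1000, 100, 100,
                100, 100, 10, 1000,
                50, 200, 400, 25), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              c("s1a", "s1b", "s2a", "s2b")))
  list(expr = m, conditions = c("c1", "c1", "c2", "c2"))
}

# small deterministic delta matrix for SOM tests
small_delta <- function(n = 60, m = 6, seed = 5) {
  set.seed(seed)
  d <- matrix(rnorm(n * m), n, m,
              dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:m)))
  d - rowMeans(d)
}

# default small synthetic fixture used across module tests
small_fixture <- function(seed = 3, n_genes = 600, n_samples = 8) {
  tr <- synthetic_truth(n_modules = 2L, module_size = 60L, n_groups = 2L,
                        seed = seed)
  generate_expression(tr, n_genes = n_genes, n_samples = n_samples)
}

# brute-force hypergeometric overrepresentation by exhaustive enumeration
# of all lists of length n_list from an n-gene universe (oracle, N <= 12)
hg_enumerate <- function(n, n_list, n_set, n_pos) {
  universe <- seq_len(n)
  set <- seq_len(n_set)
  lists <- utils::combn(universe, n_list)
  overlaps <- apply(lists, 2L, function(l) length(intersect(l, set)))
  mean(overlaps > n_pos)
}
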