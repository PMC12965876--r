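# Small in-code fixtures shared across test files.

# tiny aligned predictor set with named driver groups; continuous, no factor
make_group_data <- function(n, terms_per_group = c(A = 2L, B = 2L, C = 1L),
                            seed = 1) {
  set.seed(seed)
  cols <- unlist(lapply(names(terms_per_group), function(g)
    paste0(g, seq_len(terms_per_group[[g]]))))
  x <- as.data.frame(matrix(rnorm(n * length(cols)), n,
                            dimnames = list(NULL, cols)))
  groups <- lapply(names(terms_per_group), function(g)
    paste0(g, seq_len(terms_per_group[[g]])))
  names(groups) <- names(terms_per_group)
  list(data = x, groups = groups)
}

# brute-force variation-partitioning oracle: solve the linear system that maps
# Venn-region fractions to subset r2 values directly
varpart_oracle <- function(r2, k) {
  masks <- seq_len(2^k - 1L)
  M <- matrix(0, length(masks), length(masks))
  for (s in masks) for (t in masks)
    M[s, t] <- as.numeric(bitwAnd(s, t) > 0L)  # region t contributes to r2(S) iff T meets S
  solve(M, r2)
}

# tie-corrected two-group rank-sum z^2 (Wilcoxon), the independent oracle for
# the two-group Kruskal-Wallis statistic
ranksum_z2 <- function(x, g) {
  stopifnot(nlevels(g) == 2L)
  r <- rank(x)
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2]); N <- n1 + n2
  W <- sum(r[g == levels(g)[1]])
  ties <- table(x)
  v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  ((W - n1 * (N + 1) / 2)^2) / v
}

quiet_sim <- function(...) suppressWarnings(simulate_soildriver(sim_config(...)))
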