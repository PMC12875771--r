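# Shared fixtures and independent oracles.

# 4x3 worked deprivation matrix: rows {110, 100, 111, 000}
toy_matrix <- function() {
  G <- rbind(c(1L, 1L, 0L), c(1L, 0L, 0L), c(1L, 1L, 1L), c(0L, 0L, 0L))
  colnames(G) <- c("a", "b", "c")
  G
}

# registry of direct binary indicators, one factor each unless given
mini_registry <- function(names, factors = names, dimension = "dim1") {
  indicator_registry(mapply(function(n, f)
    indicator_rule(n, "direct_binary", f, dimension, n),
    names, factors, SIMPLIFY = FALSE))
}

# hand-constructed weight scheme for property tests with arbitrary weights
raw_scheme <- function(weights, convention = "count", name = "RAW") {
  structure(list(scheme_name = name,
                 weights = stats::setNames(weights, paste0("i", seq_along(weights))),
                 total_weight = sum(weights),
                 cutoff_convention = convention),
            class = "weight_scheme")
}

# Brute-force Alkire-Foster oracle: explicit per-participant, per-indicator
# loops, no matrix algebra shared with the production path.
af_oracle <- function(G, weights, d, convention = "count") {
  n <- nrow(G); J <- ncol(G)
  total <- sum(weights)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    c_i <- 0
    for (j in seq_len(J)) c_i <- c_i + weights[j] * G[i, j]
    scores[i] <- c_i
  }
  cut <- if (convention == "count") d else d * total
  poor <- scores >= cut - 1e-9
  H <- sum(poor) / n
  A <- if (any(poor)) mean(scores[poor] / total) else NA_real_
  M0 <- if (any(poor)) H * A else 0
  CH <- numeric(J)
  for (j in seq_len(J)) {
    cnt <- 0
    for (i in seq_len(n)) if (poor[i] && G[i, j] == 1) cnt <- cnt + 1
    CH[j] <- cnt / n
  }
  contrib <- if (M0 > 0) weights * CH / (total * M0) else rep(NA_real_, J)
  list(scores = scores, poor = poor, H = H, A = A, M0 = M0,
       CH = CH, contrib = contrib)
}

# random 0/1 matrix with at least one deprived cell
random_matrix <- function(n, J, p = 0.3) {
  G <- matrix(rbinom(n * J, 1, p), n, J)
  if (sum(G) == 0) G[1, 1] <- 1L
  storage.mode(G) <- "integer"
  colnames(G) <- paste0("i", seq_len(J))
  G
}

# reduce a matrix to its values and bare column names
strip_attrs <- function(m) {
  out <- matrix(as.integer(m), nrow(m), ncol(m))
  colnames(out) <- unname(colnames(m))
  out
}
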