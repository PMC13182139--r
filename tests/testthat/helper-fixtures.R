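# shared fixtures and independent oracles used across test files

random_supermatrix <- function(ntaxa, nsites, gap_prob = 0, amb_prob = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE)
  n <- length(chars)
  if (gap_prob > 0)
    chars[stats::runif(n) < gap_prob] <- "-"
  if (amb_prob > 0) {
    amb <- stats::runif(n) < amb_prob
    chars[amb] <- sample(c("N", "R", "Y", "W"), sum(amb), replace = TRUE)
  }
  m <- matrix(chars, ntaxa, nsites,
              dimnames = list(paste0("t", seq_len(ntaxa)), NULL))
  supermatrix(m)
}

# independent brute-force parsimony-informativeness classifier
brute_informative <- function(column) {
  tab <- table(column[column %in% c("A", "C", "G", "T")])
  sum(tab >= 2) >= 2
}

# independent per-column polarized pattern classifier (loop form, no shared
# code with the package's vectorized classifier)
brute_classify_column <- function(a, b, c, o) {
  states <- c(a, b, c, o)
  if (!all(states %in% c("A", "C", "G", "T"))) return(NA_integer_)
  if (a == b && c == o && a != o) return(1L)
  if (a == c && b == o && a != b) return(2L)
  if (b == c && a == o && b != a) return(3L)
  0L
}

# independent quartet pattern-probability oracle: enumerates internal-node
# states with transition matrices from ape::matexpo (a code path disjoint
# from the package's eigendecomposition engine)
oracle_pattern_prob <- function(model, blen, topology, pattern) {
  Q <- matrix(0, 4, 4)
  Q[lower.tri(Q)] <- model$rates
  Q <- Q + t(Q)
  Q <- Q * rep(model$bf, each = 4)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(-diag(Q) * model$bf)
  g <- phangorn::discrete.gamma(model$shape, model$k)
  if (model$pinv > 0) g <- g / (1 - model$pinv)
  w <- rep((1 - model$pinv) / model$k, model$k)
  perm <- switch(topology, x1 = c(1, 2, 3), x2 = c(1, 3, 2), x3 = c(2, 3, 1))
  bl <- c(blen[perm], blen[["o"]], blen[["int"]])
  s <- c(pattern[perm], pattern[4L])
  tot <- 0
  for (m in seq_along(g)) {
    P <- lapply(bl, function(t) ape::matexpo(Q * g[m] * t))
    acc <- 0
    for (x in 1:4) for (y in 1:4)
      acc <- acc + model$bf[x] * P[[1L]][x, s[1L]] * P[[2L]][x, s[2L]] *
        P[[5L]][x, y] * P[[3L]][y, s[3L]] * P[[4L]][y, s[4L]]
    tot <- tot + w[m] * acc
  }
  if (model$pinv > 0 && length(unique(pattern)) == 1L)
    tot <- tot + model$pinv * model$bf[pattern[1L]]
  tot
}

# small scenario used by pipeline-level tests: full 6-clade structure but
# few short loci so the whole analysis runs in seconds
tiny_preset <- function(name, seed, n_loci = 6L, locus_length = 150L) {
  simulate_dataset(name, seed = seed, n_loci = n_loci,
                   locus_length = locus_length)
}

tiny_clades <- function(name = "strong_signal", seed = 1L) {
  scenario_clades(preset_scenarios(name, seed = seed))
}
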