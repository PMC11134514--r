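# shared fixtures and independent oracles

# small labeled dataset with Gaussian class clusters
make_gaussian_ds <- function(id = "D", n = 20, d = 3, sep = 2, seed = 1,
                             featurizer = "fix") {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * d), n, d)
  X[, 1] <- X[, 1] + ifelse(y == 1L, sep / 2, -sep / 2)
  embedded_dataset(id, X, y, featurizer)
}

gmodel <- function(mean, cov) {
  structure(list(label = 0L, mean = mean, covariance = as.matrix(cov),
                 n_samples = 1L),
            class = "gaussian_label_model")
}

# brute-force OT cost for uniform square marginals: enumeration over
# permutation couplings (optimal vertex by Birkhoff-von Neumann)
brute_force_ot <- function(C) {
  n <- nrow(C)
  stopifnot(n == ncol(C))
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(C[cbind(seq_len(n), p)]) / n, numeric(1)))
}

# independent k-NN aggregation: full sort then average
knn_oracle <- function(column, k, weights = NULL) {
  ids <- names(column)
  o <- order(column, ids)
  sel <- o[seq_len(k)]
  if (is.null(weights)) return(mean(column[sel]))
  w <- weights[sel]
  sum(w * column[sel]) / sum(w)
}

# tiny universe that runs everything quickly
small_universe_config <- function(seed = 7L, ...) {
  universe_config(n_sources = 12L, n_targets = 5L, chem_dim = 8L,
                  prot_dim = 8L, n_molecules = 60L, k_related = 2L,
                  seed = seed, ...)
}

real_smiles <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "c1ccccc1O", "CC(=O)Oc1ccccc1C(=O)O",
  "CCN(CC)CC", "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  "C1CCCCC1", "CCCCCC", "OCC(O)CO", "NC(=O)c1ccccc1", "Clc1ccccc1",
  "CC(N)C(=O)O", "O=C(O)c1ccccc1O", "COc1ccccc1", "CCOC(=O)C",
  "CN1CCC[C@H]1c1cccnc1", "OC(=O)CC(O)(CC(O)=O)C(O)=O", "CSCC"
)
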