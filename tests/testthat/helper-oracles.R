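# Shared fixtures and independent oracles, built in code at test time.

random_protein <- function(n, min_len = 6L, max_len = 50L) {
  lapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1L)
    protein_sequence(paste0("rs", i),
                     paste(sample(AA_ALPHABET, L, replace = TRUE),
                           collapse = ""))
  })
}

# Brute-force GPC oracle: enumerate every (p, p + G + 1) position pair.
gpc_oracle <- function(seq, G) {
  chars <- strsplit(seq$residues, "")[[1L]]
  N <- length(chars)
  counts <- matrix(0L, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (p in seq_len(N - G - 1L)) {
    counts[chars[p], chars[p + G + 1L]] <-
      counts[chars[p], chars[p + G + 1L]] + 1L
  }
  out <- as.numeric(t(counts)) / (N - G - 1L)
  names(out) <- paste0("g", G, "_", rep(AA_ALPHABET, each = 20L),
                       rep(AA_ALPHABET, times = 20L))
  out
}

# Exhaustive pairwise-ordering oracle for the ROC area (ties count 1/2).
auc_pairwise_oracle <- function(scores, y_true, positive) {
  sp <- scores[y_true == positive]
  sn <- scores[y_true != positive]
  total <- 0
  for (a in sp) total <- total + sum(a > sn) + 0.5 * sum(a == sn)
  total / (length(sp) * length(sn))
}

# Straight-line evaluation of the PAAC equations, independent of the
# package's vectorized path.
paac_oracle <- function(residues, prop_values, d, w) {
  m <- mean(prop_values)
  rms <- sqrt(sum((prop_values - m)^2) / 20)
  theta <- (prop_values - m) / rms
  chars <- strsplit(residues, "")[[1L]]
  L <- length(chars)
  rho <- numeric(d)
  for (j in seq_len(d)) {
    acc <- 0
    for (i in seq_len(L - j)) {
      acc <- acc + (theta[chars[i]] - theta[chars[i + j]])^2
    }
    rho[j] <- acc / (L - j)
  }
  f <- vapply(AA_ALPHABET, function(a) sum(chars == a), numeric(1L))
  den <- sum(f) + w * sum(rho)
  c(f / den, w * rho / den)
}

make_toy_clouds <- function(n_per = 20L, sep = 6, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 2L), ncol = 2L),
             matrix(rnorm(n_per * 2L, mean = sep), ncol = 2L))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("A", "B"), each = n_per))
}

make_xor <- function(n_per = 30L, seed = 2L) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(4, 4), c(0, 4), c(4, 0))
  X <- do.call(rbind, lapply(1:4, function(k) {
    matrix(rnorm(n_per * 2L, sd = 0.5), ncol = 2L) +
      matrix(centers[k, ], n_per, 2L, byrow = TRUE)
  }))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(c("A", "A", "B", "B"), each = n_per))
}
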