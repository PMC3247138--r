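# Independent naive-loop oracles: each re-implements a descriptor's printed
# formula directly, sharing no code with the package internals.

random_seq <- function(L, seed, id = paste0("rnd", seed)) {
  set.seed(seed)
  protein_sequence(id, paste(sample(AMINO_ACIDS, L, replace = TRUE),
                             collapse = ""))
}

seq_chars <- function(s) strsplit(s$residues, "")[[1]]

naive_aac <- function(s) {
  ch <- seq_chars(s)
  out <- numeric(20)
  names(out) <- AMINO_ACIDS
  for (c in ch) out[c] <- out[c] + 1
  out / length(ch)
}

naive_dc <- function(s) {
  ch <- seq_chars(s)
  L <- length(ch)
  out <- numeric(400)
  names(out) <- paste0(rep(AMINO_ACIDS, each = 20), rep(AMINO_ACIDS, 20))
  for (i in 1:(L - 1)) {
    dp <- paste0(ch[i], ch[i + 1])
    out[dp] <- out[dp] + 1
  }
  out / (L - 1)
}

# P: named standardized property values
naive_autocorr <- function(s, P, kind) {
  ch <- seq_chars(s)
  L <- length(ch)
  v <- P[ch]
  out <- numeric(30)
  if (kind == "NMB") {
    for (d in 1:30) {
      acc <- 0
      for (i in 1:(L - d)) acc <- acc + v[i] * v[i + d]
      out[d] <- acc / (L - d)
    }
  } else if (kind == "Moran") {
    pbar <- sum(v) / L
    den <- sum((v - pbar)^2) / L
    for (d in 1:30) {
      acc <- 0
      for (i in 1:(L - d)) acc <- acc + (v[i] - pbar) * (v[i + d] - pbar)
      out[d] <- if (den == 0) 0 else (acc / (L - d)) / den
    }
  } else {
    pbar <- sum(v) / L
    den <- sum((v - pbar)^2) / (L - 1)
    for (d in 1:30) {
      acc <- 0
      for (i in 1:(L - d)) acc <- acc + (v[i] - v[i + d])^2
      out[d] <- if (den == 0) 0 else (acc / (2 * (L - d))) / den
    }
  }
  unname(out)
}

# g: integer recoding in 1..3; direct implementation of the CTD prose
naive_ctd <- function(g) {
  L <- length(g)
  comp <- sapply(1:3, function(k) 100 * sum(g == k) / L)
  pair_list <- list(c(1, 2), c(1, 3), c(2, 3))
  tran <- sapply(pair_list, function(pr) {
    cnt <- 0
    for (i in 1:(L - 1)) {
      if ((g[i] == pr[1] && g[i + 1] == pr[2]) ||
          (g[i] == pr[2] && g[i + 1] == pr[1])) cnt <- cnt + 1
    }
    100 * cnt / (L - 1)
  })
  dist <- numeric(15)
  for (k in 1:3) {
    pos <- which(g == k)
    n <- length(pos)
    if (n == 0) next
    qidx <- c(1, max(1, floor(0.25 * n)), max(1, floor(0.50 * n)),
              max(1, floor(0.75 * n)), n)
    dist[(k - 1) * 5 + 1:5] <- 100 * pos[qidx] / L
  }
  c(comp, tran, dist)
}

naive_socn <- function(s, D) {
  ch <- seq_chars(s)
  L <- length(ch)
  out <- numeric(30)
  for (j in 1:30) {
    acc <- 0
    for (i in 1:(L - j)) acc <- acc + D[ch[i], ch[i + j]]^2
    out[j] <- acc
  }
  out
}

naive_qso <- function(s, D, omega = 0.1) {
  f <- naive_aac(s)
  tau <- naive_socn(s, D)
  den <- sum(f) + omega * sum(tau)
  c(f / den, omega * tau / den)
}

# H: 3 x 20 matrix of standardized scales, columns named by amino acid
naive_pseaac <- function(s, H, omega = 0.1) {
  ch <- seq_chars(s)
  L <- length(ch)
  theta <- numeric(30)
  for (d in 1:30) {
    acc <- 0
    for (i in 1:(L - d)) {
      acc <- acc + mean((H[, ch[i]] - H[, ch[i + d]])^2)
    }
    theta[d] <- acc / (L - d)
  }
  f <- naive_aac(s)
  den <- sum(f) + omega * sum(theta)
  c(f / den, omega * theta / den)
}

# standardized scales for properties 9-11, for the PseAAC oracle
pseaac_H <- function() {
  k <- load_constants()
  t(vapply(k$properties[9:11], function(p) p$standardized_values, numeric(20)))
}

recode3 <- function(s, scheme) {
  ch <- seq_chars(s)
  g <- integer(length(ch))
  for (k in 1:3) g[ch %in% scheme$groups[[k]]] <- k
  g
}

expect_close <- function(actual, expected, rel_tol = 1e-10) {
  scale <- pmax(abs(expected), 1e-12)
  expect_true(max(abs(actual - expected) / scale) < rel_tol)
}

# 3 classes whose mean structure is exactly rank 2: class scores in a plane,
# spread over all p columns through a fixed loading matrix, plus unit noise.
# The two leading principal components recover the class plane.
make_rank2_fixture <- function(seed, n_per = 12, p = 40) {
  set.seed(seed)
  scores <- rbind(c(4, 0), c(-4, 3), c(0, -5))
  B <- matrix(rnorm(p * 2), p, 2)
  X <- do.call(rbind, lapply(1:3, function(cl) {
    matrix(rep(scores[cl, ], each = n_per), n_per, 2) %*% t(B) +
      matrix(rnorm(n_per * p), n_per, p)
  }))
  list(X = X, labels = rep(c("a", "b", "c"), each = n_per))
}
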