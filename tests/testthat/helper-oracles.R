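# Independent brute-force oracles, coded directly from the defining
# equations with explicit loops, against which the package implementation
# (vectorised / compiled) is compared.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))

oracle_channel <- function(F, w) {
  C <- dim(F)[3]
  mlp <- function(v) {
    h <- pmax(as.numeric(w$W1 %*% v + w$b1), 0)
    as.numeric(w$W2 %*% h + w$b2)
  }
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) { avg[c] <- mean(F[, , c]); mx[c] <- max(F[, , c]) }
  oracle_sigmoid(mlp(avg) + mlp(mx))
}

oracle_spatial <- function(F, w, k) {
  H <- dim(F)[1]; W <- dim(F)[2]; p <- (k - 1) / 2
  avg <- apply(F, c(1, 2), mean); mx <- apply(F, c(1, 2), max)
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (cc in seq_len(W)) {
    acc <- w$conv_b
    for (i in seq_len(k)) for (j in seq_len(k)) {
      ri <- r + i - 1 - p; cj <- cc + j - 1 - p
      if (ri >= 1 && ri <= H && cj >= 1 && cj <= W) {
        acc <- acc + w$conv[i, j, 1] * avg[ri, cj] + w$conv[i, j, 2] * mx[ri, cj]
      }
    }
    out[r, cc] <- oracle_sigmoid(acc)
  }
  out
}

oracle_hybrid <- function(F, w, k, strict = TRUE) {
  cw <- oracle_channel(F, w)
  Fc <- F
  for (c in seq_len(dim(F)[3])) Fc[, , c] <- F[, , c] * cw[c]
  sw <- oracle_spatial(Fc, w, k)
  base <- if (strict) F else Fc
  out <- base
  for (c in seq_len(dim(F)[3])) out[, , c] <- base[, , c] * sw
  out
}

rand_map <- function(H, W, C, seed) {
  set.seed(seed)
  array(rnorm(H * W * C), dim = c(H, W, C))
}

rand_weights <- function(C, cfg, seed) {
  init_attention_weights(C, cfg, scintimet:::make_rng(seed))
}


# brute-force AUC oracle: exhaustive concordant-pair counting per the
# rank-probability definition (ties count one half)
pair_count_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

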