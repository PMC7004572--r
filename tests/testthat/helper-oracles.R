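# Independent oracles used to cross-check the implementation. These are
# deliberately written with different primitives than the package code.

# exhaustive best-subset by BIC using lm() on every subset
oracle_best_subset <- function(y, A) {
  n <- length(y)
  p <- ncol(A)
  yc <- y - mean(y)
  Ac <- scale(A, center = TRUE, scale = FALSE)
  best <- list(bic = Inf, idx = integer(0))
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (r in seq_len(nrow(subsets))) {
    inc <- unname(which(unlist(subsets[r, ])))
    if (length(inc) == 0) {
      rss <- sum(yc^2)
    } else {
      fit <- lm.fit(Ac[, inc, drop = FALSE], yc)
      rss <- sum(fit$residuals^2)
    }
    q <- length(inc)
    bic <- n * log(max(rss, 1e-12) / n) + q * log(n)
    if (bic < best$bic - 1e-9 ||
        (abs(bic - best$bic) <= 1e-9 && q < length(best$idx)) ||
        (abs(bic - best$bic) <= 1e-9 && q == length(best$idx) &&
         length(inc) && paste(inc, collapse = ",") < paste(best$idx, collapse = ","))) {
      best <- list(bic = bic, idx = inc, rss = rss)
    }
  }
  best
}

# minimum-norm least squares through the SVD, coded without MASS
oracle_tfa <- function(P, X) {
  sv <- svd(P)
  pos <- sv$d > max(dim(P)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% X))
}

# precision/recall by explicit prefix counting over a logical hit vector
oracle_prefix_pr <- function(hits, n_pos) {
  prec <- numeric(length(hits)); rec <- numeric(length(hits))
  found <- 0
  for (r in seq_along(hits)) {
    found <- found + hits[r]
    prec[r] <- found / r
    rec[r] <- found / n_pos
  }
  list(precision = prec, recall = rec,
       aupr = sum(prec[hits]) / n_pos)
}

# entropy (bits) of an equal-width-binned vector
oracle_binned_entropy <- function(u, n_bins) {
  r <- range(u)
  b <- pmin(floor((u - r[1]) / (r[2] - r[1]) * n_bins) + 1, n_bins)
  p <- table(b) / length(b)
  -sum(p * log2(p))
}

# evaluate the multitask objective directly from its definition
oracle_amusr_objective <- function(ys, As, S, B, lambda_s, lambda_b) {
  d <- length(ys)
  fit <- sum(vapply(seq_len(d), function(t) {
    sum((ys[[t]] - As[[t]] %*% (S[, t] + B[, t]))^2)
  }, numeric(1)))
  fit + lambda_s * sum(abs(S)) + lambda_b * sum(apply(abs(B), 1, max))
}

# standardize task data exactly as the fitter does, for objective comparisons
standardize_tasks <- function(ys, As) {
  list(
    ys = lapply(ys, function(y) { y <- y - mean(y); s <- sd(y); if (s > 0) y / s else y }),
    As = lapply(As, function(A) { A <- scale(A); A[, !is.finite(colSums(A))] <- 0; A })
  )
}

# deterministic small expression/activity fixture
fixture_activity_data <- function(n = 60, p = 4, seed = 11) {
  set.seed(seed)
  A <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("TF", seq_len(p))))
  A
}
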