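# Eigen-based PLS1 reference implementation, independent of the package's
# NIPALS code path: each weight vector is extracted as the dominant
# eigenvector of the (rank-one) matrix S S' with S = X'y via eigen(),
# deflation and VIP are computed directly from their definitions.
pls1_oracle <- function(X, y, ncomp) {
  xm <- colMeans(X); ym <- mean(y)
  Xa <- sweep(X, 2L, xm); ya <- y - ym
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  q <- ssy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    s <- as.vector(crossprod(Xa, ya))
    ev <- eigen(tcrossprod(s), symmetric = TRUE)
    w <- ev$vectors[, 1L]
    if (sum(w * s) < 0) w <- -w
    t_a <- as.vector(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- as.vector(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a; ssy[a] <- q_a^2 * tt
  }
  b <- as.vector(W %*% solve(crossprod(P, W), q))
  vip <- sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
  list(coef = b, vip = vip,
       predict = function(Xn) as.vector(sweep(Xn, 2L, xm) %*% b) + ym)
}
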