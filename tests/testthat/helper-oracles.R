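# Independent reference implementations used to cross-check the package's
# own code paths.  These are deliberately naive.

# brute-force maximum-correlation classifier: plain loops and cor()
oracle_mcc <- function(train_x, train_y, test_x) {
  classes <- sort(unique(as.character(train_y)))
  templates <- lapply(classes, function(cl)
    colMeans(train_x[train_y == cl, , drop = FALSE]))
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    rs <- vapply(templates, function(tp)
      suppressWarnings(cor(test_x[i, ], tp)), numeric(1))
    rs[!is.finite(rs)] <- -Inf
    out[i] <- if (all(!is.finite(rs))) classes[1] else classes[which.max(rs)]
  }
  out
}

# selectivity index written out longhand
oracle_dprime <- function(p, np) {
  mp <- sum(p) / length(p)
  mnp <- sum(np) / length(np)
  vp <- sum((p - mp)^2) / (length(p) - 1)
  vnp <- sum((np - mnp)^2) / (length(np) - 1)
  (mp - mnp) / sqrt((vp + vnp) / 2)
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  w_all <- apply(combos, 2, function(ix) sum(r[ix]))
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}
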