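# Independent oracles used to check the package's computations. These are
# deliberately written from the model equations directly, sharing no code
# with the package internals.

# explicit fixed-step Euler integration of the direct-mode scheme
euler_direct <- function(spec, params, dt = 0.001, t_end = 60) {
  p <- params
  Rt <- c(0, 0, 0); Rs <- c(0, 0, 0)
  C <- matrix(0, 3, 3)
  P <- 0; rtx <- p$res_tx0; rtl <- p$res_tl0
  nstep <- round(t_end / dt)
  for (s in seq_len(nstep)) {
    act <- p$k_hyb * p$theta * (Rt %o% Rs)
    dRt <- p$k_tx * spec$input_conc * rtx - p$delta_rna * Rt - rowSums(act)
    dRs <- p$k_tx * spec$weight_conc * rtx - p$delta_rna * Rs
    dC <- act - p$delta_rna * C
    v <- p$k_tl * (colSums(C) + p$k_leak * Rs) * rtl
    dP <- sum(v)
    ftx <- p$k_tx * (sum(spec$input_conc) + sum(spec$weight_conc)) * rtx
    drtx <- -p$lambda_res * rtx - p$mu_res * ftx
    drtl <- -p$lambda_res * rtl - p$mu_res * dP * 1000
    Rt <- Rt + dt * dRt; Rs <- Rs + dt * dRs; C <- C + dt * dC
    P <- P + dt * dP; rtx <- rtx + dt * drtx; rtl <- rtl + dt * drtl
  }
  P
}

# bisection on f + anti * f / (kd + f) - tot = 0 over [0, tot]
bisect_free_sigma <- function(tot, anti, kd, iters = 200) {
  if (tot == 0) return(0)
  g <- function(f) f + anti * f / (kd + f) - tot
  lo <- 0; hi <- tot
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# damped fixed-point iteration on the two-ligand competitive RNAP binding
fp_holo28 <- function(s28, e_tot, s70, k28, k70, iters = 500) {
  if (s28 == 0 || e_tot == 0) return(0)
  e <- e_tot
  for (i in seq_len(iters)) {
    e_new <- e_tot / (1 + s28 / (k28 + e) + s70 / (k70 + e))
    e <- 0.5 * e + 0.5 * e_new
  }
  (e * s28 / (k28 + e)) / e_tot
}

# textbook formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

anova_oracle <- function(groups) {
  k <- length(groups); N <- sum(lengths(groups))
  gm <- mean(unlist(groups))
  ssb <- sum(lengths(groups) * (sapply(groups, mean) - gm)^2)
  ssw <- sum(sapply(groups, function(g) sum((g - mean(g))^2)))
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(f = f, df1 = k - 1, df2 = N - k, p = pf(f, k - 1, N - k,
                                              lower.tail = FALSE))
}

t_greater_oracle <- function(x, mu0) {
  n <- length(x)
  t <- (mean(x) - mu0) / (sd(x) / sqrt(n))
  list(t = t, df = n - 1, p = pt(t, n - 1, lower.tail = FALSE))
}

grubbs_oracle <- function(x, alpha = 0.05) {
  n <- length(x)
  G <- max(abs(x - mean(x))) / sd(x)
  tq <- qt(1 - alpha / (2 * n), n - 2)
  crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  list(G = G, crit = crit, flagged = G > crit)
}
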