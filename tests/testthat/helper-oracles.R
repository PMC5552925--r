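# independent oracles used by the model tests

# small multi-track detection data with known logistic truth
toy_glmm_data <- function(seed, sig_true = 1.5, n = 20, k = 3) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(k), function(i) {
    r <- runif(n, 0, 3000)
    u <- rnorm(1, 0, sig_true)
    data.frame(track_id = i, range = r,
               detected = rbinom(n, 1, plogis(2 - 0.001 * r + u)))
  }))
}
toy_acceptance_glmm <- toy_glmm_data

# marginal log-likelihood of a random-intercept logistic model by fine-grid
# trapezoid integration over the track effect (independent of any quadrature)
glmm_loglik_oracle <- function(fit, d) {
  beta <- coef(fit)
  sig <- fit$sigma_track
  sum(vapply(split(d, d$track_id), function(dd) {
    eta0 <- beta[[1]] + beta[[2]] * dd$range
    if (sig < 1e-6) {
      p <- plogis(eta0)
      return(sum(dd$detected * log(p) + (1 - dd$detected) * log1p(-p)))
    }
    u <- seq(-8 * sig, 8 * sig, length.out = 20001)
    du <- u[2] - u[1]
    p <- plogis(outer(eta0, u, "+"))
    lg <- dd$detected * log(p) + (1 - dd$detected) * log1p(-p)
    li <- exp(colSums(lg)) * stats::dnorm(u, 0, sig)
    log(sum((li[-1] + li[-length(li)]) / 2) * du)
  }, 0))
}
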