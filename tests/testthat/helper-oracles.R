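# Independent oracles used across the suite. These deliberately avoid
# the package's own recursion code paths: the latent-state likelihood is
# summed by exhaustive enumeration, and failure-day likelihoods by
# explicit enumeration of the latent failure day.

# Exhaustive enumeration of the open N-mixture site likelihood over all
# latent trajectories (N_1, ..., N_T) in {0..K}^T.
enum_site_loglik <- function(y, mask, lambda, p, gamma, omega, K,
                             mixture = "poisson", alpha = NULL) {
  Tn <- length(y)
  init <- if (mixture == "negbin")
    dnbinom(0:K, size = alpha, mu = lambda) else dpois(0:K, lambda)
  grids <- do.call(expand.grid, rep(list(0:K), Tn))
  tot <- 0
  for (r in seq_len(nrow(grids))) {
    N <- as.integer(grids[r, ])
    pr <- init[N[1] + 1]
    if (pr == 0) next
    if (Tn > 1) for (t in 2:Tn) {
      s <- 0:min(N[t], N[t - 1])
      pr <- pr * sum(dbinom(s, N[t - 1], omega) * dpois(N[t] - s, gamma))
    }
    for (t in seq_len(Tn))
      if (mask[t]) pr <- pr * dbinom(y[t], N[t], p[t])
    tot <- tot + pr
  }
  log(tot)
}

# Brute-force smoothing posterior of N_t given all counts, by
# enumerating trajectories and accumulating joint mass.
enum_posterior <- function(y, mask, lambda, p, gamma, omega, K) {
  Tn <- length(y)
  init <- dpois(0:K, lambda)
  grids <- do.call(expand.grid, rep(list(0:K), Tn))
  post <- matrix(0, K + 1, Tn)
  for (r in seq_len(nrow(grids))) {
    N <- as.integer(grids[r, ])
    pr <- init[N[1] + 1]
    if (Tn > 1) for (t in 2:Tn) {
      s <- 0:min(N[t], N[t - 1])
      pr <- pr * sum(dbinom(s, N[t - 1], omega) * dpois(N[t] - s, gamma))
    }
    for (t in seq_len(Tn))
      if (mask[t]) pr <- pr * dbinom(y[t], N[t], p[t])
    for (t in seq_len(Tn)) post[N[t] + 1, t] <- post[N[t] + 1, t] + pr
  }
  sweep(post, 2, colSums(post), "/")
}

# Failure-term likelihood by enumerating the latent failure day within a
# window of w days at constant daily survival s.
enum_failure_prob <- function(s, w) {
  sum(vapply(1:w, function(d) s^(d - 1) * (1 - s), numeric(1)))
}

# A small deterministic encounter-record fixture.
toy_records <- function() {
  nest_records(data.frame(
    nest_id = paste0("n", 1:4), plot_id = c("A", "A", "B", "B"),
    first_found = c(5L, 3L, 10L, 8L),
    last_active = c(15L, 9L, 13L, 8L),
    last_checked = c(15L, 12L, 13L, 11L),
    fate = c("success", "failure", "success", "failure"),
    year = c("y1", "y1", "y2", "y2")))
}
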