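# Shared test oracles and fixture builders. The enumeration oracle computes
# DBN likelihoods by brute force over all hidden-state sequences; it shares
# no code with the package's forward recursion.

# Brute-force log-likelihood: sum over all H^T hidden sequences of the
# product of initial/transition probabilities and (observed-slice) von Mises
# densities. angles: per-slice evidence, NA = unobserved.
enum_loglik <- function(model, aa, angles) {
  idx <- slice_sequence(model$spec, aa) + 1L
  T_ <- length(idx)
  H <- model$hidden
  grid <- as.matrix(expand.grid(rep(list(seq_len(H)), T_)))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    h <- grid[r, ]
    p <- model$initial[idx[1], h[1]]
    if (T_ > 1) {
      for (t in 2:T_) p <- p * model$transition[h[t - 1], h[t], idx[t]]
    }
    for (t in seq_len(T_)) {
      if (!is.na(angles[t])) {
        p <- p * dvm(angles[t], model$emission$mu[h[t]],
                     model$emission$kappa[h[t]])
      }
    }
    tot <- tot + p
  }
  log(tot)
}

# Brute-force per-slice hidden posteriors for the same evidence.
enum_posterior <- function(model, aa, angles) {
  idx <- slice_sequence(model$spec, aa) + 1L
  T_ <- length(idx)
  H <- model$hidden
  grid <- as.matrix(expand.grid(rep(list(seq_len(H)), T_)))
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    h <- grid[r, ]
    p <- model$initial[idx[1], h[1]]
    if (T_ > 1) {
      for (t in 2:T_) p <- p * model$transition[h[t - 1], h[t], idx[t]]
    }
    for (t in seq_len(T_)) {
      if (!is.na(angles[t])) {
        p <- p * dvm(angles[t], model$emission$mu[h[t]],
                     model$emission$kappa[h[t]])
      }
    }
    w[r] <- p
  }
  w <- w / sum(w)
  post <- matrix(0, T_, H)
  for (t in seq_len(T_)) {
    for (s in seq_len(H)) post[t, s] <- sum(w[grid[, t] == s])
  }
  post
}

# Small random model for oracle comparisons.
toy_model <- function(hidden = 2, aa = c(HIS = 2L), seed = 1,
                      kappa = NULL) {
  spec <- chi_spec(hidden, aa)
  params <- sidechainr:::random_params(spec, seed = seed)
  if (!is.null(kappa)) params$emission$kappa <- rep(kappa, hidden)
  sidechainr:::new_chi_dbn(spec, params)
}

# Model with no backbone coupling by construction: every transition row is
# the same distribution, so hidden states are independent across slices and
# the conditional chi distribution equals the marginal.
uncoupled_model <- function(hidden = 3, aa = c(SER = 1L, HIS = 2L),
                            seed = 2) {
  m <- toy_model(hidden, aa, seed)
  pi_h <- m$initial[1, ]
  for (k in seq_len(m$spec$K)) {
    m$transition[, , k] <- matrix(pi_h, hidden, hidden, byrow = TRUE)
  }
  m$initial <- matrix(pi_h, m$spec$K, hidden, byrow = TRUE)
  m
}

# Histogram bin probabilities of a density function by per-bin quadrature
# (21-point midpoint rule per bin), normalized.
bin_probs <- function(dens_fun, breaks) {
  nb <- length(breaks) - 1
  p <- vapply(seq_len(nb), function(b) {
    xs <- seq(breaks[b], breaks[b + 1], length.out = 22)
    xs <- (xs[-1] + xs[-22]) / 2
    mean(dens_fun(xs)) * (breaks[b + 1] - breaks[b])
  }, 0)
  p / sum(p)
}

# Chi-squared goodness-of-fit p-value of samples against a density.
gof_pvalue <- function(x, dens_fun, nb = 50) {
  br <- seq(-pi, pi, length.out = nb + 1)
  obs <- hist(x, breaks = br, plot = FALSE)$counts
  p <- bin_probs(dens_fun, br)
  suppressWarnings(stats::chisq.test(obs, p = p)$p.value)
}

# Path to the installed CLI script.
cli_path <- function() {
  system.file("cli", "sidechainr", package = "sidechainr")
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  res <- suppressWarnings(system2(rscript, c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  list(status = attr(res, "status") %||% 0L, output = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
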