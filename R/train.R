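# Maximum-likelihood training of the chi DBN by expectation-maximization,
# with AIC-based selection of the hidden-node size.
#
# The exact variant computes expected hidden-state counts by forward-backward
# smoothing; the stochastic variant draws hidden-state sequences from their
# exact posterior (forward-backtrack) and uses hard counts. Both share the
# same M-step: CPD rows from (expected or sampled) counts plus a pseudocount,
# emissions by weighted von Mises maximum likelihood.

# Precompute per-group evidence matrices: rows grouped by (aa, phi/psi
# missingness). Chi angles must be present for every modelled column.
prep_groups <- function(spec, data) {
  key <- paste(data$aa, is.na(data$phi), is.na(data$psi))
  lapply(split(seq_len(nrow(data)), key), function(sel) {
    aa <- data$aa[sel[1]]
    if (!aa %in% names(spec$aa)) {
      stop("amino acid not modelled: ", aa, call. = FALSE)
    }
    nchi <- spec$aa[[aa]]
    chi <- as.matrix(data[sel, paste0("chi", seq_len(nchi)), drop = FALSE])
    if (any(is.na(chi))) {
      stop("missing chi angle in training data for ", aa, call. = FALSE)
    }
    bb <- cbind(data$phi[sel], data$psi[sel])
    list(idx = slice_sequence(spec, aa) + 1L,
         X = cbind(ifelse(is.na(bb), 0, bb), chi),
         M = cbind(!is.na(bb), matrix(TRUE, length(sel), nchi)))
  })
}

# One EM iteration. Returns list(params, loglik) where loglik is the total
# log-likelihood under the INCOMING parameters.
em_step <- function(model, groups, pseudocount, stochastic = FALSE) {
  H <- model$hidden
  K <- model$spec$K
  init_counts <- matrix(0, K, H)
  trans_counts <- array(0, dim = c(H, H, K))
  Sw <- numeric(H); Ss <- numeric(H); Sc <- numeric(H)
  loglik <- 0
  for (g in groups) {
    T_ <- length(g$idx)
    fwd <- forward_batch(model, g$idx, g$X, g$M)
    loglik <- loglik + sum(fwd$loglik)
    if (stochastic) {
      hs <- backtrack_hidden(model, g$idx, fwd)
      tab1 <- tabulate(hs[, 1], H)
      init_counts[g$idx[1], ] <- init_counts[g$idx[1], ] + tab1
      for (t in seq_len(T_)[-1]) {
        lin <- hs[, t - 1] + H * (hs[, t] - 1L)
        trans_counts[, , g$idx[t]] <- trans_counts[, , g$idx[t]] +
          matrix(tabulate(lin, H * H), H, H)
      }
      for (t in seq_len(T_)) {
        obs <- g$M[, t]
        if (!any(obs)) next
        h <- hs[obs, t]
        x <- g$X[obs, t]
        Sw <- Sw + tabulate(h, H)
        Ss <- Ss + vapply(seq_len(H), function(s) sum(sin(x[h == s])), 0)
        Sc <- Sc + vapply(seq_len(H), function(s) sum(cos(x[h == s])), 0)
      }
    } else {
      beta <- backward_batch(model, g$idx, g$X, g$M, fwd)
      gam1 <- fwd$alpha[[1]] * beta[[1]]
      init_counts[g$idx[1], ] <- init_counts[g$idx[1], ] + colSums(gam1)
      for (t in seq_len(T_)[-1]) {
        A <- trans_mat(model, g$idx[t])
        E <- emis_slice(model, g$X[, t], g$M[, t])
        B <- E * beta[[t]] / exp(fwd$logc[, t])
        trans_counts[, , g$idx[t]] <- trans_counts[, , g$idx[t]] +
          A * crossprod(fwd$alpha[[t - 1]], B)
      }
      for (t in seq_len(T_)) {
        obs <- g$M[, t]
        if (!any(obs)) next
        w <- (fwd$alpha[[t]] * beta[[t]])[obs, , drop = FALSE]
        x <- g$X[obs, t]
        Sw <- Sw + colSums(w)
        Ss <- Ss + as.numeric(crossprod(w, sin(x)))
        Sc <- Sc + as.numeric(crossprod(w, cos(x)))
      }
    }
  }
  # M-step: rows with no mass (and zero pseudocount) keep their old values.
  initial <- model$initial
  for (k in seq_len(K)) {
    rs <- init_counts[k, ] + pseudocount
    if (sum(rs) > 0) initial[k, ] <- rs / sum(rs)
  }
  transition <- model$transition
  for (k in seq_len(K)) {
    Ck <- matrix(trans_counts[, , k], H, H) + pseudocount
    rs <- rowSums(Ck)
    upd <- rs > 0
    if (any(upd)) {
      transition[upd, , k] <- Ck[upd, , drop = FALSE] / rs[upd]
    }
  }
  mu <- model$emission$mu
  kappa <- model$emission$kappa
  for (s in seq_len(H)) {
    if (Sw[s] > 0) {
      mu[s] <- wrap_angle(atan2(Ss[s], Sc[s]))
      R <- min(sqrt(Ss[s]^2 + Sc[s]^2) / Sw[s], 1)
      kappa[s] <- vm_kappa_from_R(R)
    }
  }
  list(params = list(initial = initial, transition = transition,
                     emission = list(mu = mu, kappa = kappa)),
       loglik = loglik)
}

# Single EM run from a random initialization.
em_run <- function(spec, groups, n, variant, max_iter, tol, pseudocount,
                   seed, verbose = FALSE) {
  model <- new_chi_dbn(spec, random_params(spec, seed = seed))
  trace <- numeric(0)
  last <- -Inf
  stochastic <- variant == "stochastic"
  for (it in seq_len(max_iter)) {
    it_seed <- if (stochastic) (seed + it) %% (.Machine$integer.max - 1) else NULL
    step <- with_seed(it_seed, em_step(model, groups, pseudocount, stochastic))
    trace <- c(trace, step$loglik)
    if (verbose) message(sprintf("iter %3d  loglik %.4f", it, step$loglik))
    improved <- (step$loglik - last) / n
    model <- new_chi_dbn(spec, step$params)
    if (is.finite(last) && improved < tol) break
    last <- step$loglik
  }
  # final log-likelihood under the final parameters
  final <- sum(vapply(groups,
                      function(g) sum(forward_batch(model, g$idx, g$X,
                                                    g$M)$loglik), 0))
  list(model = model, trace = c(trace, final), loglik = final)
}

#' AIC score
#'
#' `2k - 2 logLik`; lower is better. Used to select the hidden-node size.
#'
#' @param loglik log-likelihood of the fitted model.
#' @param k number of free parameters.
#' @return the AIC score.
#' @export
aic_score <- function(loglik, k) {
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  2 * k - 2 * loglik
}

#' Fit the side-chain DBN by expectation-maximization
#'
#' Estimates the model's initial, transition and von Mises emission
#' parameters from an angle table by maximum likelihood. Rows with missing
#' phi/psi are allowed (the backbone slices are treated as unobserved); chi
#' angles must be present for every modelled position.
#'
#' @param data a `chi_angles` data.frame (see [angle_table()], [read_angles()]).
#' @param hidden hidden-node size H.
#' @param variant `"exact"` (forward-backward expected counts; default) or
#'   `"stochastic"` (hidden sequences sampled from their exact posterior).
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the per-residue log-likelihood
#'   improvement (nats).
#' @param restarts number of random restarts; the best final log-likelihood
#'   wins.
#' @param pseudocount added to every CPD cell in the M-step.
#' @param seed integer seed; per-restart seeds are derived from it.
#' @param aa amino-acid chi-count table defining the spec (default:
#'   the types present in `data`, with canonical chi counts).
#' @param verbose print per-iteration log-likelihoods.
#' @return an object of class `chi_dbn` with components `hidden`, `spec`,
#'   `initial`, `transition`, `emission`, `logLik`, `trace` (per-iteration
#'   total log-likelihood of the winning restart), `aic`, `k`, `n`.
#' @seealso [select_hidden()], [loglik_chi()], [sample_ancestral()],
#'   [sample_conditional()]
#' @export
chi_dbn <- function(data, hidden = 15, variant = c("exact", "stochastic"),
                    max_iter = 300, tol = 1e-6, restarts = 1,
                    pseudocount = 1e-3, seed = NULL, aa = NULL,
                    verbose = FALSE) {
  variant <- match.arg(variant)
  if (nrow(data) == 0) stop("empty training data", call. = FALSE)
  if (tol <= 0) stop("tol must be > 0", call. = FALSE)
  if (restarts < 1) stop("restarts must be >= 1", call. = FALSE)
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  if (is.null(aa)) {
    present <- sort(unique(data$aa))
    known <- chi_counts()
    if (!all(present %in% names(known))) {
      stop("unknown amino acid(s): ",
           paste(setdiff(present, names(known)), collapse = ", "),
           call. = FALSE)
    }
    aa <- known[present]
  }
  spec <- chi_spec(hidden, aa)
  groups <- prep_groups(spec, data)
  n <- nrow(data)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, restarts))
  runs <- lapply(seq_len(restarts), function(r) {
    em_run(spec, groups, n, variant, max_iter, tol, pseudocount,
           seed = seeds[r], verbose = verbose)
  })
  best <- runs[[which.max(vapply(runs, `[[`, 0, "loglik"))]]
  k <- count_parameters(best$model)
  m <- best$model
  m$logLik <- best$loglik
  m$trace <- best$trace
  m$k <- k
  m$aic <- aic_score(best$loglik, k)
  m$n <- n
  m$call <- match.call()
  m
}

#' Hidden-node size selection by AIC
#'
#' Trains `restarts` models for each candidate hidden size and keeps the
#' model with the lowest AIC overall.
#'
#' @param data a `chi_angles` data.frame.
#' @param hidden_sizes integer vector of candidate hidden sizes.
#' @param restarts models trained per size.
#' @param seed master seed; each (size, restart) gets a derived seed.
#' @param ... passed to [chi_dbn()] (`variant`, `max_iter`, `tol`, ...).
#' @return an object of class `chi_dbn_scan`: list with `best` (the winning
#'   `chi_dbn`), `table` (data.frame with one row per size x restart:
#'   `hidden`, `restart`, `logLik`, `k`, `aic`).
#' @export
select_hidden <- function(data, hidden_sizes, restarts = 5, seed = NULL,
                          ...) {
  if (length(hidden_sizes) == 0) {
    stop("hidden_sizes must be non-empty", call. = FALSE)
  }
  seeds <- with_seed(seed,
                     sample.int(.Machine$integer.max - 1,
                                length(hidden_sizes) * restarts))
  rows <- list()
  best <- NULL
  i <- 0
  for (Hs in hidden_sizes) {
    for (r in seq_len(restarts)) {
      i <- i + 1
      fit <- chi_dbn(data, hidden = Hs, restarts = 1, seed = seeds[i], ...)
      rows[[i]] <- data.frame(hidden = Hs, restart = r, logLik = fit$logLik,
                              k = fit$k, aic = fit$aic)
      if (is.null(best) || fit$aic < best$aic) best <- fit
    }
  }
  structure(list(best = best, table = do.call(rbind, rows)),
            class = "chi_dbn_scan")
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.chi_dbn <- function(x, ...) {
  cat("Side-chain DBN (von Mises emissions)\n")
  cat(sprintf("  amino acids: %d   input indices: %d   hidden states: %d\n",
              length(x$spec$aa), x$spec$K, x$hidden))
  if (!is.na(x$logLik)) {
    cat(sprintf("  logLik: %.2f on n = %d residues (k = %d, AIC = %.2f)\n",
                x$logLik, x$n, x$k, x$aic))
  }
  invisible(x)
}

#' @export
summary.chi_dbn <- function(object, ...) {
  print(object)
  cat(sprintf("  free parameters (dense): %d;  non-zero: %d\n",
              count_parameters(object),
              count_parameters(object, nonzero_only = TRUE)))
  em <- data.frame(state = seq_len(object$hidden),
                   mu = object$emission$mu,
                   kappa = object$emission$kappa)
  cat("  emission components (mu in radians):\n")
  print(utils::head(em, 10), row.names = FALSE)
  if (object$hidden > 10) cat("  ...\n")
  invisible(object)
}

#' @export
logLik.chi_dbn <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
coef.chi_dbn <- function(object, ...) {
  data.frame(state = seq_len(object$hidden),
             mu = object$emission$mu,
             kappa = object$emission$kappa)
}

#' Simulate residues from a fitted model
#'
#' Ancestral draws of (phi, psi, chi) for a given amino acid; a thin wrapper
#' around [sample_ancestral()] following the [stats::simulate()] convention.
#'
#' @param object a `chi_dbn` object.
#' @param nsim number of residues.
#' @param seed optional integer seed.
#' @param aa 3-letter amino-acid code (defaults to the first modelled type).
#' @param ... unused.
#' @return a `chi_angles` data.frame with `nsim` rows.
#' @export
simulate.chi_dbn <- function(object, nsim = 1, seed = NULL,
                             aa = names(object$spec$aa)[1], ...) {
  sample_ancestral(object, aa, nsim, seed = seed)
}

#' Predict method: chi log-densities for new residues
#'
#' @param object a `chi_dbn` object.
#' @param newdata a `chi_angles` data.frame.
#' @param backbone `"marginal"` or `"conditional"` (see [loglik_chi()]).
#' @param ... unused.
#' @return numeric vector of per-residue log-densities (nats).
#' @export
predict.chi_dbn <- function(object, newdata,
                            backbone = c("marginal", "conditional"), ...) {
  loglik_chi(object, newdata, backbone = match.arg(backbone))
}

#' Model density of a single chi angle
#'
#' Evaluates, on a regular grid, the model's density of one chi angle with
#' all other chi angles marginalized out — backbone-independent by default,
#' or conditioned on (phi, psi) when both are supplied. This is the
#' quadrature-friendly view of the model used for plotting and for
#' histogram-vs-density checks.
#'
#' @param model a `chi_dbn` object.
#' @param aa 3-letter amino-acid code.
#' @param chi_index which chi angle (1-based).
#' @param phi,psi optional backbone angles in radians; supply both to
#'   condition on the backbone.
#' @param n_grid number of grid points over `[-pi, pi)`.
#' @return data.frame with columns `x` (radians) and `density` (per radian).
#' @export
chi_density <- function(model, aa, chi_index = 1, phi = NULL, psi = NULL,
                        n_grid = 361) {
  validate_chi_dbn(model)
  nchi <- model$spec$aa[[aa]]
  if (chi_index < 1 || chi_index > nchi) {
    stop("chi_index out of range for ", aa, call. = FALSE)
  }
  idx <- slice_sequence(model$spec, aa) + 1L
  T_ <- length(idx)
  grid <- seq(-pi, pi, length.out = n_grid + 1)[seq_len(n_grid)]
  cond <- !is.null(phi) && !is.null(psi)
  X <- matrix(0, n_grid, T_)
  M <- matrix(FALSE, n_grid, T_)
  X[, 2 + chi_index] <- grid
  M[, 2 + chi_index] <- TRUE
  if (cond) {
    X[, 1] <- phi; X[, 2] <- psi
    M[, 1] <- M[, 2] <- TRUE
    ll_joint <- forward_batch(model, idx, X, M)$loglik
    ll_bb <- forward_batch(model, idx, X[1, , drop = FALSE],
                           matrix(c(TRUE, TRUE, rep(FALSE, T_ - 2)), 1))$loglik
    dens <- exp(ll_joint - ll_bb)
  } else {
    dens <- exp(forward_batch(model, idx, X, M)$loglik)
  }
  data.frame(x = grid, density = dens)
}

#' Plot emission components and a marginal chi density
#'
#' Base-graphics display: the marginal model density of a chosen chi angle
#' (solid line), with the shared von Mises emission components underneath
#' (dotted, scaled by 1/H) for orientation.
#'
#' @param x a `chi_dbn` object.
#' @param aa 3-letter amino-acid code (default: first modelled type).
#' @param chi_index which chi angle to display.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.chi_dbn <- function(x, aa = names(x$spec$aa)[1], chi_index = 1, ...) {
  d <- chi_density(x, aa, chi_index)
  graphics::plot(d$x, d$density, type = "l", lwd = 2,
                 xlab = sprintf("chi%d of %s (radians)", chi_index, aa),
                 ylab = "density (per radian)", ...)
  for (s in seq_len(x$hidden)) {
    graphics::lines(d$x, dvm(d$x, x$emission$mu[s], x$emission$kappa[s]) /
                      x$hidden, lty = 3)
  }
  invisible(x)
}

#' @export
print.chi_dbn_scan <- function(x, ...) {
  cat("Hidden-size selection by AIC\n")
  agg <- stats::aggregate(aic ~ hidden, data = x$table, FUN = min)
  names(agg)[2] <- "best_aic"
  print(agg, row.names = FALSE)
  cat(sprintf("selected: H = %d (AIC = %.2f)\n", x$best$hidden, x$best$aic))
  invisible(x)
}
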