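# Exact inference in the chi DBN: scaled forward recursions with evidence
# masks, forward-backward posteriors, ancestral sampling and forward-backtrack
# conditional sampling.
#
# All likelihood values are per-radian log-DENSITIES in nats (the emissions
# are continuous); unobserved slices contribute an emission factor of 1,
# i.e. they are marginalized out.
#
# Internals are batched: residues sharing an amino acid (hence an index
# sequence) and an observation mask are processed as rows of matrices, which
# keeps EM training and large sampling runs fast in pure R.

# Transition matrix for input index k, robust to H = 1 dimension dropping.
trans_mat <- function(model, k) {
  matrix(model$transition[, , k], model$hidden, model$hidden)
}

# Emission density matrix for one slice: n x H, rows are residues. Unobserved
# rows are 1 (marginalization).
emis_slice <- function(model, x, obs) {
  n <- length(x)
  H <- model$hidden
  E <- matrix(1, n, H)
  if (any(obs)) {
    xo <- x[obs]
    # outer over the H shared von Mises components
    L <- outer(xo, model$emission$mu, function(a, m) a - m)
    E[obs, ] <- exp(sweep(cos(L) %*% diag(model$emission$kappa, H), 2,
                          log(2 * pi) + log_bessel_i0(model$emission$kappa),
                          "-"))
  }
  E
}

# Scaled forward pass for a batch of residues with a common index sequence.
# idx: 1-based input indices (length T); X: n x T angles; M: n x T observed.
# Returns alpha (list of n x H row-normalized matrices), logc (n x T),
# loglik (n).
forward_batch <- function(model, idx, X, M) {
  n <- nrow(X)
  T_ <- length(idx)
  H <- model$hidden
  alpha <- vector("list", T_)
  logc <- matrix(0, n, T_)
  E <- emis_slice(model, X[, 1], M[, 1])
  a <- sweep(E, 2, model$initial[idx[1], ], "*")
  cs <- rowSums(a)
  alpha[[1]] <- a / cs
  logc[, 1] <- log(cs)
  if (T_ > 1) {
    for (t in 2:T_) {
      A <- trans_mat(model, idx[t])
      E <- emis_slice(model, X[, t], M[, t])
      a <- (alpha[[t - 1]] %*% A) * E
      cs <- rowSums(a)
      alpha[[t]] <- a / cs
      logc[, t] <- log(cs)
    }
  }
  list(alpha = alpha, logc = logc, loglik = rowSums(logc))
}

# Backward pass matching forward_batch's scaling. Returns beta (list of
# n x H matrices) such that gamma_t = alpha_t * beta_t sums to 1 per row.
backward_batch <- function(model, idx, X, M, fwd) {
  n <- nrow(X)
  T_ <- length(idx)
  H <- model$hidden
  beta <- vector("list", T_)
  beta[[T_]] <- matrix(1, n, H)
  if (T_ > 1) {
    for (t in T_:2) {
      A <- trans_mat(model, idx[t])
      E <- emis_slice(model, X[, t], M[, t])
      b <- (E * beta[[t]] / exp(fwd$logc[, t])) %*% t(A)
      beta[[t - 1]] <- b
    }
  }
  beta
}

# Draw hidden-state sequences from their exact posterior given the evidence,
# using the forward lattice: H_T ~ alpha_T, then
# H_t | H_{t+1} proportional to alpha_t(h) * A(h, H_{t+1}).
# Returns an n x T integer matrix. Uses the current RNG stream.
backtrack_hidden <- function(model, idx, fwd) {
  T_ <- length(idx)
  n <- nrow(fwd$alpha[[1]])
  H <- model$hidden
  hs <- matrix(0L, n, T_)
  hs[, T_] <- sample_rows(fwd$alpha[[T_]])
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      A <- trans_mat(model, idx[t + 1])
      W <- fwd$alpha[[t]] * t(A)[hs[, t + 1], , drop = FALSE]
      hs[, t] <- sample_rows(W / rowSums(W))
    }
  }
  hs
}

# One categorical draw per row of a row-stochastic matrix (inverse CDF).
sample_rows <- function(P) {
  if (ncol(P) == 1) return(rep(1L, nrow(P)))
  cp <- t(apply(P, 1, cumsum))
  u <- stats::runif(nrow(P))
  as.integer(rowSums(cp < u) + 1L)
}

# Draw one von Mises angle per element of a hidden-state vector, grouping by
# state so the rejection sampler runs in batches.
emit_angles <- function(model, h) {
  out <- numeric(length(h))
  for (s in unique(h)) {
    sel <- h == s
    out[sel] <- rvm(sum(sel), model$emission$mu[s], model$emission$kappa[s])
  }
  out
}

# Evidence checks shared by the exported single-residue entry points.
check_evidence <- function(spec, aa, angles) {
  T_ <- 2L + spec$aa[[aa]]
  if (length(angles) != T_) {
    stop("evidence length ", length(angles), " does not match the ", T_,
         " slices of ", aa, call. = FALSE)
  }
  if (any(is.infinite(angles))) stop("angles must be finite or NA",
                                     call. = FALSE)
  invisible(T_)
}

#' Forward algorithm over one residue's slices
#'
#' Computes the scaled forward lattice for a residue of type `aa` with the
#' given evidence. `angles` is the per-slice evidence vector (phi, psi,
#' chi1..chin) in radians; `NA` marks a slice as unobserved, in which case it
#' is marginalized out. The log-likelihood is the log joint density of the
#' observed angles (nats); with no observed slice it is 0.
#'
#' @param model a `chi_dbn` object.
#' @param aa 3-letter amino-acid code.
#' @param angles numeric vector of length `2 + n_chi`, `NA` = unobserved.
#' @return an object of class `forward_lattice`: list with `alpha` (T x H
#'   row-normalized matrix), `log_scale` (length T) and `loglik`.
#' @export
forward_dbn <- function(model, aa, angles) {
  validate_chi_dbn(model)
  check_evidence(model$spec, aa, angles)
  idx <- slice_sequence(model$spec, aa) + 1L
  X <- matrix(ifelse(is.na(angles), 0, angles), 1)
  M <- matrix(!is.na(angles), 1)
  fwd <- forward_batch(model, idx, X, M)
  structure(list(alpha = do.call(rbind, lapply(fwd$alpha, as.numeric)),
                 log_scale = as.numeric(fwd$logc),
                 loglik = fwd$loglik),
            class = "forward_lattice")
}

#' Per-slice posteriors of the hidden nodes
#'
#' Exact forward-backward smoothing: the posterior distribution of each
#' slice's hidden node given the evidence.
#'
#' @inheritParams forward_dbn
#' @return T x H matrix; each row sums to 1.
#' @export
posterior_hidden <- function(model, aa, angles) {
  validate_chi_dbn(model)
  check_evidence(model$spec, aa, angles)
  idx <- slice_sequence(model$spec, aa) + 1L
  X <- matrix(ifelse(is.na(angles), 0, angles), 1)
  M <- matrix(!is.na(angles), 1)
  fwd <- forward_batch(model, idx, X, M)
  beta <- backward_batch(model, idx, X, M, fwd)
  G <- vapply(seq_along(idx),
              function(t) as.numeric(fwd$alpha[[t]] * beta[[t]]),
              numeric(model$hidden))
  t(G / rep(colSums(G), each = model$hidden))
}

# Batched chi log-density over the rows of an angle table. Rows are grouped
# by (aa, phi/psi-missing pattern); within a group a single matrix pipeline
# evaluates all residues.
loglik_chi_batch <- function(model, data, backbone) {
  out <- rep(NA_real_, nrow(data))
  key <- paste(data$aa, is.na(data$phi), is.na(data$psi))
  for (g in unique(key)) {
    sel <- which(key == g)
    aa <- data$aa[sel[1]]
    if (!aa %in% names(model$spec$aa)) {
      stop("amino acid not modelled: ", aa, call. = FALSE)
    }
    nchi <- model$spec$aa[[aa]]
    idx <- slice_sequence(model$spec, aa) + 1L
    chi <- as.matrix(data[sel, paste0("chi", seq_len(nchi)), drop = FALSE])
    if (any(is.na(chi))) {
      stop("missing chi angle for modelled residue of type ", aa,
           call. = FALSE)
    }
    bb <- cbind(data$phi[sel], data$psi[sel])
    X <- cbind(ifelse(is.na(bb), 0, bb), chi)
    T_ <- 2L + nchi
    n <- length(sel)
    if (backbone == "conditional") {
      if (any(is.na(bb))) {
        stop("conditional mode requires phi and psi to be present",
             call. = FALSE)
      }
      M_all <- matrix(TRUE, n, T_)
      M_bb <- cbind(matrix(TRUE, n, 2), matrix(FALSE, n, nchi))
      out[sel] <- forward_batch(model, idx, X, M_all)$loglik -
        forward_batch(model, idx, X, M_bb)$loglik
    } else {
      M <- cbind(matrix(FALSE, n, 2), matrix(TRUE, n, nchi))
      out[sel] <- forward_batch(model, idx, X, M)$loglik
    }
  }
  out
}

#' Log-density of side-chain angles under the model
#'
#' Backbone-independent mode (`backbone = "marginal"`) marginalizes the
#' phi/psi slices out and returns `log p(chi | aa)`. Backbone-dependent mode
#' (`backbone = "conditional"`) conditions on the observed backbone:
#' `log p(chi | aa, phi, psi) = log p(chi, phi, psi) - log p(phi, psi)`,
#' both terms computed by the forward algorithm. Values are per-radian
#' densities in nats.
#'
#' @param model a `chi_dbn` object.
#' @param data a `chi_angles` data.frame (see [angle_table()]).
#' @param backbone `"marginal"` or `"conditional"`.
#' @return numeric vector of log-densities, one per row of `data`.
#' @export
loglik_chi <- function(model, data, backbone = c("marginal", "conditional")) {
  backbone <- match.arg(backbone)
  validate_chi_dbn(model)
  loglik_chi_batch(model, data, backbone)
}

#' Ancestral sampling of full residue angle sets
#'
#' Samples phi, psi and all chi angles for `n` residues of type `aa` by
#' root-to-leaf (ancestral) sampling of the DBN.
#'
#' @param model a `chi_dbn` object.
#' @param aa 3-letter amino-acid code.
#' @param n number of residues to draw.
#' @param seed optional integer seed for reproducibility.
#' @return a `chi_angles` data.frame with `n` rows.
#' @export
sample_ancestral <- function(model, aa, n, seed = NULL) {
  validate_chi_dbn(model)
  if (!aa %in% names(model$spec$aa)) {
    stop("amino acid not modelled: ", aa, call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  idx <- slice_sequence(model$spec, aa) + 1L
  T_ <- length(idx)
  H <- model$hidden
  with_seed(seed, {
    X <- matrix(0, n, T_)
    h <- sample_rows(matrix(model$initial[idx[1], ], n, H, byrow = TRUE))
    X[, 1] <- emit_angles(model, h)
    for (t in seq_len(T_)[-1]) {
      A <- trans_mat(model, idx[t])
      h <- sample_rows(A[h, , drop = FALSE])
      X[, t] <- emit_angles(model, h)
    }
    angle_table(rep(aa, n), X[, 1], X[, 2], X[, -(1:2), drop = FALSE])
  })
}

#' Conditional sampling of chi angles given the backbone
#'
#' Exact draws from `p(chi | aa, phi, psi)` by the forward-backtrack
#' algorithm: a forward pass with phi/psi observed and the chi slices
#' marginalized, then backward sampling of the hidden nodes from the lattice
#' and emission of the chi angles.
#'
#' @param model a `chi_dbn` object.
#' @param aa 3-letter amino-acid code.
#' @param phi,psi backbone angles in radians (finite).
#' @param n number of chi vectors to draw.
#' @param seed optional integer seed.
#' @return n x n_chi matrix of chi angles in radians.
#' @export
sample_conditional <- function(model, aa, phi, psi, n, seed = NULL) {
  validate_chi_dbn(model)
  if (!aa %in% names(model$spec$aa)) {
    stop("amino acid not modelled: ", aa, call. = FALSE)
  }
  if (!is.finite(phi) || !is.finite(psi)) {
    stop("phi and psi must be finite in conditional sampling", call. = FALSE)
  }
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  nchi <- model$spec$aa[[aa]]
  idx <- slice_sequence(model$spec, aa) + 1L
  T_ <- length(idx)
  with_seed(seed, {
    X <- matrix(rep(c(phi, psi, numeric(nchi)), each = n), n, T_)
    M <- cbind(matrix(TRUE, n, 2), matrix(FALSE, n, nchi))
    fwd <- forward_batch(model, idx, X, M)
    hs <- backtrack_hidden(model, idx, fwd)
    chi <- matrix(0, n, nchi)
    for (j in seq_len(nchi)) chi[, j] <- emit_angles(model, hs[, 2 + j])
    colnames(chi) <- paste0("chi", seq_len(nchi))
    chi
  })
}
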