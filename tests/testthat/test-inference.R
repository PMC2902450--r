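test_that("forward log-likelihood matches exhaustive enumeration", {
  set.seed(1)
  cases <- list(list(H = 2, aa = c(HIS = 2L)),
                list(H = 3, aa = c(SER = 1L)),
                list(H = 4, aa = c(LYS = 4L)))   # 6 slices, 4^6 sequences
  for (cs in cases) {
    m <- toy_model(cs$H, cs$aa, seed = cs$H + 10)
    aa <- names(cs$aa)[1]
    T_ <- 2 + cs$aa[[1]]
    for (rep in 1:3) {
      angles <- stats::runif(T_, -pi, pi)
      # random observation mask, at least one slice observed
      mask <- stats::runif(T_) < 0.7
      if (!any(mask)) mask[1] <- TRUE
      ev <- ifelse(mask, angles, NA)
      expect_equal(forward_dbn(m, aa, ev)$loglik, enum_loglik(m, aa, ev),
                   tolerance = 1e-10)
    }
  }
})

test_that("uniform emissions and total marginalization give closed forms", {
  m <- toy_model(3, c(LYS = 4L), seed = 4, kappa = 0)
  ev <- stats::runif(6, -pi, pi)
  expect_equal(forward_dbn(m, "LYS", ev)$loglik, -6 * log(2 * pi),
               tolerance = 1e-12)
  m2 <- toy_model(3, c(LYS = 4L), seed = 5)
  expect_equal(forward_dbn(m2, "LYS", rep(NA_real_, 6))$loglik, 0,
               tolerance = 1e-12)
})

test_that("conditional chi log-density equals the enumeration log-ratio
           and normalizes by quadrature", {
  m <- toy_model(2, c(HIS = 2L), seed = 21)
  df <- angle_table("HIS", 0.3, -1.2, matrix(c(2.0, -2.5, NA, NA), 1))
  ll <- loglik_chi(m, df, "conditional")
  oracle <- enum_loglik(m, "HIS", c(0.3, -1.2, 2.0, -2.5)) -
    enum_loglik(m, "HIS", c(0.3, -1.2, NA, NA))
  expect_equal(ll, oracle, tolerance = 1e-10)

  m1 <- toy_model(3, c(SER = 1L), seed = 22)
  for (bb in list(c(0.5, -0.5), c(-2, 2.5))) {
    I <- stats::integrate(function(x) {
      vapply(x, function(xi) {
        exp(loglik_chi(m1, angle_table("SER", bb[1], bb[2],
                                       matrix(c(xi, NA, NA, NA), 1)),
                       "conditional"))
      }, 0)
    }, -pi, pi, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-6)
  }
  expect_error(loglik_chi(m1, angle_table("SER", NA, 0.5,
                                          matrix(c(1, NA, NA, NA), 1)),
                          "conditional"), "phi and psi")
})

test_that("marginal chi density integrates to 1 and ignores the backbone
           when transitions are input-independent", {
  m <- uncoupled_model(seed = 31)
  I <- stats::integrate(function(x) {
    vapply(x, function(xi) {
      exp(loglik_chi(m, angle_table("SER", NA, NA,
                                    matrix(c(xi, NA, NA, NA), 1)),
                     "marginal"))
    }, 0)
  }, -pi, pi, rel.tol = 1e-9)$value
  expect_equal(I, 1, tolerance = 1e-6)
  for (xi in c(-2, 0.3, 1.9)) {
    df_m <- angle_table("SER", NA, NA, matrix(c(xi, NA, NA, NA), 1))
    df_c <- angle_table("SER", 0.8, -0.9, matrix(c(xi, NA, NA, NA), 1))
    expect_equal(loglik_chi(m, df_m, "marginal"),
                 loglik_chi(m, df_c, "conditional"), tolerance = 1e-9)
  }
})

test_that("hidden posteriors match enumeration and handle edge regimes", {
  m <- toy_model(2, c(HIS = 2L), seed = 41)
  ev <- c(0.2, 1.5, -2.8, 0.9)
  expect_equal(posterior_hidden(m, "HIS", ev), enum_posterior(m, "HIS", ev),
               tolerance = 1e-10)
  expect_equal(posterior_hidden(m, "HIS", c(NA, 0.4, NA, -1)),
               enum_posterior(m, "HIS", c(NA, 0.4, NA, -1)),
               tolerance = 1e-10)
  # uniform model, no evidence -> uniform posteriors
  spec <- chi_spec(3, c(SER = 1L))
  p <- list(initial = matrix(1 / 3, spec$K, 3),
            transition = array(1 / 3, c(3, 3, spec$K)),
            emission = list(mu = c(-1, 0, 1), kappa = c(1, 1, 1)))
  mu_ <- sidechainr:::new_chi_dbn(spec, p)
  post <- posterior_hidden(mu_, "SER", rep(NA_real_, 3))
  expect_equal(post, matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # concentrated emission far from one component kills that component
  p$emission$kappa <- c(300, 300, 300)
  mk <- sidechainr:::new_chi_dbn(spec, p)
  post <- posterior_hidden(mk, "SER", c(NA, NA, -1))  # chi1 at mu of state 1
  expect_lt(post[3, 3], 1e-10)
  expect_gt(post[3, 1], 0.99)
})

test_that("ancestral sampling is seed-deterministic and matches marginals", {
  truth <- make_ground_truth(seed = 11, hidden = 3)
  s1 <- sample_ancestral(truth, "HIS", 500, seed = 9)
  s2 <- sample_ancestral(truth, "HIS", 500, seed = 9)
  expect_identical(s1, s2)
  df <- sample_ancestral(truth, "HIS", 5e4, seed = 10)
  dens <- chi_density(truth, "HIS", 2, n_grid = 4000)
  f <- stats::approxfun(dens$x, dens$density, rule = 2)
  expect_gt(gof_pvalue(df$chi2, f, nb = 40), 0.001)
  # H = 1: angles are i.i.d. von Mises with the single emission
  spec1 <- chi_spec(1, c(SER = 1L))
  m1 <- sidechainr:::new_chi_dbn(spec1, list(
    initial = matrix(1, spec1$K, 1),
    transition = array(1, c(1, 1, spec1$K)),
    emission = list(mu = 0.5, kappa = 6)))
  x <- sample_ancestral(m1, "SER", 4e4, seed = 12)$chi1
  expect_gt(gof_pvalue(x, function(z) dvm(z, 0.5, 6), nb = 40), 0.001)
})

test_that("forward-backtrack conditional sampling draws from the exact
           conditional; uncoupled models reduce to the marginal", {
  truth <- make_ground_truth(seed = 11, hidden = 3)
  chi <- sample_conditional(truth, "SER", 0.7, -1.1, 5e4, seed = 13)
  dens <- chi_density(truth, "SER", 1, phi = 0.7, psi = -1.1, n_grid = 4000)
  f <- stats::approxfun(dens$x, dens$density, rule = 2)
  expect_gt(gof_pvalue(chi[, 1], f, nb = 40), 0.001)
  expect_identical(sample_conditional(truth, "SER", 0.7, -1.1, 50, seed = 3),
                   sample_conditional(truth, "SER", 0.7, -1.1, 50, seed = 3))

  mu_ <- uncoupled_model(seed = 14)
  c1 <- sample_conditional(mu_, "HIS", 1.2, -0.3, 2e4, seed = 15)[, 1]
  a1 <- sample_ancestral(mu_, "HIS", 2e4, seed = 16)$chi1
  expect_gt(suppressWarnings(stats::ks.test(c1, a1)$p.value), 0.001)
})

test_that("conditional samples score at least as well as ancestral chi
           under the conditional density (Gibbs inequality)", {
  truth <- make_ground_truth(seed = 11, hidden = 3)
  phi <- 0.7; psi <- -1.1
  n <- 1e4
  cond <- sample_conditional(truth, "HIS", phi, psi, n, seed = 17)
  anc <- sample_ancestral(truth, "HIS", n, seed = 18)
  df_c <- angle_table("HIS", rep(phi, n), rep(psi, n),
                      cbind(cond, NA, NA))
  df_a <- angle_table("HIS", rep(phi, n), rep(psi, n),
                      cbind(anc$chi1, anc$chi2, NA, NA))
  expect_gt(mean(loglik_chi(truth, df_c, "conditional")),
            mean(loglik_chi(truth, df_a, "conditional")))
})
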