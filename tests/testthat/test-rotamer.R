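write_lib <- function(lines) {
  path <- withr::local_tempfile(fileext = ".lib",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("fixture-dialect parsing, renormalization and skipping", {
  path <- write_lib(c("# comment", "SER 0.7 -65 10", "SER 0.3 178 12"))
  lib <- read_rotamer_library(path)
  expect_equal(lib$SER$prob, c(0.7, 0.3))
  expect_equal(lib$SER$means[, 1], c(-65, 178) * pi / 180)
  expect_equal(lib$SER$sds[, 1], c(10, 12) * pi / 180)

  path2 <- write_lib(c("SER 0.5 -65 10", "SER 0.49 178 12"))
  expect_warning(lib2 <- read_rotamer_library(path2), "renormalizing")
  expect_equal(sum(lib2$SER$prob), 1)

  path3 <- write_lib(character(0))
  expect_length(read_rotamer_library(path3), 0)

  path4 <- write_lib(c("SER 1.0 -65 10", "XXX 1.0 0 5"))
  expect_warning(lib4 <- read_rotamer_library(path4), "unknown residue")
  expect_identical(names(lib4), "SER")

  path5 <- write_lib("SER 0.7 -65")
  expect_error(read_rotamer_library(path5), "line 1")
  path6 <- write_lib("SER 1.0 0 -3")
  expect_error(read_rotamer_library(path6), "standard deviation")
})

test_that("column-map dialect reads foreign layouts", {
  path <- write_lib("LEU r1 r2 12 1.00 -65.1 175.2 9.8 10.1")
  lib <- read_rotamer_library(path, column_map = list(
    aa = 1, prob = 5, means = 6:7, sds = 8:9))
  expect_equal(lib$LEU$prob, 1)
  expect_equal(lib$LEU$means[1, ], c(-65.1, 175.2) * pi / 180)
})

test_that("mixture density: peak value, tails, wrapped normalization", {
  path <- write_lib("SER 1.0 0 10")
  lib <- read_rotamer_library(path)
  expect_equal(exp(rotamer_logpdf(lib, "SER", 0)),
               1 / (sqrt(2 * pi) * 10 * pi / 180), tolerance = 1e-6)
  path2 <- write_lib(c("SER 0.6 -60 8", "SER 0.4 60 8"))
  lib2 <- read_rotamer_library(path2)
  expect_lt(rotamer_logpdf(lib2, "SER", pi), -20)
  for (p in list(lib, lib2)) {
    I <- stats::integrate(function(x) exp(rotamer_logpdf(p, "SER",
                                                         matrix(x))),
                          -pi, pi, rel.tol = 1e-9)$value
    expect_equal(I, 1, tolerance = 1e-3)
  }
  # wrap: a rotamer at 178 deg keeps its mass across the +/-180 seam
  path3 <- write_lib("SER 1.0 178 6")
  lib3 <- read_rotamer_library(path3)
  expect_equal(rotamer_logpdf(lib3, "SER", -178 * pi / 180),
               rotamer_logpdf(lib3, "SER", 174 * pi / 180), tolerance = 1e-9)
  expect_error(rotamer_logpdf(lib3, "SER", c(0, 0)), "chi length")
  expect_error(rotamer_logpdf(lib3, "HIS", 0), "not in rotamer library")
})

test_that("relative KL estimator: degeneracy, antisymmetry, quadrature
           agreement, flagged records", {
  n <- 1e5
  dat <- angle_table("SER", rep(NA_real_, n), rep(NA_real_, n),
                     matrix(rvm(n, 0, 4, seed = 8)))
  lb <- function(d) dvm(d$chi1, 0, 4, log = TRUE)
  lr <- function(d) dvm(d$chi1, 0, 1, log = TRUE)
  expect_identical(delta_kl(dat, lb, lb)$overall, 0)
  dk <- delta_kl(dat, lb, lr)
  dk_sw <- delta_kl(dat, lr, lb)
  expect_identical(dk$overall, -dk_sw$overall)
  truth <- stats::integrate(function(x) {
    dvm(x, 0, 4) * (dvm(x, 0, 4, log = TRUE) - dvm(x, 0, 1, log = TRUE))
  }, -pi, pi, rel.tol = 1e-10)$value
  expect_lt(abs(dk$overall - truth), 0.01)
  expect_gte(dk$overall, 0)  # Gibbs: data drawn from model b

  lbad <- function(d) { z <- lb(d); z[1] <- -Inf; z }
  dkf <- delta_kl(dat, lbad, lr)
  expect_identical(dkf$flagged, 1L)
  expect_true(is.finite(dkf$overall))
})

test_that("delta KL standard error shrinks like 1/sqrt(n)", {
  lb <- function(d) dvm(d$chi1, 0, 4, log = TRUE)
  lr <- function(d) dvm(d$chi1, 0, 1, log = TRUE)
  se <- vapply(c(1e3, 1e4), function(n) {
    ests <- vapply(1:8, function(r) {
      dat <- angle_table("SER", rep(NA_real_, n), rep(NA_real_, n),
                         matrix(rvm(n, 0, 4, seed = 100 + r)))
      delta_kl(dat, lb, lr)$overall
    }, 0)
    stats::sd(ests)
  }, 0)
  expect_lt(se[2], se[1] / 1.8)
})

test_that("per-amino-acid report layout and TSV output", {
  dat <- rbind(
    angle_table("SER", rep(NA_real_, 50), rep(NA_real_, 50),
                matrix(rvm(50, 0, 4, seed = 1))),
    angle_table("CYS", rep(NA_real_, 50), rep(NA_real_, 50),
                matrix(rvm(50, 1, 4, seed = 2))))
  lb <- function(d) dvm(d$chi1, 0, 4, log = TRUE)
  lr <- function(d) dvm(d$chi1, 0, 2, log = TRUE)
  dk <- delta_kl(dat, lb, lr)
  expect_identical(dk$table$aa, c("CYS", "SER"))
  expect_identical(dk$table$n, c(50L, 50L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_delta_kl(dk, path)
  out <- utils::read.delim(path)
  expect_identical(out$aa, c("CYS", "SER", "average"))
})
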