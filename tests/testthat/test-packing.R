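# Two-atom helper: a pair of alanine CB atoms at distance d.
two_atoms <- function(d) {
  sidechainr:::new_structure(data.frame(
    chain = "A", resno = c(1, 10), resid = "ALA", atom = "CB",
    x = c(0, d), y = 0, z = 0, o = 1, b = 0, stringsAsFactors = FALSE))
}

test_that("Lennard-Jones analytics: minimum depth, zero crossing, tail", {
  eps <- 0.066; sigma <- 3.5   # aliphatic-carbon class
  expect_equal(lj_energy(two_atoms(2^(1 / 6) * sigma)), -eps,
               tolerance = 1e-12)
  expect_equal(lj_energy(two_atoms(sigma)), 0, tolerance = 1e-12)
  expect_lt(abs(lj_energy(two_atoms(10 * sigma))), 1e-5 * eps)
})

test_that("Boltzmann weighting at room temperature", {
  em <- energy_model()
  expect_equal(em$RT, 0.5925, tolerance = 1e-3)
  expect_identical(boltzmann_logweight(0, em), 0)
  expect_equal(boltzmann_logweight(0.5925, em) -
                 boltzmann_logweight(0, em), -1, tolerance = 1e-3)
  E <- seq(-2, 5, by = 0.5)
  expect_true(all(diff(boltzmann_logweight(E, em)) < 0))
})

test_that("MH acceptance: identity move, algebraic reduction, hard clash", {
  em <- energy_model()
  st <- list(energy = 3.2, logq = -1.7)
  dec <- mh_accept(st, st, "pseudo_energy", em, u = 0.999999)
  expect_identical(dec$log_alpha, 0)
  expect_true(dec$accept)
  set.seed(5)
  for (r in 1:20) {
    cur <- list(energy = stats::rnorm(1, 0, 5), logq = stats::rnorm(1))
    prop <- list(energy = stats::rnorm(1, 0, 5), logq = stats::rnorm(1))
    full <- mh_accept(cur, prop, "pseudo_energy", em, reduced = FALSE,
                      u = 0.5)
    red <- mh_accept(cur, prop, "pseudo_energy", em, reduced = TRUE,
                     u = 0.5)
    expect_equal(full$log_alpha, red$log_alpha, tolerance = 1e-12)
  }
  clash <- mh_accept(list(energy = 1, logq = 0),
                     list(energy = Inf, logq = 0), "pseudo_energy", em)
  expect_false(clash$accept)
  # proposal-only acceptance corrects for the proposal density
  cur <- list(energy = 1, logq = -2)
  prop <- list(energy = 1, logq = -1)   # more probable under the proposal
  dec <- mh_accept(cur, prop, "proposal_only", em, u = 0.5)
  expect_equal(dec$log_alpha, -1)       # q(x)/q(x') = exp(-1)
})

test_that("incremental move energies equal full recomputation", {
  toy <- make_toy_protein("helix_clash")
  bb <- toy$backbone
  set.seed(31)
  s_prev <- rebuild_side_chains(bb, list(`2` = stats::runif(2, -pi, pi),
                                         `4` = stats::runif(2, -pi, pi)))
  E_prev <- lj_energy(s_prev)
  for (r in 1:12) {
    moved <- sample(list(2, 4, c(2, 4)), 1)[[1]]
    chi_new <- stats::setNames(
      lapply(moved, function(...) stats::runif(2, -pi, pi)),
      as.character(moved))
    ang <- residue_angles(s_prev)
    keep <- setdiff(c(2, 4), moved)
    chi_all <- chi_new
    for (k in keep) {
      chi_all[[as.character(k)]] <-
        as.numeric(ang[ang$resno == k, c("chi1", "chi2")])
    }
    s_new <- rebuild_side_chains(bb, chi_all)
    dE_incr <- lj_energy(s_new, moved = moved) -
      lj_energy(s_prev, moved = moved)
    E_new <- lj_energy(s_new)
    expect_equal(E_new - E_prev, dE_incr, tolerance = 1e-6)
    s_prev <- s_new
    E_prev <- E_new
  }
})

test_that("packing run: cached energy is exact, seeds reproduce, clash
           resolves", {
  truth <- make_ground_truth(aa = c(LEU = 2L), style = "rotameric")
  toy <- make_toy_protein("helix_clash")
  p1 <- pack_side_chains(toy$backbone, truth, mode = "pseudo_energy_bbdep",
                         iterations = 800, seed = 7, trace_every = 200)
  p2 <- pack_side_chains(toy$backbone, truth, mode = "pseudo_energy_bbdep",
                         iterations = 800, seed = 7, trace_every = 200)
  expect_identical(p1$trace, p2$trace)
  expect_identical(p1$chi, p2$chi)
  expect_equal(p1$energy, lj_energy(p1$structure), tolerance = 1e-6)
  # the designed clash is gone in the best state
  expect_gt(min_nonbonded_distance(p1$structure), 2.5)
  naive <- rebuild_side_chains(toy$backbone, toy$naive)
  expect_gt(p1$energy + 1e-6, 0)  # sanity: finite
  expect_lt(p1$energy, lj_energy(naive))
})

test_that("flat-energy limit: every pseudo-energy move is accepted and the
           visited chi distribution is the model's", {
  truth <- make_ground_truth(aa = c(SER = 1L), style = "rotameric")
  bb <- build_backbone(c("SER"), -pi / 2, pi / 2)
  hot <- energy_model(temperature = 1e15)   # -dE/RT indistinguishable from 0
  p <- pack_side_chains(bb, truth, mode = "pseudo_energy", energy = hot,
                        iterations = 4000, seed = 9, trace_every = 1,
                        record_states = TRUE)
  expect_identical(p$acceptance_rate, 1)
  visited <- vapply(p$states, function(st) st[["1"]][1], 0)
  ref <- sample_ancestral(truth, "SER", 4000, seed = 10)$chi1
  expect_gt(suppressWarnings(stats::ks.test(visited, ref)$p.value), 0.001)
})

test_that("accuracy evaluator: cutoff boundary, wraparound, conditional
           chi2 counting, burial mask, symmetry folding", {
  mk <- function(chi1, chi2, resno, aa = "HIS") {
    df <- angle_table(aa, rep(NA_real_, length(chi1)),
                      rep(NA_real_, length(chi1)),
                      cbind(chi1, chi2, NA, NA) * pi / 180)
    cbind(data.frame(chain = "A", resno = resno), df)
  }
  ref <- mk(c(0, 0, 0, 0), c(0, 0, 0, 0), 1:4)
  # chi1 deviations: 19.9 (ok), 20.1 (bad), -6 via wraparound (ok), 0 (ok)
  prd <- mk(c(19.9, 20.1, 175, 0), c(5, 0, 30, 25), 1:4)
  prd$chi1[3] <- 175 * pi / 180
  ref$chi1[3] <- -179 * pi / 180
  acc <- chi_accuracy(prd, ref)
  expect_equal(acc$chi1_pct, 75)
  # chi2 among chi1-correct (rows 1, 3, 4): deviations 5, 30, 25 -> 1 of 3
  expect_equal(acc$chi2_given_chi1_pct, 100 / 3, tolerance = 1e-9)
  # the documented fixture: chi1 3/4, chi2|chi1 2/3
  ref2 <- mk(c(0, 0, 0, 0), c(0, 0, 0, 0), 1:4)
  prd2 <- mk(c(5, 30, -10, 8), c(5, 0, 30, 15), 1:4)
  acc2 <- chi_accuracy(prd2, ref2)
  expect_equal(acc2$chi1_pct, 75)
  expect_equal(acc2$chi2_given_chi1_pct, 200 / 3, tolerance = 1e-9)
  # burial restricts the denominator
  acc3 <- chi_accuracy(prd2, ref2, burial = c(1, 2))
  expect_identical(acc3$n, 2L)
  expect_equal(acc3$chi1_pct, 50)
  # orphans are reported
  acc4 <- chi_accuracy(prd2[1:3, ], ref2)
  expect_equal(acc4$orphans, 4)
  # two-fold symmetry folding for ASP chi2 (opt-in)
  refd <- mk(0, -89, 1, aa = "ASP")
  prdd <- mk(0, 89, 1, aa = "ASP")
  expect_equal(chi_accuracy(prdd, refd)$chi2_given_chi1_pct, 0)
  expect_equal(chi_accuracy(prdd, refd,
                            fold_symmetry = TRUE)$chi2_given_chi1_pct, 100)
})

test_that("burial approximation marks core residues of a compact fixture", {
  toy <- make_toy_protein("helix_clash")
  b <- buried_residues(toy$structure, threshold = 0.25)
  expect_true(is.integer(b))
  # a 5-residue strand is essentially fully exposed at strict threshold
  expect_length(buried_residues(toy$structure, threshold = 0), 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chain\tresno\tburied", "A\t2\t1", "A\t4\t0"), path)
  expect_identical(read_burial(path), 2L)
})
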