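# Fixed-backbone side-chain packing: Lennard-Jones 6-12 energy with
# OPLS-convention parameters, Metropolis-Hastings sampling with the chi DBN
# as proposal distribution (and optionally pseudo-energy), and the +/-20
# degree accuracy evaluator.

# Heavy-atom Lennard-Jones parameters (kcal/mol, Angstroms), OPLS-style:
# sigma is the zero-crossing of the 4*eps[(s/d)^12 - (s/d)^6] form and pair
# parameters combine by geometric means. Atom classes are resolved from the
# PDB atom name with a few residue-specific refinements.
LJ_CLASSES <- list(
  C_ali = c(eps = 0.066, sigma = 3.50),  # sp3 carbon
  C_aro = c(eps = 0.070, sigma = 3.55),  # aromatic carbon
  C_co  = c(eps = 0.105, sigma = 3.75),  # carbonyl/carboxyl/guanidinium C
  N     = c(eps = 0.170, sigma = 3.25),
  O_co  = c(eps = 0.210, sigma = 2.96),  # carbonyl/carboxylate O
  O_oh  = c(eps = 0.170, sigma = 3.12),  # hydroxyl O
  S     = c(eps = 0.250, sigma = 3.55)
)

AROMATIC_RES <- c("PHE", "TYR", "TRP", "HIS")

lj_class <- function(resid, atom) {
  el <- substr(atom, 1, 1)
  if (el == "N") return("N")
  if (el == "S") return("S")
  if (el == "O") {
    if (atom %in% c("OG", "OG1", "OH")) return("O_oh")
    return("O_co")
  }
  if (atom == "C") return("C_co")
  if (resid %in% c("ASP", "ASN") && atom == "CG") return("C_co")
  if (resid %in% c("GLU", "GLN") && atom == "CD") return("C_co")
  if (resid == "ARG" && atom == "CZ") return("C_co")
  if (resid %in% AROMATIC_RES && !atom %in% c("CA", "CB")) {
    if (resid == "HIS" && atom == "CG") return("C_aro")
    if (grepl("^C[GDEZH]", atom)) return("C_aro")
  }
  "C_ali"
}

#' Energy model for side-chain packing
#'
#' Bundles the thermodynamic constants and conventions of the Lennard-Jones
#' 6-12 potential: `E(d) = 4 eps [ (sigma/d)^12 - (sigma/d)^6 ]` per
#' non-excluded atom pair, with geometric-mean combination of per-atom
#' parameters. Boltzmann weighting uses `-E / (R T)`.
#'
#' @param temperature temperature in Kelvin (default room temperature).
#' @param cap numerical cap on a pair energy (kcal/mol); prevents overflow
#'   only, the potential is otherwise unmodified.
#' @return an object of class `energy_model` with fields `temperature`,
#'   `R` (kcal/(mol K)), `RT`, `cap`.
#' @export
energy_model <- function(temperature = 298.15, cap = 1e6) {
  R <- 1.98720425864083e-3
  structure(list(temperature = temperature, R = R, RT = R * temperature,
                 cap = cap),
            class = "energy_model")
}

#' Boltzmann log-weight of an energy
#'
#' `-E / (R T)`: the log-probability of a conformation up to an additive
#' constant. At 298.15 K, `R T` is about 0.5925 kcal/mol.
#'
#' @param E energy in kcal/mol.
#' @param energy an [energy_model()].
#' @return log-weight in nats.
#' @export
boltzmann_logweight <- function(E, energy = energy_model()) {
  stopifnot(all(is.finite(E)))
  -E / energy$RT
}

# Ring-closure and backbone bonds not expressed by the topology's
# placement references; needed for correct 1-2/1-3 exclusions.
RING_BONDS <- list(
  HIS = list(c("CE1", "NE2")),
  PHE = list(c("CZ", "CE2")),
  TYR = list(c("CZ", "CE2")),
  TRP = list(c("NE1", "CE2"), c("CZ3", "CH2")),
  PRO = list(c("CD", "N"))
)

# Bond list of a structure: within-residue bonds from the topology (each
# placed atom is bonded to its third reference) plus backbone and peptide
# bonds. Returns a 2-column matrix of atom row indices.
structure_bonds <- function(s) {
  idx <- function(rn, at) which(s$resno == rn & s$atom == at)[1]
  bonds <- list()
  add <- function(i, j) {
    if (length(i) && length(j) && !is.na(i) && !is.na(j)) {
      bonds[[length(bonds) + 1]] <<- c(i, j)
    }
  }
  res <- unique(s[, c("resno", "resid")])
  for (r in seq_len(nrow(res))) {
    rn <- res$resno[r]; aa <- res$resid[r]
    add(idx(rn, "N"), idx(rn, "CA"))
    add(idx(rn, "CA"), idx(rn, "C"))
    add(idx(rn, "C"), idx(rn, "O"))
    if (!is.na(idx(rn, "CB"))) add(idx(rn, "CA"), idx(rn, "CB"))
    if (aa %in% names(chi_counts())) {
      topo <- sidechain_topology(aa)
      for (i in seq_len(nrow(topo))[-1]) {
        add(idx(rn, topo$atom[i]), idx(rn, topo$r3[i]))
      }
      for (b in RING_BONDS[[aa]]) add(idx(rn, b[1]), idx(rn, b[2]))
    }
    if (r < nrow(res)) add(idx(rn, "C"), idx(res$resno[r + 1], "N"))
  }
  do.call(rbind, bonds)
}

# Pairs with bond-graph distance <= 2 (1-2 and 1-3), as an n x n logical
# exclusion matrix (1-4 pairs are included at full weight).
exclusion_matrix <- function(s) {
  n <- nrow(s)
  adj <- matrix(FALSE, n, n)
  b <- structure_bonds(s)
  adj[b] <- TRUE
  adj[b[, 2:1, drop = FALSE]] <- TRUE
  two <- (adj %*% adj) > 0
  excl <- adj | two
  diag(excl) <- TRUE
  excl
}

# LJ parameter vectors for the atoms of a structure.
lj_atom_params <- function(s) {
  cls <- mapply(lj_class, s$resid, s$atom)
  eps <- vapply(cls, function(cl) LJ_CLASSES[[cl]]["eps"], 0)
  sigma <- vapply(cls, function(cl) LJ_CLASSES[[cl]]["sigma"], 0)
  list(eps = as.numeric(eps), sigma = as.numeric(sigma))
}

# Pairwise LJ energy between atom index sets I and J (disjoint), given
# coordinate matrix X and per-atom parameters; excluded pairs skipped.
lj_pair_sum <- function(X, par, excl, I, J, cap) {
  if (length(I) == 0 || length(J) == 0) return(0)
  E <- 0
  for (i in I) {
    keep <- J[!excl[i, J]]
    if (length(keep) == 0) next
    d2 <- (X[keep, 1] - X[i, 1])^2 + (X[keep, 2] - X[i, 2])^2 +
      (X[keep, 3] - X[i, 3])^2
    s2 <- (par$sigma[i] * par$sigma[keep]) / d2   # (sigma_ij/d)^2
    s6 <- s2^3
    e <- 4 * sqrt(par$eps[i] * par$eps[keep]) * (s6^2 - s6)
    E <- E + sum(pmin(e, cap))
  }
  E
}

#' Lennard-Jones energy of a structure
#'
#' Sums `4 eps_ij [ (sigma_ij/d)^12 - (sigma_ij/d)^6 ]` over all atom pairs
#' except bonded 1-2 and 1-3 neighbours (1-4 pairs count at full weight).
#' Pair parameters combine by geometric means. If `moved` is given, only the
#' energy terms involving at least one atom of those residues are summed —
#' the incremental contribution used by the sampler.
#'
#' @param structure a `protein_structure` with all side chains built.
#' @param energy an [energy_model()].
#' @param moved optional integer vector of residue numbers.
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(structure, energy = energy_model(), moved = NULL) {
  s <- structure
  X <- as.matrix(s[, c("x", "y", "z")])
  par <- lj_atom_params(s)
  excl <- exclusion_matrix(s)
  all_idx <- seq_len(nrow(s))
  if (is.null(moved)) {
    E <- 0
    for (i in all_idx[-length(all_idx)]) {
      J <- all_idx[all_idx > i]
      E <- E + lj_pair_sum(X, par, excl, i, J, energy$cap)
    }
    E
  } else {
    I <- all_idx[s$resno %in% moved]
    J <- setdiff(all_idx, I)
    E <- lj_pair_sum(X, par, excl, I, J, energy$cap)
    # pairs within the moved set (intra-residue 1-4/1-5 pairs flex with chi,
    # so they belong to the move's energy), counted once
    if (length(I) > 1) {
      for (a in seq_along(I)[-length(I)]) {
        E <- E + lj_pair_sum(X, par, excl, I[a], I[(a + 1):length(I)],
                             energy$cap)
      }
    }
    E
  }
}

#' Metropolis-Hastings acceptance for packing moves
#'
#' States are lists with fields `energy` (Lennard-Jones, kcal/mol) and
#' `logq` (model log-density of the state's side chains, nats). In
#' `proposal_only` mode the target is the pure Boltzmann distribution and
#' the model appears only as the proposal, so
#' `log alpha = -(E' - E)/RT + logq(x) - logq(x')`. In the pseudo-energy
#' modes the model multiplies the target as well; proposal and target model
#' terms cancel and the expression reduces to the energy ratio
#' `log alpha = -(E' - E)/RT` (set `reduced = FALSE` to evaluate the full
#' four-term expression instead; the two agree identically).
#'
#' @param current,proposed state lists with `energy` and `logq`.
#' @param mode `"proposal_only"`, `"pseudo_energy"` or
#'   `"pseudo_energy_bbdep"`.
#' @param energy an [energy_model()].
#' @param reduced use the cancelled form in pseudo-energy modes.
#' @param u optional uniform variate (for reproducing a decision); default
#'   is drawn from the RNG.
#' @return list with `log_alpha` and logical `accept`.
#' @export
mh_accept <- function(current, proposed,
                      mode = c("proposal_only", "pseudo_energy",
                               "pseudo_energy_bbdep"),
                      energy = energy_model(), reduced = TRUE, u = NULL) {
  mode <- match.arg(mode)
  dE <- proposed$energy - current$energy
  la <- if (mode == "proposal_only") {
    -dE / energy$RT + (current$logq - proposed$logq)
  } else if (reduced) {
    -dE / energy$RT
  } else {
    # full expression: target = Boltzmann x model density, proposal = model
    (-proposed$energy / energy$RT + proposed$logq) -
      (-current$energy / energy$RT + current$logq) +
      (current$logq - proposed$logq)
  }
  if (!is.finite(la)) {
    return(list(log_alpha = -Inf, accept = FALSE))
  }
  if (is.null(u)) u <- stats::runif(1)
  list(log_alpha = min(la, 0), accept = log(u) < la)
}

# Marginal or conditional chi proposal for one residue.
propose_chi <- function(model, aa, nchi, bbdep, phi, psi) {
  if (bbdep && is.finite(phi) && is.finite(psi)) {
    as.numeric(sample_conditional(model, aa, phi, psi, 1))
  } else {
    as.numeric(sample_ancestral(model, aa, 1)[, paste0("chi",
                                                       seq_len(nchi))])
  }
}

# Model log-density of one residue's chi under the packing mode.
state_logq <- function(model, aa, chi, bbdep, phi, psi) {
  df <- angle_table(aa, if (bbdep) phi else NA_real_,
                    if (bbdep) psi else NA_real_,
                    matrix(c(chi, rep(NA_real_, 4 - length(chi))), 1))
  if (bbdep && is.finite(phi) && is.finite(psi)) {
    loglik_chi(model, df, "conditional")
  } else {
    df$phi <- NA_real_; df$psi <- NA_real_
    loglik_chi(model, df, "marginal")
  }
}

#' Side-chain packing by Metropolis-Hastings
#'
#' Places all side chains on a fixed backbone. Each iteration jointly
#' resamples the chi angles of `residues_per_move` randomly chosen residues
#' from the model (marginal chi distribution, or conditional on the
#' residue's phi/psi in `pseudo_energy_bbdep` mode) and accepts or rejects
#' the joint move with [mh_accept()]. Non-rotameric residues (Ala/Gly) pass
#' through unchanged. The returned prediction is the visited state with the
#' lowest score: the Lennard-Jones energy in `proposal_only` mode,
#' `E - RT log q` in the pseudo-energy modes.
#'
#' @param backbone a `protein_structure`; side-chain atoms, if present, are
#'   discarded.
#' @param model a `chi_dbn` covering the backbone's rotameric residues.
#' @param mode acceptance mode; see [mh_accept()].
#' @param energy an [energy_model()].
#' @param iterations number of MH iterations.
#' @param residues_per_move residues resampled jointly per iteration
#'   (trimmed to the number of rotameric residues).
#' @param seed optional integer seed.
#' @param trace_every record the trace every this many iterations.
#' @param record_states also store the current chi assignment at every
#'   trace point (diagnostics; memory grows with `iterations/trace_every`).
#' @return an object of class `chi_packing`: list with `structure` (the
#'   best full-atom structure), `chi` (its chi assignment), `energy`,
#'   `logq`, `score`, `trace` (data.frame: iteration, energy, logq,
#'   accepted), `states` (if recorded), `acceptance_rate`, `mode`.
#' @export
pack_side_chains <- function(backbone, model,
                             mode = c("proposal_only", "pseudo_energy",
                                      "pseudo_energy_bbdep"),
                             energy = energy_model(),
                             iterations = 500000, residues_per_move = 3,
                             seed = NULL, trace_every = 100,
                             record_states = FALSE) {
  mode <- match.arg(mode)
  if (iterations < 1 || residues_per_move < 1) {
    stop("iterations and residues_per_move must be >= 1", call. = FALSE)
  }
  validate_chi_dbn(model)
  bbdep <- mode == "pseudo_energy_bbdep"
  bb <- backbone[backbone$atom %in% c("N", "CA", "C", "O"), ]
  ang <- residue_angles(bb)
  cc <- chi_counts()
  rot <- which(ang$aa %in% names(model$spec$aa))
  if (length(rot) == 0) stop("no rotameric residues to pack", call. = FALSE)
  m <- min(residues_per_move, length(rot))
  with_seed(seed, {
    # initial side chains sampled from the model
    chi <- list()
    logq_res <- numeric(nrow(ang))
    for (i in rot) {
      aa <- ang$aa[i]
      chi[[as.character(ang$resno[i])]] <-
        propose_chi(model, aa, cc[[aa]], bbdep, ang$phi[i], ang$psi[i])
      logq_res[i] <- state_logq(model, aa, chi[[as.character(ang$resno[i])]],
                                bbdep, ang$phi[i], ang$psi[i])
    }
    s <- rebuild_side_chains(bb, chi)
    # static atom bookkeeping: exclusions and parameters are rebuilt once on
    # a template whose atom layout never changes during the run
    X <- as.matrix(s[, c("x", "y", "z")])
    par <- lj_atom_params(s)
    excl <- exclusion_matrix(s)
    res_atoms <- split(seq_len(nrow(s)), s$resno)
    backbone_xyz <- lapply(split(seq_len(nrow(s)), s$resno), function(ix) {
      sub <- s[ix, ]
      list(N = as.numeric(sub[sub$atom == "N", c("x", "y", "z")]),
           CA = as.numeric(sub[sub$atom == "CA", c("x", "y", "z")]),
           C = as.numeric(sub[sub$atom == "C", c("x", "y", "z")]))
    })
    sc_rows <- lapply(res_atoms, function(ix) {
      ix[!s$atom[ix] %in% c("N", "CA", "C", "O")]
    })
    all_idx <- seq_len(nrow(s))
    energy_of_move <- function(Xm, resnos) {
      I <- unlist(res_atoms[as.character(resnos)])
      J <- setdiff(all_idx, I)
      E <- lj_pair_sum(Xm, par, excl, I, J, energy$cap)
      # pairs among and within the moved residues, counted once
      if (length(resnos) > 1) {
        for (a in seq_along(resnos)[-length(resnos)]) {
          Ia <- res_atoms[[as.character(resnos[a])]]
          Jb <- unlist(res_atoms[as.character(resnos[(a + 1):
                                                       length(resnos)])])
          E <- E + lj_pair_sum(Xm, par, excl, Ia, Jb, energy$cap)
        }
      }
      for (k in as.character(resnos)) {
        Ik <- res_atoms[[k]]
        if (length(Ik) > 1) {
          for (a in seq_along(Ik)[-length(Ik)]) {
            E <- E + lj_pair_sum(Xm, par, excl, Ik[a],
                                 Ik[(a + 1):length(Ik)], energy$cap)
          }
        }
      }
      E
    }
    E_total <- lj_energy(s, energy)
    score_of <- function(E, lq) {
      if (mode == "proposal_only") E else E - energy$RT * lq
    }
    best <- list(chi = chi, energy = E_total, logq = sum(logq_res),
                 score = score_of(E_total, sum(logq_res)), X = X)
    acc <- 0L
    tr <- list()
    states <- if (record_states) list() else NULL
    for (it in seq_len(iterations)) {
      sel <- rot[sample.int(length(rot), m)]
      resnos <- ang$resno[sel]
      keys <- as.character(resnos)
      old_E_part <- energy_of_move(X, resnos)
      new_chi <- list(); new_lq <- numeric(length(sel))
      Xp <- X
      for (j in seq_along(sel)) {
        i <- sel[j]; aa <- ang$aa[i]
        ch <- propose_chi(model, aa, cc[[aa]], bbdep, ang$phi[i], ang$psi[i])
        new_chi[[keys[j]]] <- ch
        new_lq[j] <- state_logq(model, aa, ch, bbdep, ang$phi[i], ang$psi[i])
        bbx <- backbone_xyz[[keys[j]]]
        sc <- build_side_chain(bbx$N, bbx$CA, bbx$C, aa, ch)
        Xp[sc_rows[[keys[j]]], ] <- sc[s$atom[sc_rows[[keys[j]]]], ,
                                       drop = FALSE]
      }
      new_E_part <- energy_of_move(Xp, resnos)
      dE <- new_E_part - old_E_part
      cur <- list(energy = 0, logq = sum(logq_res[sel]))
      prop <- list(energy = dE, logq = sum(new_lq))
      dec <- mh_accept(cur, prop, mode, energy)
      if (dec$accept) {
        acc <- acc + 1L
        X <- Xp
        E_total <- E_total + dE
        for (j in seq_along(sel)) {
          chi[[keys[j]]] <- new_chi[[keys[j]]]
          logq_res[sel[j]] <- new_lq[j]
        }
        sc_now <- score_of(E_total, sum(logq_res))
        if (sc_now < best$score) {
          best <- list(chi = chi, energy = E_total, logq = sum(logq_res),
                       score = sc_now, X = X)
        }
      }
      if (it %% trace_every == 0 || it == iterations) {
        tr[[length(tr) + 1]] <- data.frame(iteration = it, energy = E_total,
                                           logq = sum(logq_res),
                                           accepted = acc)
        if (record_states) states[[length(states) + 1]] <- chi
      }
    }
    s_best <- s
    s_best[, c("x", "y", "z")] <- best$X
    structure(list(structure = s_best, chi = best$chi,
                   energy = best$energy, logq = best$logq,
                   score = best$score, trace = do.call(rbind, tr),
                   states = states,
                   acceptance_rate = acc / iterations, mode = mode),
              class = "chi_packing")
  })
}

#' @export
print.chi_packing <- function(x, ...) {
  cat(sprintf("Side-chain packing (%s): best E_LJ = %.3f kcal/mol, ", x$mode,
              x$energy))
  cat(sprintf("model logq = %.2f, acceptance %.1f%%\n", x$logq,
              100 * x$acceptance_rate))
  invisible(x)
}

#' Chi-angle prediction accuracy against a reference
#'
#' A chi angle is counted correct when its wrapped deviation from the
#' reference value is at most `cutoff_deg`. Reports the fraction of residues
#' with chi1 correct, and among those, the fraction with chi2 also correct
#' (the conditional chi2|chi1 column), per amino acid and overall.
#'
#' @param predicted,reference `protein_structure` objects with matching
#'   residue numbering (or `chi_angles` tables from [residue_angles()]).
#' @param cutoff_deg correctness cutoff in degrees.
#' @param burial optional integer vector of residue numbers to evaluate
#'   (e.g. the buried core); default: all rotameric residues.
#' @param fold_symmetry fold the 2-fold terminal symmetries (Phe/Tyr chi2,
#'   Asp chi2, Glu chi3) to +/-90 degrees before comparing.
#' @return an object of class `chi_accuracy`: list with `per_aa`
#'   (data.frame: aa, n, chi1_pct, chi2_given_chi1_pct), `chi1_pct`,
#'   `chi2_given_chi1_pct`, `n`, `orphans` (residue numbers present in only
#'   one input).
#' @export
chi_accuracy <- function(predicted, reference, cutoff_deg = 20,
                         burial = NULL, fold_symmetry = FALSE) {
  pa <- if (inherits(predicted, "protein_structure")) {
    residue_angles(predicted)
  } else predicted
  ra <- if (inherits(reference, "protein_structure")) {
    residue_angles(reference)
  } else reference
  orphans <- c(setdiff(pa$resno, ra$resno), setdiff(ra$resno, pa$resno))
  common <- intersect(pa$resno, ra$resno)
  if (!is.null(burial)) common <- intersect(common, burial)
  cut <- cutoff_deg * pi / 180
  cc <- chi_counts()
  sym_fold <- function(aa, k, delta) {
    two_fold <- (aa %in% c("PHE", "TYR", "ASP") & k == 2) |
      (aa == "GLU" & k == 3)
    if (fold_symmetry && two_fold) {
      d <- abs(delta) %% pi
      min(d, pi - d)
    } else {
      abs(delta)
    }
  }
  rows <- list()
  for (rn in common) {
    p <- pa[pa$resno == rn, ][1, ]
    r <- ra[ra$resno == rn, ][1, ]
    aa <- r$aa
    if (!aa %in% names(cc)) next
    if (is.na(p$chi1) || is.na(r$chi1)) next
    d1 <- sym_fold(aa, 1, angle_diff(p$chi1, r$chi1))
    chi1_ok <- d1 <= cut
    chi2_ok <- NA
    if (cc[[aa]] >= 2 && !is.na(p$chi2) && !is.na(r$chi2)) {
      d2 <- sym_fold(aa, 2, angle_diff(p$chi2, r$chi2))
      chi2_ok <- d2 <= cut
    }
    rows[[length(rows) + 1]] <- data.frame(resno = rn, aa = aa,
                                           chi1_ok = chi1_ok,
                                           chi2_ok = chi2_ok)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) {
    stop("no comparable residues", call. = FALSE)
  }
  pct <- function(x) 100 * mean(x)
  per_aa <- do.call(rbind, lapply(sort(unique(tab$aa)), function(a) {
    sub <- tab[tab$aa == a, ]
    c1 <- sub$chi1_ok
    c2 <- sub$chi2_ok[sub$chi1_ok & !is.na(sub$chi2_ok)]
    data.frame(aa = a, n = nrow(sub), chi1_pct = pct(c1),
               chi2_given_chi1_pct = if (length(c2)) pct(c2) else NA_real_)
  }))
  c2_all <- tab$chi2_ok[tab$chi1_ok & !is.na(tab$chi2_ok)]
  structure(list(per_aa = per_aa,
                 chi1_pct = pct(tab$chi1_ok),
                 chi2_given_chi1_pct = if (length(c2_all)) pct(c2_all)
                                       else NA_real_,
                 n = nrow(tab), orphans = orphans,
                 detail = tab),
            class = "chi_accuracy")
}

#' @export
print.chi_accuracy <- function(x, ...) {
  cat(sprintf("Chi accuracy over %d residues: chi1 %.1f%%", x$n, x$chi1_pct))
  if (!is.na(x$chi2_given_chi1_pct)) {
    cat(sprintf(", chi2|chi1 %.1f%%", x$chi2_given_chi1_pct))
  }
  cat("\n")
  print(x$per_aa, row.names = FALSE)
  if (length(x$orphans)) {
    cat("unmatched residue(s): ", paste(x$orphans, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Buried residues by a Shrake-Rupley-style surface approximation
#'
#' Approximates per-residue solvent-accessible surface area by scattering
#' points on each heavy atom's solvent-expanded sphere and counting points
#' not occluded by any other atom. Residues whose relative accessibility is
#' at or below `threshold` are reported as buried.
#'
#' @param structure a `protein_structure`.
#' @param probe probe radius in Angstroms.
#' @param n_points sphere points per atom.
#' @param threshold relative-accessibility cutoff (0 = fully buried).
#' @return integer vector of buried residue numbers.
#' @export
buried_residues <- function(structure, probe = 1.4, n_points = 92,
                            threshold = 0.05) {
  s <- structure
  radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
  r <- radii[substr(s$atom, 1, 1)] + probe
  X <- as.matrix(s[, c("x", "y", "z")])
  # Fibonacci sphere points
  i <- seq_len(n_points) - 0.5
  gp <- cbind(cos(2 * pi * i / ((1 + sqrt(5)) / 2)) * sqrt(1 - (1 - 2 * i /
                                                                  n_points)^2),
              1 - 2 * i / n_points,
              sin(2 * pi * i / ((1 + sqrt(5)) / 2)) * sqrt(1 - (1 - 2 * i /
                                                                  n_points)^2))
  acc <- numeric(nrow(s))
  for (a in seq_len(nrow(s))) {
    pts <- sweep(gp * r[a], 2, X[a, ], "+")
    free <- rep(TRUE, n_points)
    for (b in seq_len(nrow(s))) {
      if (b == a) next
      d2 <- (pts[, 1] - X[b, 1])^2 + (pts[, 2] - X[b, 2])^2 +
        (pts[, 3] - X[b, 3])^2
      free <- free & d2 > r[b]^2
      if (!any(free)) break
    }
    acc[a] <- mean(free) * 4 * pi * r[a]^2
  }
  per_res <- tapply(acc, s$resno, sum)
  max_area <- tapply(4 * pi * r^2, s$resno, sum)
  rel <- per_res / max_area
  as.integer(names(rel)[rel <= threshold])
}

#' Read a burial mask TSV
#'
#' Columns `chain`, `resno`, `buried` (0/1 or TRUE/FALSE).
#'
#' @param path file path.
#' @return integer vector of buried residue numbers.
#' @export
read_burial <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("resno", "buried") %in% names(df))) {
    stop("burial mask needs columns resno and buried", call. = FALSE)
  }
  df$resno[as.logical(df$buried)]
}
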