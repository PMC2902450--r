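# Synthetic data: ground-truth models with known parameters, angle datasets
# sampled from them, and toy protein structures. Every downstream module is
# testable against these without any external data.

#' Ground-truth model for simulation studies
#'
#' Builds a small, fully specified model to serve as the data-generating
#' truth in recovery and calibration studies. Two styles:
#' `"random"` draws Dirichlet CPD rows and spreads von Mises emission means
#' over the circle with concentrations in `[2, 20]`, then verifies that the
#' backbone actually informs the side chain (total-variation distance
#' between conditional and marginal chi1 densities above `min_coupling` for
#' at least one tested backbone conformation), redrawing if not.
#' `"rotameric"` is a deterministic three-state model with emissions at the
#' canonical gauche-/gauche+/trans positions (-60, 60, 180 degrees,
#' concentration 30) and hand-set rotamer couplings; it is the truth used
#' for packing demonstrations.
#'
#' @param seed integer seed.
#' @param hidden hidden-node size (ignored by `"rotameric"`, which uses 3).
#' @param aa named integer vector of chi counts; the default menu has one
#'   1-chi, one 2-chi and one 4-chi type.
#' @param style `"random"` or `"rotameric"`.
#' @param min_coupling minimum conditional-vs-marginal total variation.
#' @return a `chi_dbn` object (a ground truth, not a fitted model).
#' @export
make_ground_truth <- function(seed = 1, hidden = 3,
                              aa = c(SER = 1L, HIS = 2L, LYS = 4L),
                              style = c("random", "rotameric"),
                              min_coupling = 0.05) {
  style <- match.arg(style)
  if (style == "rotameric") return(rotameric_truth(aa))
  spec <- chi_spec(hidden, aa)
  for (try in 0:24) {
    params <- with_seed(seed + 101 * try, {
      p <- random_params(spec)
      H <- spec$hidden
      p$emission$mu <- wrap_angle(seq(-pi, pi, length.out = H + 1)[1:H] +
                                    stats::runif(1, -pi, pi))
      p$emission$kappa <- stats::runif(H, 2, 20)
      p
    })
    truth <- new_chi_dbn(spec, params)
    if (coupling_tv(truth) > min_coupling) {
      attr(truth, "seed") <- seed
      return(truth)
    }
  }
  stop("could not generate a backbone-coupled ground truth", call. = FALSE)
}

# Largest total-variation distance between conditional and marginal chi1
# densities over a small grid of backbone conformations (quadrature).
coupling_tv <- function(model, n_grid = 181) {
  a1 <- names(model$spec$aa)[1]
  marg <- chi_density(model, a1, 1, n_grid = n_grid)
  bb <- c(-2, -1, 0, 1, 2)
  tv <- 0
  for (phi in bb) {
    for (psi in bb) {
      cond <- chi_density(model, a1, 1, phi = phi, psi = psi,
                          n_grid = n_grid)
      tv <- max(tv, 0.5 * sum(abs(cond$density - marg$density)) *
                  (2 * pi / n_grid))
    }
  }
  tv
}

# Deterministic rotameric truth: three hidden states <-> the three
# staggered chi positions (gauche- = -60, gauche+ = +60, trans = 180
# degrees). The hidden state surviving the psi slice carries the backbone
# signal into the first chi transition, so the conditional chi1 mode flips
# with the backbone conformation: psi near gauche+ drives chi1 to trans,
# psi near trans drives chi1 to gauche-. Consecutive chi angles are coupled
# the way rotamer pairs are.
rotameric_truth <- function(aa) {
  spec <- chi_spec(3, aa)
  H <- 3
  K <- spec$K
  mu <- c(-pi / 3, pi / 3, pi)       # gauche-, gauche+, trans
  kappa <- c(30, 30, 30)
  initial <- matrix(1 / 3, K, H)
  transition <- array(0, dim = c(H, H, K))
  for (k in seq_len(K)) {
    lab <- spec$index_map$angle[k]
    A <- matrix(1 / 3, H, H)
    if (lab == "chi1") {
      # backbone-coupled: rows are the hidden state after the psi slice
      A <- rbind(c(0.40, 0.10, 0.50),   # from g-: mixed
                 c(0.05, 0.05, 0.90),   # from g+: chi1 goes trans
                 c(0.80, 0.05, 0.15))   # from t:  chi1 goes gauche-
    } else if (lab %in% c("chi2", "chi3", "chi4")) {
      # rotamer coupling: g- pairs with g+, g+ with g-, t with t
      A <- rbind(c(0.10, 0.80, 0.10),
                 c(0.80, 0.10, 0.10),
                 c(0.10, 0.10, 0.80))
    }
    transition[, , k] <- A / rowSums(A)
  }
  new_chi_dbn(spec, list(initial = initial, transition = transition,
                         emission = list(mu = mu, kappa = kappa)))
}

#' Sample an angle dataset from a ground truth
#'
#' Draws `n` i.i.d. residues by ancestral sampling, with amino-acid types
#' drawn from `composition` (default: uniform over the truth's menu), and
#' optionally masks a fraction of the backbone observations as missing.
#'
#' @param truth a `chi_dbn` object.
#' @param n number of residues.
#' @param seed integer seed.
#' @param missing_backbone_fraction fraction of rows whose phi/psi are set
#'   to `NA`.
#' @param composition optional named probability vector over amino acids.
#' @return a `chi_angles` data.frame with `n` rows.
#' @export
sample_dataset <- function(truth, n, seed = NULL,
                           missing_backbone_fraction = 0,
                           composition = NULL) {
  stopifnot(n >= 1, missing_backbone_fraction >= 0,
            missing_backbone_fraction <= 1)
  menu <- names(truth$spec$aa)
  if (is.null(composition)) {
    composition <- stats::setNames(rep(1 / length(menu), length(menu)), menu)
  }
  with_seed(seed, {
    types <- sample(menu, n, replace = TRUE, prob = composition[menu])
    parts <- lapply(menu, function(a) {
      cnt <- sum(types == a)
      if (cnt == 0) return(NULL)
      sample_ancestral(truth, a, cnt)
    })
    df <- do.call(rbind, parts[!vapply(parts, is.null, TRUE)])
    df <- df[sample.int(nrow(df)), ]
    rownames(df) <- NULL
    if (missing_backbone_fraction > 0) {
      k <- round(missing_backbone_fraction * n)
      if (k > 0) {
        sel <- sample.int(n, k)
        df$phi[sel] <- NA_real_
        df$psi[sel] <- NA_real_
      }
    }
    df
  })
}

# Toy-protein layouts: residue types, backbone dihedrals (degrees), native
# chi assignments (degrees), and the "naive" assignment (each residue's
# conditional-mode rotamer under the rotameric ground truth, ignoring the
# other residues). In helix_clash the two leucines sit on the same face of
# an extended backbone whose psi angles differ at the two sites; under the
# backbone-coupled rotameric truth their conditional modes are chi1 = 180
# (residue 2) and chi1 = -60 (residue 4), which collide head-on, while the
# recorded native combination packs without any close contact.
TOY_LAYOUTS <- list(
  dipeptide = list(
    aa = c("SER", "HIS"),
    phi = c(-70, -70), psi = c(140, 140),
    native = list(`1` = -60, `2` = c(-60, 60)),
    naive = list(`1` = -60, `2` = c(-60, 60))
  ),
  helix_clash = list(
    aa = c("ALA", "LEU", "ALA", "LEU", "ALA"),
    phi = rep(-90, 5), psi = c(90, 90, 90, -150, 90),
    native = list(`2` = c(180, 60), `4` = c(-60, 180)),
    naive = list(`2` = c(180, 180), `4` = c(-60, 60))
  )
)

#' Toy protein structures with known native side chains
#'
#' Builds a small single-chain structure on an ideal-geometry backbone with
#' recorded native chi angles. The `"helix_clash"` layout places two large
#' side chains on an alpha-helix such that their marginally most probable
#' rotamers (under the rotameric ground truth) clash sterically while the
#' native combination does not — the situation that requires coordinated
#' multi-residue moves during packing. `"dipeptide"` is a minimal two-residue
#' fixture for geometry round trips.
#'
#' @param layout `"helix_clash"` or `"dipeptide"`.
#' @param seed integer seed (recorded; the construction is deterministic).
#' @return list of class `toy_protein` with `structure` (full-atom, at the
#'   native chi), `backbone` (backbone-only), `native` and `naive` (named
#'   lists of chi vectors in radians, names = residue numbers; `naive` is
#'   the uncoordinated per-residue conditional-mode assignment),
#'   `native_angles` (a `chi_angles` table), `layout`.
#' @export
make_toy_protein <- function(layout = c("helix_clash", "dipeptide"),
                             seed = 1) {
  layout <- match.arg(layout)
  L <- TOY_LAYOUTS[[layout]]
  bb <- build_backbone(L$aa, L$phi * pi / 180, L$psi * pi / 180)
  native <- lapply(L$native, function(v) v * pi / 180)
  naive <- lapply(L$naive, function(v) v * pi / 180)
  full <- rebuild_side_chains(bb, native)
  structure(list(structure = full, backbone = bb, native = native,
                 naive = naive,
                 native_angles = residue_angles(full),
                 layout = layout, seed = seed),
            class = "toy_protein")
}

#' @export
print.toy_protein <- function(x, ...) {
  cat(sprintf("Toy protein '%s': %d residues, %d atoms\n", x$layout,
              length(unique(x$structure$resno)), nrow(x$structure)))
  invisible(x)
}

#' Minimum non-bonded heavy-atom distance
#'
#' The smallest distance between atoms more than `min_separation` bonds
#' apart — the clash diagnostic used by the packing tests.
#'
#' @param structure a `protein_structure`.
#' @param min_separation bond-graph distance above which pairs count.
#' @return minimum distance in Angstroms.
#' @export
min_nonbonded_distance <- function(structure, min_separation = 2) {
  s <- structure
  X <- as.matrix(s[, c("x", "y", "z")])
  excl <- exclusion_matrix(s)
  n <- nrow(s)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    J <- (i + 1):n
    J <- J[!excl[i, J]]
    if (!length(J)) next
    d2 <- (X[J, 1] - X[i, 1])^2 + (X[J, 2] - X[i, 2])^2 +
      (X[J, 3] - X[i, 3])^2
    dmin <- min(dmin, sqrt(min(d2)))
  }
  dmin
}
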