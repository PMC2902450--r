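# Model structure: amino-acid chi table, input-index scheme, parameter
# containers and their validation, model file I/O, and the angle-table format.
#
# The model is a dynamic Bayesian network with one slice per dihedral angle
# (phi, psi, chi1..chin). Each slice carries a discrete input index that
# identifies (amino acid, angle label), a discrete hidden node, and a von
# Mises output node. Initial and transition distributions are indexed by the
# input index; a single emission table of von Mises components is shared by
# all slices and all amino acids.

#' Number of chi angles per rotameric amino acid
#'
#' The 18 standard amino acids with at least one rotatable side-chain
#' dihedral (alanine and glycine have none and are not modelled). Proline is
#' included with two chi angles.
#'
#' @return named integer vector, names are 3-letter codes in alphabetical
#'   order.
#' @export
chi_counts <- function() {
  c(ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L, GLU = 3L,
    HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L, MET = 3L, PHE = 2L,
    PRO = 2L, SER = 1L, THR = 1L, TRP = 2L, TYR = 2L, VAL = 1L)
}

#' Build the input-index map for a set of amino acids
#'
#' Assigns each (amino acid, angle label) pair a contiguous integer index
#' starting at 0. The scheme is deterministic: amino acids sorted by 3-letter
#' code; within each amino acid the order is phi, psi, chi1..chin. Every
#' amino acid therefore contributes `2 + n_chi` indices.
#'
#' @param aa named integer vector mapping 3-letter codes to chi counts
#'   (default: the full [chi_counts()] table). Chi counts must be in 1..4.
#' @return data.frame with columns `aa`, `angle` (one of `phi`, `psi`,
#'   `chi1`..`chi4`) and `index` (0-based).
#' @examples
#' im <- build_index_map()
#' subset(im, aa == "ARG")   # indices 0..5
#' @export
build_index_map <- function(aa = chi_counts()) {
  if (is.null(names(aa)) || any(!nzchar(names(aa)))) {
    stop("aa must be a named vector of chi counts", call. = FALSE)
  }
  if (any(aa < 1L) || any(aa > 4L)) {
    stop("chi counts must be between 1 and 4", call. = FALSE)
  }
  ord <- order(names(aa))
  aa <- aa[ord]
  rows <- lapply(names(aa), function(a) {
    data.frame(aa = a,
               angle = c("phi", "psi", paste0("chi", seq_len(aa[[a]]))),
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  map$index <- seq_len(nrow(map)) - 1L
  map
}

#' Model specification: amino-acid menu, index map and hidden-node size
#'
#' @param hidden hidden-node size H (number of discrete hidden states),
#'   `>= 1`.
#' @param aa named integer vector of chi counts (default [chi_counts()]).
#' @return an object of class `chi_spec` with fields `hidden`, `aa`,
#'   `index_map` and `K` (total index count).
#' @export
chi_spec <- function(hidden, aa = chi_counts()) {
  if (length(hidden) != 1 || !is.finite(hidden) || hidden < 1) {
    stop("hidden must be a single integer >= 1", call. = FALSE)
  }
  map <- build_index_map(aa)
  structure(list(hidden = as.integer(hidden),
                 aa = aa[order(names(aa))],
                 index_map = map,
                 K = nrow(map)),
            class = "chi_spec")
}

#' Slice index sequence for an amino acid
#'
#' The ordered input indices of the slices modelling one residue of the given
#' type: phi, psi, then chi1..chin. The slice count never changes between
#' backbone-dependent and backbone-independent use; whether the backbone
#' slices are observed is controlled by evidence masks, not by the chain
#' length.
#'
#' @param spec a [chi_spec()] object.
#' @param aa 3-letter amino-acid code present in the spec.
#' @return integer vector of 0-based input indices, length `2 + n_chi`.
#' @export
slice_sequence <- function(spec, aa) {
  stopifnot(inherits(spec, "chi_spec"))
  if (!aa %in% names(spec$aa)) {
    stop("amino acid not modelled: ", aa, call. = FALSE)
  }
  spec$index_map$index[spec$index_map$aa == aa]
}

# Random row-stochastic parameter set for a spec (symmetric Dirichlet(1)
# rows; emission means spread over the circle, kappa = 1). Used for EM
# initialization and as raw material for synthetic ground truths.
random_params <- function(spec, seed = NULL) {
  with_seed(seed, {
    H <- spec$hidden
    K <- spec$K
    rdir <- function(n) {
      g <- matrix(stats::rexp(n * H), n, H)
      g / rowSums(g)
    }
    initial <- rdir(K)
    transition <- array(0, dim = c(H, H, K))
    for (k in seq_len(K)) transition[, , k] <- rdir(H)
    mu <- wrap_angle(seq(-pi, pi, length.out = H + 1)[seq_len(H)] +
                       stats::runif(1, -pi, pi))
    list(initial = initial,
         transition = transition,
         emission = list(mu = mu, kappa = rep(1, H)))
  })
}

# Assemble a chi_dbn object from a spec and a parameter set; validates.
new_chi_dbn <- function(spec, params, logLik = NA_real_, trace = numeric(0),
                        aic = NA_real_, k = NA_integer_, n = NA_integer_,
                        call = NULL) {
  m <- structure(list(hidden = spec$hidden,
                      spec = spec,
                      initial = params$initial,
                      transition = params$transition,
                      emission = params$emission,
                      logLik = logLik, trace = trace,
                      aic = aic, k = k, n = n, call = call),
                 class = "chi_dbn")
  validate_chi_dbn(m)
  m
}

# Invariant checks: shapes, row-stochasticity to 1e-9, non-negativity,
# emission parameter validity.
validate_chi_dbn <- function(m, tol = 1e-9) {
  H <- m$hidden
  K <- m$spec$K
  stopifnot(is.matrix(m$initial), dim(m$initial)[1] == K,
            dim(m$initial)[2] == H)
  stopifnot(length(dim(m$transition)) == 3,
            all(dim(m$transition) == c(H, H, K)))
  if (any(m$initial < 0) || any(m$transition < 0)) {
    stop("negative probability entry", call. = FALSE)
  }
  if (any(abs(rowSums(m$initial) - 1) > tol)) {
    stop("initial distribution rows do not sum to 1", call. = FALSE)
  }
  rs <- apply(m$transition, 3, rowSums)
  if (any(abs(rs - 1) > tol)) {
    stop("transition rows do not sum to 1", call. = FALSE)
  }
  stopifnot(length(m$emission$mu) == H, length(m$emission$kappa) == H)
  check_vm_params(m$emission$mu, m$emission$kappa)
  invisible(m)
}

#' Count model parameters
#'
#' With hidden size H and K input indices, the free-parameter count is
#' `K*(H-1)` for the initial distributions, `K*H*(H-1)` for the transitions
#' (each row of a stochastic matrix has `H-1` free entries) and `2*H` for the
#' shared von Mises emission table. With `nonzero_only = TRUE` the
#' probability contribution is instead the number of entries strictly above
#' `threshold`, plus `2*H` — the convention used when reporting "non-zero"
#' parameter counts of a trained model.
#'
#' @param model a `chi_dbn` object.
#' @param nonzero_only count strictly positive probability entries instead of
#'   free parameters.
#' @param threshold positivity threshold for `nonzero_only`.
#' @return integer parameter count.
#' @export
count_parameters <- function(model, nonzero_only = FALSE, threshold = 1e-8) {
  validate_chi_dbn(model)
  H <- model$hidden
  K <- model$spec$K
  if (nonzero_only) {
    sum(model$initial > threshold) + sum(model$transition > threshold) + 2L * H
  } else {
    K * (H - 1L) + K * H * (H - 1L) + 2L * H
  }
}

MODEL_FORMAT <- "sidechainr-model"
MODEL_FORMAT_VERSION <- 1L

#' Save / load a model
#'
#' The model file is self-describing structured text (JSON): a format tag and
#' version, the hidden size, the amino-acid table and index map, and all
#' probabilities and emission parameters at full double precision, so that
#' `read_chi_dbn(write_chi_dbn(m, path))` reproduces the model bit-exactly.
#'
#' @param model a `chi_dbn` object.
#' @param path file path.
#' @return `write_chi_dbn` returns `path` invisibly; `read_chi_dbn` returns
#'   the restored `chi_dbn` object.
#' @export
write_chi_dbn <- function(model, path) {
  validate_chi_dbn(model)
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_FORMAT_VERSION,
    hidden = model$hidden,
    aa = as.list(model$spec$aa),
    initial = model$initial,
    transition = lapply(seq_len(model$spec$K),
                        function(k) model$transition[, , k]),
    emission = model$emission,
    logLik = model$logLik,
    aic = model$aic,
    k = model$k,
    n = model$n
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor", na = "null")
  invisible(path)
}

#' @rdname write_chi_dbn
#' @export
read_chi_dbn <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("not a valid model file: ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (is.null(obj$format) || obj$format != MODEL_FORMAT) {
    stop("not a ", MODEL_FORMAT, " file", call. = FALSE)
  }
  if (is.null(obj$version) || obj$version != MODEL_FORMAT_VERSION) {
    stop("unsupported model file version: ", obj$version, call. = FALSE)
  }
  aa <- unlist(obj$aa)
  storage.mode(aa) <- "integer"
  spec <- chi_spec(obj$hidden, aa)
  H <- spec$hidden
  K <- spec$K
  transition <- array(0, dim = c(H, H, K))
  if (is.array(obj$transition) && length(dim(obj$transition)) == 3) {
    # jsonlite simplifies a list of equal-shape matrices to a K x H x H array
    if (!all(dim(obj$transition) == c(K, H, H))) {
      stop("corrupt model file", call. = FALSE)
    }
    for (k in seq_len(K)) transition[, , k] <- obj$transition[k, , ]
  } else {
    if (length(obj$transition) != K) stop("corrupt model file", call. = FALSE)
    for (k in seq_len(K)) transition[, , k] <- obj$transition[[k]]
  }
  storage.mode(transition) <- "double"
  params <- list(initial = matrix(as.numeric(obj$initial), K, H),
                 transition = transition,
                 emission = list(mu = as.numeric(obj$emission$mu),
                                 kappa = as.numeric(obj$emission$kappa)))
  new_chi_dbn(spec, params,
              logLik = if (is.null(obj$logLik)) NA_real_ else obj$logLik,
              aic = if (is.null(obj$aic)) NA_real_ else obj$aic,
              k = if (is.null(obj$k)) NA_integer_ else as.integer(obj$k),
              n = if (is.null(obj$n)) NA_integer_ else as.integer(obj$n))
}

# ---- Angle tables ----------------------------------------------------------

ANGLE_COLS <- c("phi", "psi", "chi1", "chi2", "chi3", "chi4")

#' Construct an angle table
#'
#' The package-wide container for residue dihedral observations: a data.frame
#' with a 3-letter `aa` column and angle columns `phi, psi, chi1..chi4` in
#' radians, `NA` meaning missing/not applicable. Chi columns beyond an amino
#' acid's chi count are `NA`.
#'
#' @param aa character vector of 3-letter codes.
#' @param phi,psi backbone angles in radians (or `NA`).
#' @param chi matrix (n x 4) of side-chain angles in radians, `NA`-padded.
#' @return data.frame of class `chi_angles`.
#' @export
angle_table <- function(aa, phi, psi, chi) {
  chi <- as.matrix(chi)
  n <- max(length(aa), length(phi), nrow(chi))
  aa <- rep(aa, length.out = n)
  if (ncol(chi) < 4) {
    chi <- cbind(chi, matrix(NA_real_, n, 4 - ncol(chi)))
  }
  df <- data.frame(aa = aa, phi = phi, psi = psi,
                   chi1 = chi[, 1], chi2 = chi[, 2],
                   chi3 = chi[, 3], chi4 = chi[, 4],
                   stringsAsFactors = FALSE)
  class(df) <- c("chi_angles", "data.frame")
  df
}

#' Read / write angle tables as TSV
#'
#' The on-disk dialect is a tab-separated file with header
#' `aa phi psi chi1 chi2 chi3 chi4`, angles in degrees, empty fields for
#' missing values. Angles are radians in memory.
#'
#' @param path file path.
#' @param x a `chi_angles` data.frame.
#' @return `read_angles` returns a `chi_angles` data.frame;
#'   `write_angles` returns `path` invisibly.
#' @export
read_angles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), comment.char = "#")
  need <- c("aa", ANGLE_COLS)
  if (!all(need %in% names(df))) {
    stop("angle TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (cl in ANGLE_COLS) df[[cl]] <- df[[cl]] * pi / 180
  class(df) <- c("chi_angles", "data.frame")
  df
}

#' @rdname read_angles
#' @export
write_angles <- function(x, path) {
  df <- as.data.frame(x)[, c("aa", ANGLE_COLS)]
  for (cl in ANGLE_COLS) df[[cl]] <- df[[cl]] * 180 / pi
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

# Chi vector of one angle-table row, trimmed to the amino acid's chi count.
row_chi <- function(row, spec) {
  nchi <- spec$aa[[row$aa]]
  as.numeric(row[paste0("chi", seq_len(nchi))])
}
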