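# Backbone-independent rotamer libraries: parsing, Gaussian-mixture density
# evaluation, and relative Kullback-Leibler model comparison.
#
# A library assigns each amino acid a set of rotamers; each rotamer has a
# probability weight and, per chi angle, a Gaussian (mean, sd). The density
# of a chi vector is the weighted mixture with each Gaussian evaluated on the
# WRAPPED difference to its mean, so rotamers centred near +/-180 degrees
# keep their full mass.

#' Read a backbone-independent rotamer library
#'
#' The default dialect is whitespace-separated text, one rotamer per line:
#' `aa prob mean1 sd1 [mean2 sd2 ...]` with angles in degrees; lines starting
#' with `#` are comments. Files in other column layouts can be read by
#' supplying `column_map`, a list with entries `aa`, `prob`, `means`, `sds`
#' giving 1-based column positions. Per-amino-acid weights are renormalized
#' on load (libraries round their probabilities); a warning is emitted when
#' the raw sum is off by more than `renorm_warn`.
#'
#' @param path file path.
#' @param column_map optional column-position list for foreign layouts.
#' @param known restrict to these amino acids; rows for other residue names
#'   are skipped with a warning (default: the [chi_counts()] menu).
#' @param renorm_warn warn when a weight sum deviates from 1 by more than
#'   this.
#' @return an object of class `rotamer_library`: named list, one entry per
#'   amino acid, each with `prob` (weights summing to 1), `means` and `sds`
#'   (rotamer x chi matrices, radians).
#' @export
read_rotamer_library <- function(path, column_map = NULL,
                                 known = names(chi_counts()),
                                 renorm_warn = 1e-3) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (is.null(column_map)) {
      if (length(f) < 4 || length(f) %% 2 != 0) {
        stop("rotamer library parse error at line ", i,
             ": expected 'aa prob mean1 sd1 [mean2 sd2 ...]'", call. = FALSE)
      }
      aa <- f[1]
      nums <- suppressWarnings(as.numeric(f[-1]))
      if (any(is.na(nums))) {
        stop("rotamer library parse error at line ", i,
             ": non-numeric field", call. = FALSE)
      }
      prob <- nums[1]
      rest <- nums[-1]
      means <- rest[seq(1, length(rest), 2)]
      sds <- rest[seq(2, length(rest), 2)]
    } else {
      need <- max(unlist(column_map))
      if (length(f) < need) {
        stop("rotamer library parse error at line ", i,
             ": fewer than ", need, " columns", call. = FALSE)
      }
      aa <- f[column_map$aa]
      prob <- suppressWarnings(as.numeric(f[column_map$prob]))
      means <- suppressWarnings(as.numeric(f[column_map$means]))
      sds <- suppressWarnings(as.numeric(f[column_map$sds]))
      ok <- !is.na(means) & !is.na(sds)
      means <- means[ok]; sds <- sds[ok]
      if (is.na(prob) || length(means) == 0) {
        stop("rotamer library parse error at line ", i, call. = FALSE)
      }
    }
    if (any(sds <= 0)) {
      stop("rotamer library parse error at line ", i,
           ": non-positive standard deviation", call. = FALSE)
    }
    rows[[length(rows) + 1]] <- list(aa = aa, prob = prob,
                                     means = means, sds = sds)
  }
  aa_all <- vapply(rows, `[[`, "", "aa")
  unknown <- setdiff(unique(aa_all), known)
  if (length(unknown)) {
    warning("skipping unknown residue name(s): ",
            paste(unknown, collapse = ", "))
  }
  lib <- list()
  for (a in intersect(unique(aa_all), known)) {
    rs <- rows[aa_all == a]
    nchi <- length(rs[[1]]$means)
    if (any(vapply(rs, function(r) length(r$means), 0L) != nchi)) {
      stop("inconsistent chi count within ", a, call. = FALSE)
    }
    prob <- vapply(rs, `[[`, 0, "prob")
    s <- sum(prob)
    if (abs(s - 1) > renorm_warn) {
      warning(sprintf("%s: rotamer weights sum to %.4f; renormalizing", a, s))
    }
    lib[[a]] <- list(
      prob = prob / s,
      means = do.call(rbind, lapply(rs, `[[`, "means")) * pi / 180,
      sds = do.call(rbind, lapply(rs, `[[`, "sds")) * pi / 180)
  }
  structure(lib, class = "rotamer_library")
}

#' @export
print.rotamer_library <- function(x, ...) {
  cat(sprintf("Rotamer library: %d amino acid(s)\n", length(x)))
  for (a in names(x)) {
    cat(sprintf("  %s: %d rotamers, %d chi angle(s)\n",
                a, length(x[[a]]$prob), ncol(x[[a]]$means)))
  }
  invisible(x)
}

#' Log-density of chi angles under a rotamer library
#'
#' `log sum_R P(R) prod_n N(wrap(chi_n - mu_Rn); 0, sd_Rn)` — the
#' Gaussian-mixture density of the library, per radian, in nats.
#'
#' @param library a `rotamer_library`.
#' @param aa 3-letter amino-acid code present in the library.
#' @param chi numeric vector of chi angles (radians), or a matrix with one
#'   chi vector per row.
#' @return numeric vector of log-densities.
#' @export
rotamer_logpdf <- function(library, aa, chi) {
  if (!aa %in% names(library)) {
    stop("amino acid not in rotamer library: ", aa, call. = FALSE)
  }
  ent <- library[[aa]]
  if (is.null(dim(chi))) chi <- matrix(chi, nrow = 1)
  if (ncol(chi) != ncol(ent$means)) {
    stop("chi length ", ncol(chi), " does not match the library's ",
         ncol(ent$means), " chi angles for ", aa, call. = FALSE)
  }
  n <- nrow(chi)
  R <- length(ent$prob)
  comp <- matrix(log(ent$prob), n, R, byrow = TRUE)
  for (r in seq_len(R)) {
    for (j in seq_len(ncol(chi))) {
      comp[, r] <- comp[, r] +
        stats::dnorm(angle_diff(chi[, j], ent$means[r, j]),
                     0, ent$sds[r, j], log = TRUE)
    }
  }
  mx <- apply(comp, 1, max)
  mx + log(rowSums(exp(comp - mx)))
}

#' Relative KL divergence between two density models
#'
#' Estimates `D(p || q_r) - D(p || q_b)` as the empirical expectation
#' `mean(log q_b(x) - log q_r(x))` over test observations drawn from `p`,
#' reported per amino acid plus an overall average. Positive values mean
#' model `b` fits the data better than model `r`.
#'
#' @param data a `chi_angles` data.frame of test observations.
#' @param logpdf_b,logpdf_r functions taking the data (a `chi_angles`
#'   data.frame) and returning per-row log-densities in nats.
#' @return an object of class `delta_kl`: list with `table` (data.frame
#'   `aa`, `n`, `delta_kl_nats`), `average` (unweighted mean over amino
#'   acids), `overall` (pooled mean over residues) and `flagged` (row indices
#'   with non-finite log-densities, excluded from the estimate).
#' @export
delta_kl <- function(data, logpdf_b, logpdf_r) {
  lb <- logpdf_b(data)
  lr <- logpdf_r(data)
  stopifnot(length(lb) == nrow(data), length(lr) == nrow(data))
  d <- lb - lr
  flagged <- which(!is.finite(d))
  ok <- is.finite(d)
  tab <- do.call(rbind, lapply(sort(unique(data$aa)), function(a) {
    sel <- ok & data$aa == a
    data.frame(aa = a, n = sum(sel), delta_kl_nats = mean(d[sel]))
  }))
  structure(list(table = tab,
                 average = mean(tab$delta_kl_nats),
                 overall = mean(d[ok]),
                 flagged = flagged),
            class = "delta_kl")
}

#' @export
print.delta_kl <- function(x, ...) {
  cat("Relative KL divergence (nats; positive = first model better)\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("Average %.4f\n", x$average))
  if (length(x$flagged)) {
    cat(sprintf("(%d record(s) with non-finite log-density excluded)\n",
                length(x$flagged)))
  }
  invisible(x)
}

#' Write a per-amino-acid KL report as TSV
#'
#' @param x a `delta_kl` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_delta_kl <- function(x, path) {
  tab <- rbind(x$table,
               data.frame(aa = "average", n = sum(x$table$n),
                          delta_kl_nats = x$average))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
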