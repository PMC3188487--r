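#' Elastic-network parameters
#'
#' The network is cutoff-free: every residue pair interacts.  Covalently
#' consecutive residues (author numbers differing by exactly 1 in the same
#' chain) are "bonded" springs with constant `gamma_bonded`; all other pairs
#' are "non-bonded" springs whose constant decays with the inverse square of
#' the pair distance, `k_ij = nonbonded_numerator / r_ij^2`.  The distance
#' weighting removes the arbitrary interaction cutoff of conventional
#' elastic network models.
#'
#' @param gamma_bonded spring constant for sequence-adjacent pairs
#'   (dimensionless stiffness; default 1).
#' @param nonbonded_numerator numerator `c` of the non-bonded spring law
#'   `c / r^2` with `r` in Angstrom (default 8).
#' @param min_pair_distance guard in Angstrom against coincident nodes.
#' @param cutoff optional interaction cutoff in Angstrom for
#'   experimentation; `NULL` (the default, and the intended model) keeps all
#'   pairs.  Bonded springs are never cut.
#' @return an object of class `enm_params`.
#' @export
enm_params <- function(gamma_bonded = 1, nonbonded_numerator = 8,
                       min_pair_distance = 0.1, cutoff = NULL) {
  stopifnot(gamma_bonded > 0, nonbonded_numerator > 0, min_pair_distance > 0,
            is.null(cutoff) || cutoff > 0)
  structure(list(gamma_bonded = gamma_bonded,
                 nonbonded_numerator = nonbonded_numerator,
                 min_pair_distance = min_pair_distance,
                 cutoff = cutoff),
            class = "enm_params")
}

# pairwise spring constants (N x N, zero diagonal, NA -> excluded pair)
spring_constants <- function(model, params, dist_matrix) {
  n <- n_residues(model)
  bonded <- outer(model$chain, model$chain, "==") &
    abs(outer(model$resno, model$resno, "-")) == 1L
  k <- params$nonbonded_numerator / dist_matrix^2
  if (!is.null(params$cutoff)) k[dist_matrix > params$cutoff] <- 0
  k[bonded] <- params$gamma_bonded
  diag(k) <- 0
  k
}

pair_distances <- function(model, params) {
  d <- as.matrix(stats::dist(model$coords))
  off <- d[upper.tri(d)]
  if (any(off < params$min_pair_distance)) {
    idx <- which(d < params$min_pair_distance & upper.tri(d),
                 arr.ind = TRUE)[1, ]
    lab <- residue_labels(model)
    stop("coincident/near-coincident nodes ", lab[idx[1]], " and ",
         lab[idx[2]], ": distance below ", params$min_pair_distance, " A")
  }
  d
}

#' Build the elastic-network Hessian
#'
#' Assembles the 3N x 3N stiffness matrix of the weighted network.  For each
#' interacting pair the off-diagonal 3x3 block is
#' `-(k_ij / r_ij^2) * (r_ij %o% r_ij)` with `r_ij` the separation vector;
#' each diagonal block is minus the sum of the off-diagonal blocks in its
#' row, which enforces translation invariance (uniform translations are
#' exact zero modes).
#'
#' @param model a [calpha_model()].
#' @param params an [enm_params()].
#' @return an object of class `enm_hessian`: fields `matrix` (3N x 3N),
#'   `model` and `params`.
#' @export
#' @examples
#' h <- build_hessian(make_fixture("ring", 6))
#' max(abs(h$matrix %*% rep(c(1, 0, 0), 6)))  # translation -> zero force
build_hessian <- function(model, params = enm_params()) {
  stopifnot(inherits(model, "calpha_model"), inherits(params, "enm_params"))
  n <- n_residues(model)
  d <- pair_distances(model, params)
  k <- spring_constants(model, params, d)
  x <- model$coords
  h <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    ii <- (3 * i - 2):(3 * i)
    for (j in (i + 1):n) {
      if (k[i, j] == 0) next
      jj <- (3 * j - 2):(3 * j)
      rij <- x[j, ] - x[i, ]
      blk <- -(k[i, j] / d[i, j]^2) * tcrossprod(rij)
      h[ii, jj] <- blk
      h[jj, ii] <- blk
      h[ii, ii] <- h[ii, ii] - blk
      h[jj, jj] <- h[jj, jj] - blk
    }
  }
  structure(list(matrix = h, model = model, params = params),
            class = "enm_hessian")
}

#' Hessian through the directional-cosine factorization
#'
#' Assembles the same stiffness matrix as [build_hessian()] by the
#' mechanics-of-trusses route: `H = B K B^T`, where `B` (3N x M) holds the
#' directional cosines of the M pairwise interactions and `K` (M x M,
#' diagonal) their Hooke spring constants.  The two constructions are
#' algebraically identical; keeping both provides an internal cross-check
#' of the block assembly.
#'
#' @inheritParams build_hessian
#' @return an `enm_hessian` (as [build_hessian()]).
#' @export
build_bkb_hessian <- function(model, params = enm_params()) {
  stopifnot(inherits(model, "calpha_model"), inherits(params, "enm_params"))
  n <- n_residues(model)
  d <- pair_distances(model, params)
  k <- spring_constants(model, params, d)
  pairs <- which(upper.tri(k) & k != 0, arr.ind = TRUE)
  m <- nrow(pairs)
  if (m == 0L) stop("no interacting pairs")
  b <- matrix(0, 3 * n, m)
  kdiag <- numeric(m)
  for (p in seq_len(m)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    e <- (model$coords[j, ] - model$coords[i, ]) / d[i, j]
    b[(3 * i - 2):(3 * i), p] <- e
    b[(3 * j - 2):(3 * j), p] <- -e
    kdiag[p] <- k[i, j]
  }
  h <- b %*% (kdiag * t(b))
  structure(list(matrix = h, model = model, params = params),
            class = "enm_hessian")
}

#' @export
print.enm_hessian <- function(x, ...) {
  cat("Elastic-network Hessian: ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (", n_residues(x$model), " residues), gamma_b = ",
      x$params$gamma_bonded, ", c_nb = ", x$params$nonbonded_numerator,
      if (is.null(x$params$cutoff)) ", no cutoff" else
        paste0(", cutoff ", x$params$cutoff, " A"),
      "\n", sep = "")
  invisible(x)
}

#' Compliance: pseudo-inverse of the Hessian
#'
#' Linear response theory relates an applied force to the equilibrium
#' displacement through the inverse Hessian.  The Hessian of an
#' unconstrained 3D network is singular (six rigid-body zero modes for a
#' generic geometry), so the inverse is realized as the Moore-Penrose
#' pseudo-inverse via symmetric eigendecomposition: eigenvalues below
#' `tolerance` times the largest eigenvalue are treated as the null space
#' and dropped.
#'
#' @param h an `enm_hessian`.
#' @param tolerance relative eigenvalue cutoff (default 1e-8).
#' @return object of class `enm_compliance`: `matrix` (3N x 3N),
#'   `dropped_modes`, `tolerance_used`, `model`.  A warning is raised when
#'   the number of dropped modes differs from 6, which signals collinear or
#'   otherwise degenerate geometry.
#' @export
compute_compliance <- function(h, tolerance = 1e-8) {
  stopifnot(inherits(h, "enm_hessian"))
  m <- h$matrix
  if (max(abs(m - t(m))) > 1e-9 * max(abs(m)))
    stop("Hessian is not symmetric")
  eig <- eigen((m + t(m)) / 2, symmetric = TRUE)
  keep <- eig$values > tolerance * max(eig$values)
  dropped <- sum(!keep)
  if (dropped != 6L)
    warning("dropped ", dropped, " null modes (expected 6): ",
            "geometry is degenerate (e.g. collinear) or tolerance unsuitable")
  v <- eig$vectors[, keep, drop = FALSE]
  cmat <- v %*% (t(v) / eig$values[keep])
  structure(list(matrix = cmat, dropped_modes = dropped,
                 tolerance_used = tolerance, model = h$model),
            class = "enm_compliance")
}

#' @export
print.enm_compliance <- function(x, ...) {
  cat("Elastic-network compliance (pseudo-inverse Hessian): ",
      nrow(x$matrix), " x ", ncol(x$matrix), ", ", x$dropped_modes,
      " null modes dropped (tol ", format(x$tolerance_used), ")\n", sep = "")
  invisible(x)
}
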