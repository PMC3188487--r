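#' Synthetic C-alpha geometries for testing and demonstration
#'
#' Generates idealized coarse-grained structures on which every stage of the
#' analysis has a known, hand-checkable answer: a collinear chain (a
#' deliberately degenerate geometry whose elastic network has more than six
#' zero modes), a planar ring, an ideal alpha-helix (3.6 residues per turn,
#' 1.5 Angstrom rise, 2.3 Angstrom radius), a seeded random point cloud with
#' a minimum-separation guarantee, and a two-node spring.
#'
#' Fixture residues are labelled ALA on chain "A", numbered sequentially
#' from 1.
#'
#' @param kind one of `"linear_chain"`, `"ring"`, `"ideal_helix"`,
#'   `"random_cloud"`, `"two_mass"`.
#' @param n_residues number of residues (>= 2; `two_mass` forces 2).
#' @param spacing consecutive C-alpha distance in Angstrom (chord length for
#'   rings; ignored for the helix, whose canonical geometry fixes it near
#'   3.8 Angstrom).
#' @param seed integer seed for `random_cloud`; the generator is
#'   deterministic per seed and restores the caller's RNG state.
#'
#' @return a [calpha_model()].
#' @export
#' @examples
#' helix <- make_fixture("ideal_helix", 20)
#' range(sqrt(rowSums(diff(helix$coords)^2)))
make_fixture <- function(kind = c("linear_chain", "ring", "ideal_helix",
                                  "random_cloud", "two_mass"),
                         n_residues = 10, spacing = 3.8, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n_residues)
  if (kind == "two_mass") n <- 2L
  if (n < 2L) stop("'n_residues' must be >= 2")
  if (spacing <= 0) stop("'spacing' must be positive")
  coords <- switch(kind,
    linear_chain = ,
    two_mass = cbind(x = spacing * (seq_len(n) - 1), y = 0, z = 0),
    ring = {
      if (n < 3L) stop("a ring needs at least 3 residues")
      radius <- spacing / (2 * sin(pi / n))
      theta <- 2 * pi * (seq_len(n) - 1) / n
      cbind(x = radius * cos(theta), y = radius * sin(theta), z = 0)
    },
    ideal_helix = {
      rise <- 1.5; radius <- 2.3; dtheta <- 2 * pi / 3.6
      theta <- dtheta * (seq_len(n) - 1)
      cbind(x = radius * cos(theta), y = radius * sin(theta),
            z = rise * (seq_len(n) - 1))
    },
    random_cloud = random_cloud_coords(n, spacing, seed))
  calpha_model(coords, resno = seq_len(n), chain = "A", resid = "ALA",
               source_label = paste0("fixture:", kind, ":", n))
}

# Uniform points in a box scaled to the target density, rejection-sampled to
# keep all pairs at least 0.8 * spacing apart.  RNG state is restored.
random_cloud_coords <- function(n, spacing, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  side <- spacing * max(2, ceiling(n^(1 / 3)) + 1)
  min_sep <- 0.8 * spacing
  pts <- matrix(NA_real_, n, 3)
  pts[1, ] <- runif(3, 0, side)
  for (i in 2:n) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      cand <- runif(3, 0, side)
      d2 <- rowSums(sweep(pts[seq_len(i - 1), , drop = FALSE], 2, cand)^2)
      if (all(d2 >= min_sep^2)) { pts[i, ] <- cand; ok <- TRUE; break }
    }
    if (!ok) stop("could not satisfy minimum separation ", min_sep,
                  " A for ", n, " points; increase spacing or box")
  }
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Independent linear-response oracle on small fixtures
#'
#' Solves the force-displacement problem of the elastic network by a route
#' independent of [compute_compliance()]/[perturb()]: the stiffness matrix is
#' assembled through the directional-cosine factorization
#' ([build_bkb_hessian()]) and inverted with [MASS::ginv()] (SVD-based
#' Moore-Penrose inverse).  For the axial two-mass system the Hooke's-law
#' closed form is also available: the relative displacement of the two nodes
#' under a unit axial force equals 1/k.
#'
#' Intended for validating [perturb()] on fixtures of at most 10 nodes.
#'
#' @param model a small [calpha_model()] (N <= 10).
#' @param site node index receiving the force.
#' @param direction force 3-vector (need not be unit length).
#' @param params [enm_params()].
#' @return displacement vector of length 3N.
#' @export
analytic_response_oracle <- function(model, site, direction,
                                     params = enm_params()) {
  n <- n_residues(model)
  if (n > 10L)
    stop("oracle supports fixtures with at most 10 nodes (got ", n, ")")
  site <- as.integer(site)
  if (site < 1L || site > n) stop("force site out of range")
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L)
  h <- build_bkb_hessian(model, params)
  f <- numeric(3 * n)
  f[(3 * site - 2):(3 * site)] <- direction
  drop(MASS::ginv(h$matrix) %*% f)
}
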