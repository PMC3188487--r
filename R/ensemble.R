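#' Generate perturbation-displaced conformers
#'
#' Displaces the C-alpha model along perturbation response fields to sample
#' receptor conformations for flexible docking.  Each conformer is
#' `base + s * dR(site, direction)` where `dR` is the linear response to a
#' unit force and `s` scales the largest per-residue displacement to
#' `amplitude`.  Sites and directions are taken from a deterministic sweep
#' over `sites x directions`; when more conformers are requested than the
#' sweep provides, additional seeded random (site, direction) draws are
#' used.  The first conformer is always the unperturbed model.  Conformers
#' that would bring two C-alphas closer than `min_clash` are rejected with
#' a warning and replaced by a seeded random draw.
#'
#' @param model a [calpha_model()].
#' @param compliance matching [compute_compliance()] result.
#' @param amplitude largest per-residue C-alpha displacement in Angstrom
#'   (default 2.0).
#' @param n_conformers number of conformers including the unperturbed one
#'   (default 50).
#' @param sites perturbation sites as node indices (default all residues).
#' @param directions unit direction rows (default [prs_directions()]).
#' @param seed integer seed for any random draws (default 1).
#' @param min_clash C-alpha clash distance in Angstrom (default 1.0).
#' @return list of `calpha_model`s; element 1 is the input model.
#' @export
#' @examples
#' m <- make_fixture("ideal_helix", 15)
#' comp <- compute_compliance(build_hessian(m))
#' ens <- generate_conformers(m, comp, amplitude = 1, n_conformers = 5)
generate_conformers <- function(model, compliance, amplitude = 2.0,
                                n_conformers = 50L, sites = NULL,
                                directions = prs_directions(), seed = 1L,
                                min_clash = 1.0) {
  stopifnot(inherits(model, "calpha_model"),
            inherits(compliance, "enm_compliance"))
  n <- n_residues(model)
  if (nrow(compliance$matrix) != 3L * n)
    stop("model and compliance sizes disagree")
  if (amplitude <= 0) stop("'amplitude' must be positive")
  n_conformers <- as.integer(n_conformers)
  if (n_conformers < 1L) stop("'n_conformers' must be >= 1")
  if (is.null(sites)) sites <- seq_len(n)
  directions <- check_directions(directions)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))

  sweep_sites <- rep(sites, each = nrow(directions))
  sweep_dirs <- directions[rep(seq_len(nrow(directions)), length(sites)), ,
                           drop = FALSE]
  random_draw <- function() {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    list(site = sites[sample.int(length(sites), 1L)], dir = v)
  }
  displaced <- function(site, dir) {
    dr <- matrix(perturb(compliance, site, dir), ncol = 3L, byrow = TRUE)
    mags <- sqrt(rowSums(dr^2))
    if (max(mags) == 0) return(NULL)
    model$coords + (amplitude / max(mags)) * dr
  }
  out <- vector("list", n_conformers)
  out[[1L]] <- model
  k <- 2L; sweep_pos <- 1L
  while (k <= n_conformers) {
    if (sweep_pos <= length(sweep_sites)) {
      site <- sweep_sites[sweep_pos]
      dir <- sweep_dirs[sweep_pos, ]
      sweep_pos <- sweep_pos + 1L
    } else {
      draw <- random_draw(); site <- draw$site; dir <- draw$dir
    }
    xyz <- displaced(site, dir)
    if (is.null(xyz)) next
    if (min(stats::dist(xyz)) < min_clash) {
      warning("conformer rejected: C-alpha clash below ", min_clash,
              " A; drawing replacement")
      ok <- FALSE
      for (try in seq_len(200L)) {
        draw <- random_draw()
        xyz <- displaced(draw$site, draw$dir)
        if (!is.null(xyz) && min(stats::dist(xyz)) >= min_clash) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("could not draw a clash-free conformer after 200 attempts; ",
             "reduce 'amplitude'")
    }
    m2 <- model
    m2$coords <- xyz
    m2$source_label <- sprintf("%s|conf%03d", model$source_label, k - 1L)
    out[[k]] <- m2
    k <- k + 1L
  }
  out
}

#' Simulate conformers from a PRS fit
#'
#' `simulate()` on a [prs()] object draws a perturbation-displaced
#' conformer ensemble (see [generate_conformers()]).
#'
#' @param object a [prs()] fit.
#' @param nsim number of conformers (including the unperturbed model).
#' @param seed integer seed.
#' @param amplitude maximum per-residue displacement in Angstrom.
#' @param ... passed on to [generate_conformers()].
#' @return list of `calpha_model`s.
#' @export
simulate.prs <- function(object, nsim = 50L, seed = 1L, amplitude = 2.0,
                         ...) {
  generate_conformers(object$model, object$compliance,
                      amplitude = amplitude, n_conformers = nsim,
                      seed = if (is.null(seed)) 1L else seed, ...)
}
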