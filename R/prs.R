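#' Canonical perturbation direction set
#'
#' The seven canonical force directions used when scanning: the three
#' Cartesian axes, the three face diagonals and the body diagonal, each
#' normalized to unit length.  Predictions are insensitive to the precise
#' direction set; [random_directions()] provides an alternative for
#' robustness checks.
#'
#' @return matrix with one unit 3-vector per row, rownames = labels.
#' @export
prs_directions <- function() {
  d <- rbind(x   = c(1, 0, 0),
             y   = c(0, 1, 0),
             z   = c(0, 0, 1),
             xy  = c(1, 1, 0),
             xz  = c(1, 0, 1),
             yz  = c(0, 1, 1),
             xyz = c(1, 1, 1))
  d / sqrt(rowSums(d^2))
}

#' Random unit direction set
#' @param n number of directions.
#' @param seed integer seed (RNG state restored on exit).
#' @return matrix of `n` unit 3-vectors (rows), labelled `r1..rn`.
#' @export
random_directions <- function(n, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  rownames(v) <- paste0("r", seq_len(n))
  colnames(v) <- c("x", "y", "z")
  v
}

check_directions <- function(directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be 3-vectors (rows)")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("direction vectors must be unit length (max |norm-1| = ",
         format(max(abs(nrm - 1))), ")")
  if (is.null(rownames(directions)))
    rownames(directions) <- paste0("d", seq_len(nrow(directions)))
  directions
}

#' Displacement response to a directed force on one residue
#'
#' Linear response: `dR = C dF`, where `dF` is zero except for the three
#' components of the perturbed residue, which carry the force vector.  The
#' response is linear in the force magnitude; rigid-body content is absent
#' because the compliance has the null modes projected out.
#'
#' @param compliance an [compute_compliance()] result.
#' @param residue_index 1-based node index of the perturbed residue.
#' @param direction force 3-vector (unit length for the canonical scan, but
#'   any magnitude is accepted and scales the response linearly).
#' @return numeric displacement vector of length 3N.
#' @export
perturb <- function(compliance, residue_index, direction) {
  stopifnot(inherits(compliance, "enm_compliance"))
  n <- nrow(compliance$matrix) / 3L
  residue_index <- as.integer(residue_index)
  if (length(residue_index) != 1L || is.na(residue_index) ||
      residue_index < 1L || residue_index > n)
    stop("residue index out of range [1, ", n, "]")
  direction <- as.numeric(direction)
  stopifnot(length(direction) == 3L)
  cols <- (3L * residue_index - 2L):(3L * residue_index)
  drop(compliance$matrix[, cols] %*% direction)
}

#' Perturbation response scan
#'
#' Sequentially applies each direction as a unit force on every residue and
#' records, per direction, the N x N response matrix `A`: row i = perturbed
#' residue, column j = response of residue j.  By default `A_ij` is the
#' squared magnitude of residue j's displacement 3-vector (mean-square
#' fluctuation response); `squared = FALSE` records the plain magnitude for
#' sensitivity checks.
#'
#' @param compliance an [compute_compliance()] result.
#' @param directions matrix of unit direction rows ([prs_directions()] by
#'   default).
#' @param squared logical: square the displacement magnitude (default TRUE).
#' @return object of class `prs_responses`: a named list of N x N matrices
#'   (one per direction) with attributes `squared` and `directions`.
#' @export
prs_scan <- function(compliance, directions = prs_directions(),
                     squared = TRUE) {
  stopifnot(inherits(compliance, "enm_compliance"))
  directions <- check_directions(directions)
  cmat <- compliance$matrix
  n <- nrow(cmat) / 3L
  i1 <- seq(1L, 3L * n, by = 3L)
  cx <- cmat[, i1]; cy <- cmat[, i1 + 1L]; cz <- cmat[, i1 + 2L]
  out <- vector("list", nrow(directions))
  names(out) <- rownames(directions)
  for (d in seq_len(nrow(directions))) {
    v <- directions[d, ]
    # column i = full 3N response to a unit force v on residue i
    resp <- cx * v[1] + cy * v[2] + cz * v[3]
    a2 <- resp[i1, ]^2 + resp[i1 + 1L, ]^2 + resp[i1 + 2L, ]^2
    out[[d]] <- if (squared) t(a2) else t(sqrt(a2))
  }
  structure(out, squared = squared, directions = directions,
            class = "prs_responses")
}

#' Allosteric response ratio
#'
#' For each direction d, `chi_j^(d)` is the mean response of residue j to
#' perturbations at binding-pocket residues divided by its mean response to
#' perturbations at all residues; the reported `chi_j` is the maximum over
#' directions (the default) or the ratio of direction-averaged responses
#' (`aggregate = "mean"`).  With the pocket equal to the full residue set
#' the ratio is identically 1, which is the built-in normalization check.
#'
#' @param responses a [prs_scan()] result.
#' @param pocket a [binding_pocket()] (or integer node indices) resolved
#'   against the same model.
#' @param model optional [calpha_model()] used to label residues in the
#'   output (and to validate the pocket).
#' @param aggregate `"max"` (default) or `"mean"` across directions.
#' @return object of class `chi_profile`: a data.frame with columns
#'   `chain`, `resno`, `resid`, `chi` and one `chi.<direction>` column per
#'   direction; the pocket indices are attached as attribute `pocket`.
#' @export
allosteric_response_ratio <- function(responses, pocket, model = NULL,
                                      aggregate = c("max", "mean")) {
  stopifnot(inherits(responses, "prs_responses"))
  aggregate <- match.arg(aggregate)
  idx <- if (inherits(pocket, "binding_pocket")) pocket$indices
         else as.integer(pocket)
  n <- ncol(responses[[1L]])
  if (length(idx) == 0L) stop("empty binding pocket")
  if (any(idx < 1L | idx > n)) stop("pocket indices out of range")
  per_dir <- sapply(responses, function(a) {
    num <- colMeans(a[idx, , drop = FALSE])
    den <- colMeans(a)
    if (any(den <= 0)) {
      bad <- which(den <= 0)[1L]
      stop("zero total response for residue index ", bad,
           ": cannot form response ratio")
    }
    num / den
  })
  chi <- if (aggregate == "max") apply(per_dir, 1L, max)
         else {
    num <- Reduce(`+`, lapply(responses, function(a)
      colMeans(a[idx, , drop = FALSE])))
    den <- Reduce(`+`, lapply(responses, colMeans))
    num / den
  }
  prof <- data.frame(
    chain = if (is.null(model)) "A" else model$chain,
    resno = if (is.null(model)) seq_len(n) else model$resno,
    resid = if (is.null(model)) NA_character_ else model$resid,
    chi = chi, stringsAsFactors = FALSE)
  colnames(per_dir) <- paste0("chi.", colnames(per_dir))
  prof <- cbind(prof, as.data.frame(per_dir))
  rownames(prof) <- NULL
  structure(prof, pocket = idx, aggregate = aggregate,
            class = c("chi_profile", "data.frame"))
}

#' Select hot residues from a chi profile
#'
#' Residues whose allosteric response ratio exceeds the threshold, in
#' descending chi order and reported in author numbering.
#'
#' @param chi a `chi_profile` (from [allosteric_response_ratio()]).
#' @param threshold ratio cutoff (default 1.0).
#' @return data.frame of the selected rows, ordered by decreasing `chi`.
#' @export
select_hot_residues <- function(chi, threshold = 1.0) {
  stopifnot(inherits(chi, "chi_profile"), threshold > 0)
  hot <- chi[chi$chi > threshold, , drop = FALSE]
  hot <- hot[order(-hot$chi), , drop = FALSE]
  rownames(hot) <- NULL
  class(hot) <- "data.frame"
  hot
}

#' Fit a perturbation-response-scanning model
#'
#' The top-level analysis: builds the cutoff-free distance-weighted elastic
#' network for the C-alpha trace, inverts it (pseudo-inverse), scans
#' directed unit forces over all residues and directions, and computes the
#' allosteric response ratio of every residue with respect to the supplied
#' binding pocket.
#'
#' @param structure a [calpha_model()] or the path to a PDB file.
#' @param pocket binding-pocket specification: a string of author-numbered
#'   ranges such as `"320-328,371-380"`, an integer vector of author residue
#'   numbers, or a [binding_pocket()].
#' @param chain chain selector passed to [read_calpha()] when `structure`
#'   is a file path.
#' @param threshold chi cutoff for hot-residue selection (default 1.0).
#' @param params [enm_params()].
#' @param directions matrix of unit force directions (default the 7
#'   canonical directions, [prs_directions()]).
#' @param squared use squared displacement magnitudes (default TRUE).
#' @param aggregate chi aggregation across directions (`"max"` default).
#' @param pinv_tolerance relative eigenvalue cutoff for the pseudo-inverse.
#' @return an object of class `prs` with components `model`, `pocket`,
#'   `params`, `compliance`, `responses`, `chi` (a `chi_profile`), `hot`
#'   (hot-residue table at `threshold`) and `threshold`.  Methods:
#'   [print.prs()], [summary.prs()], [coef.prs()] (chi vector),
#'   [plot.prs()] (chi profile), [simulate.prs()] (conformer ensemble).
#' @seealso [prs_pathway()] for the signalling-pathway construction.
#' @export
#' @examples
#' fit <- prs(make_fixture("ideal_helix", 25), pocket = "1-4")
#' head(coef(fit))
prs <- function(structure, pocket, chain = NULL, threshold = 1.0,
                params = enm_params(), directions = prs_directions(),
                squared = TRUE, aggregate = c("max", "mean"),
                pinv_tolerance = 1e-8) {
  cl <- match.call()
  aggregate <- match.arg(aggregate)
  model <- if (inherits(structure, "calpha_model")) structure
           else read_calpha(structure, chain = chain)
  bp <- if (inherits(pocket, "binding_pocket")) pocket
        else parse_pocket_spec(pocket, model)
  h <- build_hessian(model, params)
  comp <- compute_compliance(h, tolerance = pinv_tolerance)
  resp <- prs_scan(comp, directions = directions, squared = squared)
  chi <- allosteric_response_ratio(resp, bp, model = model,
                                   aggregate = aggregate)
  fit <- structure(
    list(model = model, pocket = bp, params = params, compliance = comp,
         responses = resp, chi = chi,
         hot = select_hot_residues(chi, threshold),
         threshold = threshold, call = cl),
    class = "prs")
  fit
}

#' @export
print.prs <- function(x, ...) {
  cat("Perturbation response scan of '", x$model$source_label, "'\n",
      sep = "")
  cat("  residues: ", n_residues(x$model),
      "; pocket: ", length(x$pocket$indices), " residues (",
      x$pocket$spec, ")\n", sep = "")
  cat("  directions: ", length(x$responses),
      "; null modes dropped: ", x$compliance$dropped_modes, "\n", sep = "")
  cat("  hot residues (chi > ", format(x$threshold), "): ",
      nrow(x$hot), "\n", sep = "")
  invisible(x)
}

#' @rdname print.prs
#' @param object,x a `prs` fit.
#' @param ... unused.
#' @export
summary.prs <- function(object, ...) {
  hot <- object$hot
  structure(list(
    source = object$model$source_label,
    n = n_residues(object$model),
    pocket = object$pocket,
    threshold = object$threshold,
    chi_range = range(object$chi$chi),
    hot = hot), class = "summary.prs")
}

#' @export
print.summary.prs <- function(x, ...) {
  cat("PRS fit: ", x$source, " (", x$n, " residues)\n", sep = "")
  cat("Binding pocket: ", x$pocket$spec, " (",
      length(x$pocket$indices), " residues)\n", sep = "")
  cat("chi range: [", format(x$chi_range[1], digits = 4), ", ",
      format(x$chi_range[2], digits = 4), "]\n", sep = "")
  cat("Hot residues (chi > ", format(x$threshold), "):\n", sep = "")
  if (nrow(x$hot) == 0L) cat("  none\n") else
    print(x$hot[, c("chain", "resno", "resid", "chi")], row.names = FALSE)
  invisible(x)
}

#' @rdname prs
#' @param object a `prs` fit.
#' @param ... unused.
#' @export
coef.prs <- function(object, ...) {
  stats::setNames(object$chi$chi,
                  paste0(object$chi$chain, ":", object$chi$resno))
}

#' Plot the allosteric response ratio profile
#'
#' Chi against author residue number, with the selection threshold as a
#' horizontal line and binding-pocket residues tick-marked on the axis.
#'
#' @param x a `prs` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.prs <- function(x, ...) {
  chi <- x$chi
  graphics::plot(chi$resno, chi$chi, type = "l", xlab = "residue",
                 ylab = expression(chi), ...)
  graphics::abline(h = x$threshold, lty = 2, col = "grey40")
  graphics::points(chi$resno[chi$chi > x$threshold],
                   chi$chi[chi$chi > x$threshold], pch = 19, col = "red3")
  graphics::rug(x$model$resno[x$pocket$indices], col = "blue3")
  invisible(x)
}
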