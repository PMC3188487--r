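#' Dominant response directions under pocket perturbation
#'
#' For each candidate residue k and each binding-pocket residue i, the 3x3
#' block of the compliance coupling k to i is decomposed by singular value
#' decomposition; the left singular vector of the largest singular value is
#' the dominant direction in which k moves when i is pushed.  A residue
#' pair that moves "in line" shares (up to sign) its dominant direction
#' across the pocket perturbations.  Signs of singular vectors are
#' arbitrary; vectors are canonicalized so their first nonzero component is
#' positive.
#'
#' @param compliance an [compute_compliance()] result.
#' @param residues integer node indices of the candidate residues.
#' @param pocket a [binding_pocket()] or integer node indices.
#' @return object of class `directional_response`: `vectors`, an array
#'   `[candidate, pocket, 3]` of unit dominant directions; `spectra`, an
#'   array `[candidate, pocket, 3]` of descending singular values;
#'   `residues` and `pocket` index vectors.  All-zero blocks yield an `NA`
#'   direction (flagged "no response").
#' @export
dominant_directions <- function(compliance, residues, pocket) {
  stopifnot(inherits(compliance, "enm_compliance"))
  cmat <- compliance$matrix
  n <- nrow(cmat) / 3L
  residues <- as.integer(residues)
  pk <- if (inherits(pocket, "binding_pocket")) pocket$indices
        else as.integer(pocket)
  if (any(c(residues, pk) < 1L) || any(c(residues, pk) > n))
    stop("node index out of range")
  vecs <- array(NA_real_, c(length(residues), length(pk), 3L))
  spec <- array(NA_real_, c(length(residues), length(pk), 3L))
  for (a in seq_along(residues)) {
    k <- residues[a]
    rk <- (3L * k - 2L):(3L * k)
    for (b in seq_along(pk)) {
      i <- pk[b]
      blk <- cmat[rk, (3L * i - 2L):(3L * i), drop = FALSE]
      if (max(abs(blk)) == 0) next  # no response; stays NA
      sv <- svd(blk)
      u <- sv$u[, 1L]
      nz <- which(abs(u) > 1e-12)[1L]
      if (!is.na(nz) && u[nz] < 0) u <- -u
      vecs[a, b, ] <- u
      spec[a, b, ] <- sv$d
    }
  }
  structure(list(vectors = vecs, spectra = spec,
                 residues = residues, pocket = pk),
            class = "directional_response")
}

#' Overlap coefficient of two response directions
#'
#' The absolute cosine of the angle between two unit vectors.  The absolute
#' value makes the measure insensitive to the arbitrary sign of singular
#' vectors: antiparallel motion counts as collinear.
#'
#' @param v1,v2 unit 3-vectors.
#' @return scalar in `[0, 1]`.
#' @export
overlap_coefficient <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  stopifnot(length(v1) == 3L, length(v2) == 3L)
  if (abs(sum(v1^2) - 1) > 1e-8 || abs(sum(v2^2) - 1) > 1e-8)
    stop("overlap_coefficient expects unit vectors")
  min(1, abs(sum(v1 * v2)))
}

#' Expand hot residues by a sequence window
#'
#' Each hot residue contributes itself and its `(window - 1) / 2` sequence
#' neighbours on either side (author numbering, same chain), keeping only
#' residues present in the model.  The default window of 3 turns a hot
#' residue `r` into `{r - 1, r, r + 1}`.
#'
#' @param hot integer vector of hot author residue numbers (or a hot-residue
#'   data.frame from [select_hot_residues()]).
#' @param model a [calpha_model()].
#' @param window odd integer >= 1.
#' @return sorted integer vector of candidate node indices.
#' @export
candidate_set <- function(hot, model, window = 3L) {
  stopifnot(inherits(model, "calpha_model"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("'window' must be odd, >= 1")
  if (is.data.frame(hot)) hot <- hot$resno
  hot <- as.integer(hot)
  half <- (window - 1L) %/% 2L
  wanted <- unique(as.vector(outer(hot, (-half):half, "+")))
  sort(which(model$resno %in% wanted))
}

#' Build the sequence-ordered overlap graph
#'
#' For every candidate pair a < b (sequence order) the pair overlap is the
#' mean over binding-pocket perturbation sites of the overlap coefficient
#' between the two residues' dominant directions (`combine = "max"` takes
#' the maximum across sites instead).  An edge is kept when the pair
#' overlap reaches `cutoff`; edges always point from the earlier to the
#' later residue, so the graph is a DAG.
#'
#' @param candidates integer node indices (see [candidate_set()]).
#' @param directional a [dominant_directions()] result covering
#'   `candidates` (its `residues` field must contain them).
#' @param cutoff minimum pair overlap (default 0.98).
#' @param combine `"mean"` (default) or `"max"` across pocket sites.
#' @param model optional [calpha_model()] to attach author numbering.
#' @return object of class `overlap_graph`: `nodes` (indices), `resno`,
#'   `edges` data.frame (`from`, `to` as node indices; `weight`), `cutoff`.
#' @export
build_overlap_graph <- function(candidates, directional, cutoff = 0.98,
                                combine = c("mean", "max"), model = NULL) {
  stopifnot(inherits(directional, "directional_response"))
  combine <- match.arg(combine)
  candidates <- sort(as.integer(candidates))
  pos <- match(candidates, directional$residues)
  if (anyNA(pos))
    stop("directional responses missing for some candidates")
  nc <- length(candidates)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  if (nc >= 2L) for (a in seq_len(nc - 1L)) for (b in (a + 1L):nc) {
    va <- directional$vectors[pos[a], , , drop = FALSE]
    vb <- directional$vectors[pos[b], , , drop = FALSE]
    ov <- vapply(seq_len(dim(va)[2L]), function(s) {
      u1 <- va[1L, s, ]; u2 <- vb[1L, s, ]
      if (anyNA(u1) || anyNA(u2)) return(NA_real_)
      overlap_coefficient(u1, u2)
    }, numeric(1L))
    ov <- ov[!is.na(ov)]
    if (length(ov) == 0L) next
    pw <- if (combine == "mean") mean(ov) else max(ov)
    if (pw >= cutoff) {
      from <- c(from, candidates[a]); to <- c(to, candidates[b])
      w <- c(w, pw)
    }
  }
  resno <- if (!is.null(model)) model$resno[candidates] else candidates
  structure(list(nodes = candidates, resno = resno,
                 edges = data.frame(from = from, to = to, weight = w),
                 cutoff = cutoff, model = model),
            class = "overlap_graph")
}

#' Maximum-weight signalling pathway
#'
#' Among all maximal sequence-monotone pathways of the overlap graph (paths
#' that start at a node with no incoming edge and end at a node with no
#' outgoing edge, so no further link can be prepended or appended), selects
#' the one with the largest product of edge overlaps.  Exact dynamic
#' programming over increasing sequence position, equivalent to exhaustive
#' enumeration.  Ties are broken in favour of more residues, then of the
#' smaller start residue.
#'
#' @param g an [build_overlap_graph()] result.
#' @return object of class `prs_pathway`: `residues` (author numbers),
#'   `indices` (node indices), `edge_overlaps`, `total_weight`.  A graph
#'   without edges yields a single-node pathway of weight 1 with a warning.
#' @export
max_weight_pathway <- function(g) {
  stopifnot(inherits(g, "overlap_graph"))
  nodes <- g$nodes
  if (length(nodes) == 0L) stop("empty overlap graph")
  resno_of <- function(idx) g$resno[match(idx, nodes)]
  if (nrow(g$edges) == 0L) {
    warning("no edges above cutoff; returning single-node pathway")
    return(structure(list(residues = resno_of(nodes[1L]),
                          indices = nodes[1L], edge_overlaps = numeric(0),
                          total_weight = 1), class = "prs_pathway"))
  }
  e <- g$edges[order(g$edges$to, g$edges$from), , drop = FALSE]
  has_in  <- nodes %in% e$to
  has_out <- nodes %in% e$from
  best_w <- rep(NA_real_, length(nodes))       # best product ending here
  best_len <- rep(NA_integer_, length(nodes))
  best_prev <- rep(NA_integer_, length(nodes)) # predecessor node index
  best_edge <- rep(NA_real_, length(nodes))
  best_w[!has_in] <- 1; best_len[!has_in] <- 1L
  ord <- order(nodes)
  for (v_i in ord) {
    v <- nodes[v_i]
    ein <- e[e$to == v, , drop = FALSE]
    if (nrow(ein) == 0L) next
    for (r in seq_len(nrow(ein))) {
      u_i <- match(ein$from[r], nodes)
      if (is.na(best_w[u_i])) next
      cand_w <- best_w[u_i] * ein$weight[r]
      cand_len <- best_len[u_i] + 1L
      better <- is.na(best_w[v_i]) ||
        cand_w > best_w[v_i] + 1e-12 ||
        (abs(cand_w - best_w[v_i]) <= 1e-12 &&
           (cand_len > best_len[v_i] ||
              (cand_len == best_len[v_i] &&
                 path_start(best_prev, best_edge, nodes, u_i) <
                   path_start(best_prev, best_edge, nodes, v_i))))
      if (better) {
        best_w[v_i] <- cand_w; best_len[v_i] <- cand_len
        best_prev[v_i] <- u_i; best_edge[v_i] <- ein$weight[r]
      }
    }
  }
  sinks <- which(!has_out & has_in & !is.na(best_w))
  pick <- sinks[1L]
  for (s in sinks[-1L]) {
    if (best_w[s] > best_w[pick] + 1e-12 ||
        (abs(best_w[s] - best_w[pick]) <= 1e-12 &&
           (best_len[s] > best_len[pick] ||
              (best_len[s] == best_len[pick] &&
                 path_start(best_prev, best_edge, nodes, s) <
                   path_start(best_prev, best_edge, nodes, pick)))))
      pick <- s
  }
  idx_path <- integer(0); ovl <- numeric(0); cur <- pick
  while (!is.na(cur)) {
    idx_path <- c(nodes[cur], idx_path)
    if (!is.na(best_edge[cur]) && !is.na(best_prev[cur]))
      ovl <- c(best_edge[cur], ovl)
    cur <- best_prev[cur]
  }
  structure(list(residues = resno_of(idx_path), indices = idx_path,
                 edge_overlaps = ovl, total_weight = prod(ovl)),
            class = "prs_pathway")
}

# start node (sequence position) of the best path ending at position i
path_start <- function(best_prev, best_edge, nodes, i) {
  while (!is.na(best_prev[i])) i <- best_prev[i]
  nodes[i]
}

#' @export
print.prs_pathway <- function(x, ...) {
  cat("Signalling pathway (", length(x$residues), " residues), total weight ",
      format(x$total_weight, digits = 4), "\n  ", sep = "")
  cat(paste(x$residues, collapse = " -> "), "\n")
  if (length(x$edge_overlaps))
    cat("  edge overlaps: ",
        paste(format(x$edge_overlaps, digits = 4), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Construct the allosteric pathway from a PRS fit
#'
#' Convenience wrapper chaining [candidate_set()], [dominant_directions()],
#' [build_overlap_graph()] and [max_weight_pathway()] on a fitted [prs()]
#' object: hot residues are expanded by the sequence window, each
#' candidate's dominant response direction per pocket perturbation is
#' extracted, pairs whose mean overlap reaches the cutoff are linked, and
#' the maximum-product maximal pathway is returned.
#'
#' @param fit a [prs()] object.
#' @param cutoff overlap-coefficient cutoff (default 0.98).
#' @param window sequence window around hot residues (default 3).
#' @param combine pocket-site aggregation for pair overlaps (`"mean"`).
#' @param threshold chi threshold; defaults to the fit's.
#' @return a `prs_pathway` with the `overlap_graph` attached as attribute
#'   `graph`.
#' @export
prs_pathway <- function(fit, cutoff = 0.98, window = 3L,
                        combine = c("mean", "max"), threshold = NULL) {
  stopifnot(inherits(fit, "prs"))
  combine <- match.arg(combine)
  hot <- if (is.null(threshold)) fit$hot
         else select_hot_residues(fit$chi, threshold)
  if (nrow(hot) == 0L) stop("no hot residues at this threshold")
  cand <- candidate_set(hot$resno, fit$model, window = window)
  dirs <- dominant_directions(fit$compliance, cand, fit$pocket)
  g <- build_overlap_graph(cand, dirs, cutoff = cutoff, combine = combine,
                           model = fit$model)
  pw <- max_weight_pathway(g)
  attr(pw, "graph") <- g
  pw
}
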