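# Independent oracles used across the suite.  These deliberately avoid the
# package's computational paths: enumeration, closed forms, and alternative
# algorithms only.

# --- exhaustive hypergeometric two-sided Fisher p (probability-mass rule) ---
fisher_oracle <- function(a, b, c_, d,
                          alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  m1 <- a + b; m2 <- c_ + d; n1 <- a + c_; n <- m1 + m2
  lo <- max(0L, n1 - m2); hi <- min(n1, m1)
  av <- lo:hi
  logp <- lchoose(m1, av) + lchoose(m2, n1 - av) - lchoose(n, n1)
  p <- exp(logp)
  obs <- p[av == a]
  if (alternative == "greater") sum(p[av >= a])
  else sum(p[p <= obs * (1 + 1e-7)])
}

# --- quaternion (Horn) absolute-orientation superposition + RMSD ---
quaternion_rmsd <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  m <- crossprod(b0, a0)   # sum over points of b_i a_i^T
  sxx <- m[1, 1]; sxy <- m[1, 2]; sxz <- m[1, 3]
  syx <- m[2, 1]; syy <- m[2, 2]; syz <- m[2, 3]
  szx <- m[3, 1]; szy <- m[3, 2]; szz <- m[3, 3]
  k <- matrix(c(
    sxx + syy + szz, syz - szy,       szx - sxz,       sxy - syx,
    syz - szy,       sxx - syy - szz, sxy + syx,       szx + sxz,
    szx - sxz,       sxy + syx,       syy - sxx - szz, syz + szy,
    sxy - syx,       szx + sxz,       syz + szy,       szz - sxx - syy),
    4, 4, byrow = TRUE)
  q <- eigen(k, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rot <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  fitted <- b0 %*% t(rot)
  sqrt(mean(rowSums((fitted - a0)^2)))
}

# --- maximal-path enumeration on a sequence DAG -----------------------------
# edges: data.frame(from, to, weight) with from < to.  Enumerates every
# maximal monotone path (start has no in-edge, end has no out-edge) and
# returns the best by (product weight, then length, then smaller start).
brute_force_best_path <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(NULL)
  has_in <- nodes %in% edges$to
  has_out <- nodes %in% edges$from
  best <- NULL
  consider <- function(path, w) {
    if (is.null(best) || w > best$w + 1e-12 ||
        (abs(w - best$w) <= 1e-12 &&
           (length(path) > length(best$path) ||
              (length(path) == length(best$path) &&
                 path[1] < best$path[1]))))
      best <<- list(path = path, w = w)
  }
  walk <- function(path, w) {
    out <- edges[edges$from == path[length(path)], , drop = FALSE]
    if (nrow(out) == 0L) { consider(path, w); return(invisible()) }
    for (r in seq_len(nrow(out)))
      walk(c(path, out$to[r]), w * out$weight[r])
  }
  for (s in nodes[!has_in & has_out]) walk(s, 1)
  best
}

random_dag <- function(n, p = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- sort(sample(1:(3 * n), n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  edges <- data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                      weight = runif(sum(keep), 0.2, 1))
  structure(list(nodes = nodes, resno = nodes, edges = edges,
                 cutoff = 0, model = NULL), class = "overlap_graph")
}

# --- misc helpers -----------------------------------------------------------
rigid_motion <- function(coords, seed = 1) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), -sin(ang[1]),
                 0, sin(ang[1]), cos(ang[1])), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(ang[2]), 0, sin(ang[2]), 0, 1, 0,
                 -sin(ang[2]), 0, cos(ang[2])), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(ang[3]), -sin(ang[3]), 0, sin(ang[3]), cos(ang[3]),
                 0, 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(coords %*% t(rx %*% ry %*% rz), 2, runif(3, -20, 20), "+")
}

write_pdb_lines <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# standard well-posed 3D fixtures used in several files
fixture_models <- function() {
  list(helix = make_fixture("ideal_helix", 20),
       cloud = make_fixture("random_cloud", 10, seed = 7))
}
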