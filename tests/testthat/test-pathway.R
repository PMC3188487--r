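test_that("dominant response direction of a two-node spring is the bond axis", {
  m <- make_fixture("two_mass")
  cc <- suppressWarnings(compute_compliance(build_hessian(m)))
  dd <- dominant_directions(cc, residues = 1:2, pocket = 1L)
  for (k in 1:2)
    expect_equal(abs(dd$vectors[k, 1, ]), c(1, 0, 0), tolerance = 1e-10)
  # canonical sign: first nonzero component positive
  expect_gt(dd$vectors[1, 1, 1], 0)
})

test_that("dominant directions match a direct SVD of the extracted blocks", {
  for (m in list(make_fixture("ideal_helix", 9),
                 make_fixture("linear_chain", 5))) {
    cc <- suppressWarnings(compute_compliance(build_hessian(m)))
    cand <- seq_len(n_residues(m))
    pocket <- c(1L, 2L)
    dd <- dominant_directions(cc, cand, pocket)
    for (k in cand) for (b in seq_along(pocket)) {
      i <- pocket[b]
      blk <- cc$matrix[(3 * k - 2):(3 * k), (3 * i - 2):(3 * i)]
      if (max(abs(blk)) == 0) { expect_true(anyNA(dd$vectors[k, b, ])); next }
      sv <- svd(blk)
      u <- sv$u[, 1]
      u <- u * sign(u[which(abs(u) > 1e-12)[1]])
      expect_equal(dd$vectors[k, b, ], u, tolerance = 1e-9)
      expect_equal(dd$spectra[k, b, ], sv$d, tolerance = 1e-12)
      expect_true(all(diff(dd$spectra[k, b, ]) <= 1e-12))  # descending
    }
  }
})

test_that("self blocks of the compliance are positive semidefinite", {
  m <- make_fixture("random_cloud", 8, seed = 5)
  cc <- compute_compliance(build_hessian(m))
  for (k in c(1L, 4L, 8L)) {
    blk <- cc$matrix[(3 * k - 2):(3 * k), (3 * k - 2):(3 * k)]
    expect_gte(min(eigen(blk, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("overlap coefficient is the sign-free cosine", {
  v <- c(1, 0, 0)
  expect_equal(overlap_coefficient(v, v), 1.0)
  expect_equal(overlap_coefficient(v, c(0, 1, 0)), 0.0)
  expect_equal(overlap_coefficient(v, -v), 1.0)
  w1 <- c(1, 2, -1) / sqrt(6); w2 <- c(0, 1, 1) / sqrt(2)
  expect_equal(overlap_coefficient(w1, w2), overlap_coefficient(w2, w1))
  expect_error(overlap_coefficient(c(1, 1, 0), v), "unit")
})

test_that("candidate sets expand hot residues by the sequence window", {
  m <- make_fixture("ideal_helix", 30)
  m$resno <- 301:330
  expect_equal(m$resno[candidate_set(320, m, window = 3)], 319:321)
  expect_equal(m$resno[candidate_set(c(305, 306), m, window = 3)], 304:307)
  # chain terminus: only residues that exist
  expect_equal(m$resno[candidate_set(301, m, window = 3)], 301:302)
  # window 1 is the hot set itself
  expect_equal(m$resno[candidate_set(c(310, 315), m, window = 1)],
               c(310L, 315L))
  expect_error(candidate_set(310, m, window = 2), "odd")
})

test_that("overlap graph honours the cutoff at its extremes", {
  m <- make_fixture("ideal_helix", 10)
  cc <- compute_compliance(build_hessian(m))
  cand <- 1:6
  dd <- dominant_directions(cc, cand, pocket = c(1L, 2L))
  g0 <- build_overlap_graph(cand, dd, cutoff = 0, model = m)
  expect_equal(nrow(g0$edges), choose(6, 2))
  expect_true(all(g0$edges$from < g0$edges$to))
  g2 <- build_overlap_graph(cand, dd, cutoff = 1.0000001, model = m)
  expect_equal(nrow(g2$edges), 0L)
  expect_true(all(g0$edges$weight >= 0 & g0$edges$weight <= 1))
})

test_that("printed-factor chain gives the product weight through the DP", {
  g <- structure(list(
    nodes = c(314L, 327L, 338L), resno = c(314L, 327L, 338L),
    edges = data.frame(from = c(314L, 327L), to = c(327L, 338L),
                       weight = c(0.99, 0.98)),
    cutoff = 0.98, model = NULL), class = "overlap_graph")
  pw <- max_weight_pathway(g)
  expect_equal(pw$residues, c(314L, 327L, 338L))
  expect_equal(pw$edge_overlaps, c(0.99, 0.98))
  expect_equal(pw$total_weight, 0.99 * 0.98, tolerance = 1e-12)
})

test_that("a lone strong edge beats a longer weaker maximal path", {
  g <- structure(list(
    nodes = c(1L, 2L, 5L, 6L, 7L), resno = c(1L, 2L, 5L, 6L, 7L),
    edges = data.frame(from = c(1L, 5L, 6L), to = c(2L, 6L, 7L),
                       weight = c(0.99, 0.98, 0.98)),
    cutoff = 0, model = NULL), class = "overlap_graph")
  pw <- max_weight_pathway(g)
  expect_equal(pw$residues, c(1L, 2L))
  expect_equal(pw$total_weight, 0.99)
})

test_that("single edge graphs return that edge; empty graphs warn", {
  g1 <- structure(list(nodes = c(3L, 9L), resno = c(3L, 9L),
                       edges = data.frame(from = 3L, to = 9L, weight = 0.5),
                       cutoff = 0, model = NULL), class = "overlap_graph")
  expect_equal(max_weight_pathway(g1)$residues, c(3L, 9L))
  g0 <- structure(list(nodes = c(3L, 9L), resno = c(3L, 9L),
                       edges = data.frame(from = integer(0), to = integer(0),
                                          weight = numeric(0)),
                       cutoff = 0.98, model = NULL), class = "overlap_graph")
  expect_warning(pw <- max_weight_pathway(g0), "no edges")
  expect_equal(pw$total_weight, 1)
  expect_equal(length(pw$residues), 1L)
})

test_that("dynamic programming equals exhaustive enumeration on random DAGs", {
  set.seed(42)
  for (rep in 1:60) {
    g <- random_dag(sample(3:10, 1), p = runif(1, 0.15, 0.6))
    ref <- brute_force_best_path(g$nodes, g$edges)
    if (is.null(ref)) {
      expect_warning(max_weight_pathway(g), "no edges")
      next
    }
    pw <- max_weight_pathway(g)
    expect_equal(pw$total_weight, ref$w, tolerance = 1e-12)
    expect_equal(pw$residues, ref$path)
  }
})

test_that("returned pathways are maximal and bounded by the strongest edge", {
  set.seed(7)
  for (rep in 1:20) {
    g <- random_dag(8, p = 0.5)
    if (nrow(g$edges) == 0) next
    pw <- max_weight_pathway(g)
    # maximal: nothing can be prepended or appended
    expect_false(pw$residues[1] %in% g$edges$to)
    expect_false(pw$residues[length(pw$residues)] %in% g$edges$from)
    # a product of weights in (0, 1] never exceeds its largest factor
    expect_lte(pw$total_weight, max(g$edges$weight) + 1e-12)
    expect_equal(pw$total_weight, prod(pw$edge_overlaps), tolerance = 1e-12)
  }
})

test_that("pathway construction from a fit is sequence-monotone", {
  m <- make_fixture("ideal_helix", 40)
  fit <- prs(m, pocket = "18-22")
  pw <- prs_pathway(fit, cutoff = 0.9)
  expect_s3_class(pw, "prs_pathway")
  expect_true(all(diff(pw$residues) > 0))
  expect_equal(pw$total_weight, prod(pw$edge_overlaps), tolerance = 1e-12)
  g <- attr(pw, "graph")
  expect_true(all(g$edges$weight >= 0.9))
})
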