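test_that("canonical direction set has 7 unit members", {
  d <- prs_directions()
  expect_equal(nrow(d), 7L)
  expect_equal(sqrt(rowSums(d^2)), rep(1, 7), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(d["xy", ]), c(1, 1, 0) / sqrt(2))
  expect_equal(unname(d["xyz", ]), c(1, 1, 1) / sqrt(3))
})

test_that("response is linear in the applied force", {
  m <- make_fixture("random_cloud", 7, seed = 1)
  cc <- compute_compliance(build_hessian(m))
  d1 <- perturb(cc, 3, c(0, 1, 0))
  d2 <- perturb(cc, 3, c(0, 2, 0))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # sign flip leaves magnitudes unchanged
  expect_equal(abs(perturb(cc, 3, c(0, -1, 0))), abs(d1), tolerance = 1e-12)
})

test_that("axial two-mass response matches the balanced-force closed form", {
  # a single-node force has its rigid translational part projected out,
  # leaving the balanced pair (+F/2, -F/2); spring extension = (F/2)/k
  m <- make_fixture("two_mass", spacing = 3.0)
  cc <- suppressWarnings(compute_compliance(build_hessian(m)))
  dr <- perturb(cc, 1, c(1, 0, 0))
  expect_equal(dr[1] - dr[4], 0.5, tolerance = 1e-10)
  expect_equal(dr[1], -dr[4], tolerance = 1e-10)   # zero net translation
  expect_equal(dr[c(2, 3, 5, 6)], rep(0, 4), tolerance = 1e-12)
  # ginv-based oracle agrees
  expect_equal(dr, analytic_response_oracle(m, 1, c(1, 0, 0)),
               tolerance = 1e-8)
})

test_that("in-plane forces on a planar fixture give no out-of-plane response", {
  m <- make_fixture("ring", 8)
  cc <- suppressWarnings(compute_compliance(build_hessian(m)))
  dr <- perturb(cc, 2, c(0, 1, 0))
  expect_lt(max(abs(dr[seq(3, length(dr), by = 3)])), 1e-10)
})

test_that("perturb validates its index", {
  m <- make_fixture("ideal_helix", 6)
  cc <- compute_compliance(build_hessian(m))
  expect_error(perturb(cc, 0, c(1, 0, 0)), "out of range")
  expect_error(perturb(cc, 7, c(1, 0, 0)), "out of range")
})

test_that("scan magnitudes match per-force dense solves", {
  for (m in list(make_fixture("ring", 3, spacing = 3),
                 make_fixture("random_cloud", 6, seed = 9))) {
    cc <- suppressWarnings(compute_compliance(build_hessian(m)))
    resp <- prs_scan(cc)
    n <- n_residues(m)
    for (dn in rownames(prs_directions())) {
      d <- prs_directions()[dn, ]
      for (i in seq_len(n)) {
        dr <- matrix(analytic_response_oracle(m, i, d), ncol = 3,
                     byrow = TRUE)
        expect_equal(resp[[dn]][i, ], unname(rowSums(dr^2)),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("self-response is positive and responses decay along a chain", {
  m <- make_fixture("linear_chain", 20)
  cc <- suppressWarnings(compute_compliance(build_hessian(m)))
  resp <- prs_scan(cc)
  a <- resp[["x"]]
  expect_true(all(diag(a) > 0))
  expect_true(all(a >= 0))
  # responses to perturbing residue 1 shrink with sequence separation in
  # the propagation region (the distal free end recoils slightly because
  # the rigid-translation content of the field is projected out, so the
  # decay is tested over the near half of the chain)
  expect_lt(cor(a[1, 1:8], 0:7, method = "spearman"), -0.99)
  expect_gt(a[1, 1] / a[1, 8], 100)
})

test_that("chi is identically 1 when the pocket is every residue", {
  for (m in fixture_models()) {
    fit <- prs(m, pocket = seq_len(n_residues(m)) , threshold = 1)
    expect_lt(max(abs(fit$chi$chi - 1)), 1e-10)
  }
})

test_that("uniform response rows give chi = 1 for a single-residue pocket", {
  fake <- structure(list(u = matrix(1, 10, 10)), class = "prs_responses")
  attr(fake, "squared") <- TRUE
  chi <- allosteric_response_ratio(fake, pocket = 1L)
  expect_equal(chi$chi, rep(1, 10), tolerance = 1e-12)
})

test_that("symmetric residues of a ring get equal chi under a symmetric pocket", {
  # the bonded springs follow sequence (1-2, ..., 7-8, but not 8-1), so the
  # mirror must map bonds to bonds: place the ring so that reflection in
  # the y = 0 plane maps node j to node 9 - j
  n <- 8
  radius <- 3.8 / (2 * sin(pi / n))
  theta <- 2 * pi * (seq_len(n) - 4.5) / n
  m <- calpha_model(cbind(radius * cos(theta), radius * sin(theta), 0),
                    resno = seq_len(n))
  dirs <- rbind(x = c(1, 0, 0), y = c(0, 1, 0))   # respect the mirror plane
  cc <- suppressWarnings(compute_compliance(build_hessian(m)))
  resp <- prs_scan(cc, directions = dirs)
  # pocket {1, 8} is itself mirror-symmetric
  chi <- allosteric_response_ratio(resp, pocket = c(1L, 8L), model = m)$chi
  for (j in 1:4) expect_equal(chi[j], chi[9 - j], tolerance = 1e-9)
})

test_that("hot-residue selection thresholds and orders correctly", {
  chi <- structure(
    data.frame(chain = "A", resno = 1:4, resid = "ALA",
               chi = c(2.0, 0.5, 1.2, 1.0)),
    class = c("chi_profile", "data.frame"))
  hot <- select_hot_residues(chi, 1.0)
  expect_equal(hot$resno, c(1L, 3L))     # descending chi; 1.0 is not > 1.0
  expect_equal(nrow(select_hot_residues(chi, 5)), 0L)
  expect_error(select_hot_residues(chi, 0), "threshold > 0")
})

test_that("empty or invalid pockets are rejected", {
  m <- make_fixture("ideal_helix", 8)
  cc <- compute_compliance(build_hessian(m))
  resp <- prs_scan(cc)
  expect_error(allosteric_response_ratio(resp, integer(0)), "empty")
  expect_error(allosteric_response_ratio(resp, 99L), "out of range")
})

test_that("hot sets are robust to replacing the 7 directions by 50 random ones", {
  m <- make_fixture("ideal_helix", 40)
  f7 <- prs(m, pocket = "18-22")
  f50 <- prs(m, pocket = "18-22", directions = random_directions(50, seed = 3))
  jac <- length(intersect(f7$hot$resno, f50$hot$resno)) /
    length(union(f7$hot$resno, f50$hot$resno))
  expect_gte(jac, 0.7)
  # nontrivial selection on both sides
  expect_gt(nrow(f7$hot), 0)
  expect_lt(nrow(f7$hot), n_residues(m))
})

test_that("prs object exposes coef, summary, plot and magnitude mode", {
  m <- make_fixture("ideal_helix", 15)
  fit <- prs(m, pocket = "1-3")
  expect_s3_class(fit, "prs")
  expect_named(coef(fit)[1], "A:1")
  expect_output(print(summary(fit)), "chi range")
  pf <- tempfile(fileext = ".pdf")
  grDevices::pdf(pf); plot(fit); grDevices::dev.off()
  expect_true(file.size(pf) > 0)
  fit_mag <- prs(m, pocket = "1-3", squared = FALSE)
  expect_false(isTRUE(all.equal(fit$chi$chi, fit_mag$chi$chi)))
})
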