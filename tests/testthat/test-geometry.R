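test_that("radii derive from best-fit diameters by halving, rejecting bad input", {
  expect_equal(radius_from_diameter(2.78), 1.39)
  expect_equal(radius_from_diameter(2.0), 1.0)
  expect_error(radius_from_diameter(0), "positive")
  expect_error(radius_from_diameter(-1), "positive")
})

test_that("canonical branch ordering puts the larger branch first and keeps angle pairing", {
  sw <- canonicalize(0.84, 1.16, beta_raw = 97.6, gamma_raw = 121.5,
                     p_a = 2.3, p_b = 4.3)
  expect_true(sw$swapped)
  expect_equal(sw$r1, 1.16)
  expect_equal(sw$r2, 0.84)
  expect_equal(sw$beta_deg, 121.5)   # beta follows the larger branch
  expect_equal(sw$gamma_deg, 97.6)
  expect_equal(sw$p1, 4.3)

  keep <- canonicalize(1.16, 0.84, 121.5, 97.6)
  expect_false(keep$swapped)
  expect_equal(keep$r1, 1.16)

  tie <- canonicalize(1.0, 1.0, 110, 100)
  expect_false(tie$swapped)          # exact tie preserves input order
  expect_equal(tie$beta_deg, 110)

  expect_error(canonicalize(-1, 1), "positive")
})

test_that("asymmetry and area ratios match hand arithmetic and symmetry limits", {
  r <- bifurcation_ratios(1.39, 1.16, 0.84)
  expect_equal(r$asymmetry_ratio, 0.84^2 / 1.16^2)
  expect_equal(r$asymmetry_ratio, 0.5244, tolerance = 1e-4)
  expect_equal(r$area_ratio, 1.0616, tolerance = 1e-4)

  sym <- bifurcation_ratios(sqrt(2), 1, 1)
  expect_equal(sym$asymmetry_ratio, 1)
  expect_equal(sym$area_ratio, 1)

  # scale invariance of both ratios
  set.seed(11)
  for (i in 1:25) {
    tr <- random_valid_triple()
    c0 <- runif(1, 0.1, 10)
    a <- bifurcation_ratios(tr[1], tr[2], tr[3])
    b <- bifurcation_ratios(c0 * tr[1], c0 * tr[2], c0 * tr[3])
    expect_equal(a$asymmetry_ratio, b$asymmetry_ratio)
    expect_equal(a$area_ratio, b$area_ratio)
    expect_true(a$asymmetry_ratio > 0 && a$asymmetry_ratio <= 1)
  }
})

test_that("observed branch angles are the trunk-axis complements of beta/gamma", {
  a <- observed_branch_angles(121.5, 97.6)
  expect_equal(a$phi1_obs_deg, 58.5)
  expect_equal(a$phi2_obs_deg, 82.4)
  straight <- observed_branch_angles(180, 180)
  expect_equal(straight$phi1_obs_deg, 0)
  expect_equal(straight$phi2_obs_deg, 0)
  expect_equal(observed_branch_angles(90, 90)$phi1_obs_deg, 90)
  expect_error(observed_branch_angles(0, 90), "0, 180")
  expect_error(observed_branch_angles(90, 181), "0, 180")
})

test_that("junction exponent recovers exact power-law identities", {
  expect_equal(junction_exponent(2^(1/3), 1, 1)$n, 3, tolerance = 1e-9)
  expect_equal(junction_exponent(2, 1, 1)$n, 1, tolerance = 1e-9)
  expect_equal(junction_exponent(sqrt(2), 1, 1)$n, 2, tolerance = 1e-9)
  je <- junction_exponent(1.39, 1.16, 0.84)
  expect_equal(je$status, "ok")
  expect_equal(je$n, 2.21, tolerance = 0.005)
})

test_that("junction exponent flags no-solution and capped geometries", {
  expect_equal(junction_exponent(1.0, 1.0, 0.5)$status, "no_solution")
  expect_true(is.na(junction_exponent(1.0, 1.0, 0.5)$n))
  expect_equal(junction_exponent(1.0, 1.2, 0.5)$status, "no_solution")
  capped <- junction_exponent(1.0, 0.999, 0.9)   # root beyond the cap
  expect_equal(capped$status, "capped")
  expect_equal(capped$n, 20)
  expect_error(junction_exponent(-1, 1, 1), "positive")
})

test_that("junction exponent is scale invariant and decreasing in trunk radius", {
  set.seed(21)
  for (i in 1:50) {
    tr <- random_valid_triple()
    c0 <- runif(1, 0.2, 5)
    n1 <- junction_exponent(tr[1], tr[2], tr[3])$n
    n2 <- junction_exponent(c0 * tr[1], c0 * tr[2], c0 * tr[3])$n
    expect_equal(n1, n2, tolerance = 1e-8)
  }
  # monotonicity: growing r0 toward the branch-sum shrinks the root
  set.seed(22)
  for (i in 1:30) {
    r1 <- runif(1, 0.8, 1.4); r2 <- runif(1, 0.5, 1) * r1
    r0s <- seq(r1 * 1.02, r1 + r2 - 0.01, length.out = 5)
    ns <- vapply(r0s, function(r0) junction_exponent(r0, r1, r2)$n, 0)
    expect_true(all(diff(ns) < 0))
  }
})

test_that("cube-law crossing: n = 3 exactly at r0^3 = r1^3 + r2^3 and below after perturbation", {
  set.seed(23)
  for (i in 1:20) {
    r1 <- runif(1, 0.7, 1.4); r2 <- runif(1, 0.5, 1) * r1
    r0 <- (r1^3 + r2^3)^(1/3)
    expect_equal(junction_exponent(r0, r1, r2)$n, 3, tolerance = 1e-7)
    expect_lt(junction_exponent(r0 + 1e-3, r1, r2)$n, 3)
  }
})

test_that("bisection agrees with a fine-grid brute-force scan of the sign change", {
  set.seed(24)
  for (i in 1:300) {
    tr <- random_valid_triple()
    je <- junction_exponent(tr[1], tr[2], tr[3])
    n_grid <- grid_junction_exponent(tr[1], tr[2], tr[3])
    if (je$status == "capped") {
      expect_true(is.na(n_grid))   # no sign change below the cap either
    } else {
      expect_lt(abs(je$n - n_grid), 2e-6)
    }
  }
})

test_that("geometry records validate invariants", {
  g <- bifurcation_geometry(1.39, 1.16, 0.84, alpha_deg = 128.6,
                            beta_deg = 121.5, gamma_deg = 97.6)
  expect_s3_class(g, "bifurcation_geometry")
  expect_error(bifurcation_geometry(1.39, 0.84, 1.16), "canonical")
  expect_error(bifurcation_geometry(1.39, 1.16, 0.84, p0 = -1), "positive")
  expect_error(bifurcation_geometry(1.39, 1.16, 0.84, alpha_deg = 200), "0, 180")
})
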