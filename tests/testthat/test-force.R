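geom <- organoidGeometry(E = 1000, r0 = 100e-6)

test_that("contractile stress follows the cubic elasticity relation", {
  expect_equal(contractileStress(geom, 0), 0)
  expect_equal(contractileStress(geom, geom@r0), 3 * geom@E)
  # E = 1000 Pa, r0 = 100 um, deltaR = 10 um -> 3 * 1000 * (0.1)^3 = 3 Pa
  expect_equal(contractileStress(geom, 10e-6), 3)
  expect_error(contractileStress(geom, 2 * geom@r0), "unphysical")
  expect_error(contractileStress(geom, -1e-6), ">= 0")
})

test_that("force equals stress times the spherical surface area", {
  g <- organoidGeometry(E = 1000, r0 = 1e-4)
  fe <- contractileForce(g, 1e-5)
  expect_equal(fe@force, 3 * 1000 * 1e-3 * 4 * pi * 1e-8)  # ~3.77e-7 N
  expect_equal(fe@area, 4 * pi * 1e-8)
  # two-route identity to machine precision
  sweep <- seq(0, 1e-4, length.out = 11)
  for (dr in sweep) {
    fe <- contractileForce(g, dr)
    expect_equal(fe@force, contractileStress(g, dr) * fe@area,
                 tolerance = 1e-15)
  }
})

test_that("stress scales cubically in deformation, force quadratically in size", {
  dr <- 5e-6
  s1 <- contractileStress(geom, dr)
  for (c in c(2, 3, 4.5))
    expect_equal(contractileStress(geom, c * dr), c^3 * s1,
                 tolerance = 1e-12)
  # doubling r0 at fixed deltaR/r0 ratio quadruples F
  g2 <- organoidGeometry(E = geom@E, r0 = 2 * geom@r0)
  f1 <- contractileForce(geom, 0.1 * geom@r0)@force
  f2 <- contractileForce(g2, 0.1 * g2@r0)@force
  expect_equal(f2, 4 * f1, tolerance = 1e-12)
})

test_that("force is monotone in deformation and stiffness", {
  drs <- seq(1e-6, 9e-5, length.out = 20)
  fs <- vapply(drs, function(d) contractileForce(geom, d)@force, numeric(1))
  expect_true(all(diff(fs) > 0))
  es <- seq(100, 5000, length.out = 10)
  fe <- vapply(es, function(e)
    contractileForce(organoidGeometry(E = e, r0 = 1e-4), 1e-5)@force,
    numeric(1))
  expect_true(all(diff(fe) > 0))
})

test_that("geometry accepts lab units and enforces invariants", {
  g <- organoidGeometry(stiffnessKPa = 1.5, diameterUm = 250)
  expect_equal(g@E, 1500)
  expect_equal(g@r0, 125e-6)
  expect_equal(g@nu, 0.5)
  expect_error(organoidGeometry(E = -5, r0 = 1e-4), "E")
  expect_error(organoidGeometry(E = 100, r0 = 1e-4, nu = 0.7), "nu")
  expect_error(organoidGeometry(stiffnessKPa = 1), "r0")
})
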