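# Analytic model densities and promolecular references.

test_that("Gaussian model density matches its formula", {
  f <- gaussian_density(1, 1)
  expect_equal(evaluate_field(f, matrix(0, 1, 3))$rho, pi^-1.5,
               tolerance = 1e-12)
  expect_equal(as.numeric(evaluate_field(f, matrix(0, 1, 3))$grad),
               c(0, 0, 0))
  expect_error(gaussian_density(1, -1), "alpha")
  expect_error(gaussian_density(0, 1), "n_electrons")
})

test_that("analytic derivatives agree with central finite differences", {
  f <- gaussian_density(2, 1.3, c(0.2, -0.1, 0.4))
  set.seed(7)
  pts <- matrix(rnorm(30, sd = 1.5), 10, 3)
  h <- 1e-4
  s <- evaluate_field(f, pts)
  for (d in 1:3) {
    pp <- pts; pp[, d] <- pp[, d] + h
    pm <- pts; pm[, d] <- pm[, d] - h
    num <- (evaluate_field(f, pp)$rho - evaluate_field(f, pm)$rho) / (2 * h)
    expect_equal(s$grad[, d], num, tolerance = 1e-6)
  }
  num_lap <- 0
  for (d in 1:3) {
    pp <- pts; pp[, d] <- pp[, d] + h
    pm <- pts; pm[, d] <- pm[, d] - h
    num_lap <- num_lap +
      (evaluate_field(f, pp)$rho - 2 * s$rho + evaluate_field(f, pm)$rho) / h^2
  }
  expect_equal(s$laplacian, num_lap, tolerance = 1e-5)
})

test_that("Slater 1s density has the right cusp value and norm", {
  sl <- slater_1s_density(1)
  expect_equal(evaluate_field(sl, matrix(0, 1, 3))$rho, 1 / pi,
               tolerance = 1e-12)
  expect_equal(radial_oracle(function(r) exp(-2 * r) / pi), 1,
               tolerance = 1e-6)
  expect_error(slater_1s_density(-2), "Z")
})

test_that("bundled reference atoms integrate to their electron counts", {
  ref <- promolecular_reference(c("H", "C", "N", "O", "F", "S", "Cl", "Br"))
  for (el in names(ref$elements)) {
    e <- ref$elements[[el]]
    expect_equal(radial_oracle(e$rho0, rmax = 40), e$n_electrons,
                 tolerance = 1e-4)
  }
})

test_that("promolecule superposes atomic densities", {
  ref <- promolecular_reference(c("H", "F"))
  a1 <- atoms("F", matrix(0, 1, 3))
  pm1 <- build_promolecule(a1, ref)
  pts <- matrix(rnorm(30), 10, 3)
  expect_equal(evaluate_field(pm1, pts)$rho,
               ref$elements$F$rho0(sqrt(rowSums(pts^2))), tolerance = 1e-12)

  # distant H2: integral is additive
  a2 <- atoms(c("H", "H"), rbind(c(0, 0, 0), c(12, 0, 0)))
  g2 <- build_molecular_grid(a2, 75, 288)
  pm2 <- build_promolecule(a2, ref)
  expect_equal(grid_integrate(evaluate_field(pm2, g2)$rho, g2), 2,
               tolerance = 1e-4)

  # pointwise at least the largest single-atom term
  aHF <- atoms(c("H", "F"), rbind(c(0, 0, 0), c(1.7, 0, 0)))
  pmHF <- build_promolecule(aHF, ref)
  rhoH <- ref$elements$H$rho0(sqrt(rowSums(pts^2)))
  rhoF <- ref$elements$F$rho0(sqrt(rowSums(sweep(pts, 2, c(1.7, 0, 0))^2)))
  expect_true(all(evaluate_field(pmHF, pts)$rho >= pmax(rhoH, rhoF) - 1e-14))

  expect_error(build_promolecule(atoms("N", matrix(0, 1, 3)), ref),
               "missing from the promolecular reference")
})

test_that("reference normalization is an exact uniform rescaling", {
  g <- grid_1atom_fine()
  f <- gaussian_density(2, 1)
  same <- normalize_reference(f, 2, g)
  expect_equal(attr(same, "scale"), 1, tolerance = 1e-6)
  # cation: molecule holds N-1 electrons, reference scaled by (N-1)/N
  cat_ref <- normalize_reference(f, 1, g)
  expect_equal(attr(cat_ref, "scale"), 0.5, tolerance = 1e-6)
  expect_equal(grid_integrate(evaluate_field(cat_ref, g)$rho, g), 1,
               tolerance = 1e-8)
  zero <- density_field(function(p) numeric(nrow(p)),
                        function(p) matrix(0, nrow(p), 3),
                        function(p) numeric(nrow(p)), 0)
  expect_error(normalize_reference(zero, 1, g), "cannot normalize")
})

test_that("information gain is non-negative after normalization", {
  g <- grid_1atom_coarse()
  set.seed(42)
  for (i in 1:20) {
    a1 <- runif(1, 0.5, 3); a2 <- runif(1, 0.5, 3)
    f <- gaussian_density(1, a1)
    r <- normalize_reference(gaussian_density(1, a2), 1, g)
    # far tails may fall below the density floor; that clipping only
    # removes vanishing mass and is warned about, not an error
    expect_gte(suppressWarnings(information_gain(f, r, g)), -1e-8)
  }
})

test_that("radial tables round-trip through the plain-text loader", {
  ref <- promolecular_reference("O")
  r <- exp(seq(log(1e-3), log(25), length.out = 400))
  tab <- data.frame(r = r, rho = ref$elements$O$rho0(r))
  path <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE)
  ref2 <- reference_from_tables(c(O = path))
  rt <- seq(0.05, 20, length.out = 200)
  expect_equal(ref2$elements$O$rho0(rt), ref$elements$O$rho0(rt),
               tolerance = 1e-3)
  expect_equal(radial_oracle(ref2$elements$O$rho0, rmax = 25), 8,
               tolerance = 1e-3)
})
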