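# The eleven information-theoretic functionals against closed forms and a
# dense 1-D radial quadrature oracle.

test_that("Shannon entropy matches Gaussian and Slater closed forms", {
  g <- grid_1atom_fine()
  expect_equal(shannon_entropy(gaussian_density(1, 1), g),
               1.5 * (1 + log(pi)), tolerance = 1e-5)
  expect_equal(shannon_entropy(slater_1s_density(1), g), 3 + log(pi),
               tolerance = 1e-4)
})

test_that("Shannon entropy obeys the density scaling law", {
  g <- grid_1atom_fine()
  # lambda^3 rho(lambda r) with lambda = 2 maps alpha -> 4 alpha
  s1 <- shannon_entropy(gaussian_density(1, 1), g)
  s2 <- shannon_entropy(gaussian_density(1, 4), g)
  expect_equal(s1 - s2, 3 * log(2), tolerance = 1e-5)
})

test_that("Fisher information matches closed forms and is non-negative", {
  g <- grid_1atom_fine()
  expect_equal(fisher_information(gaussian_density(1, 1), g), 6,
               tolerance = 1e-5)
  expect_equal(fisher_information(slater_1s_density(2), g), 16,
               tolerance = 1e-4)
  set.seed(3)
  for (alpha in runif(5, 0.3, 4)) {
    expect_gte(fisher_information(gaussian_density(2, alpha), g), 0)
  }
})

test_that("kinetic energy densities reproduce the Gaussian orbital", {
  g <- grid_1atom_fine()
  kd <- kinetic_energy_densities(gaussian_density(2, 1.4), g)
  # one Gaussian orbital: T = 3 alpha / 4 per electron
  expect_equal(kd$T_S, 2 * 3 * 1.4 / 4, tolerance = 1e-5)
  expect_equal(gbp_constants()$c_K, 2.871234, tolerance = 1e-6)
  # Thomas-Fermi density is the exact power law pointwise
  s <- evaluate_field(gaussian_density(2, 1.4), g)
  expect_equal(kd$t_tf, gbp_constants()$c_K * s$rho^(5 / 3),
               tolerance = 1e-12)
  expect_error(
    kinetic_energy_densities(
      density_field(function(p) rep(1, nrow(p)),
                    function(p) matrix(0, nrow(p), 3),
                    function(p) numeric(nrow(p)), 1), g),
    "orbital")
})

test_that("GBP entropy hits the t == t_TF limit exactly", {
  g <- grid_1atom_fine()
  f <- gaussian_density(1, 1)
  kd0 <- kinetic_energy_densities(f, g)
  kd <- structure(list(t = kd0$t_tf, t_tf = kd0$t_tf, T_S = NA),
                  class = "kinetic_densities")
  cc <- gbp_constants()
  expect_equal(gbp_entropy(f, kd, g), -1.5 * cc$c * 1, tolerance = 1e-6)
  # N = 3: linear in the electron count
  f3 <- gaussian_density(3, 1)
  kd3 <- kinetic_energy_densities(f3, g)
  kd3l <- structure(list(t = kd3$t_tf, t_tf = kd3$t_tf, T_S = NA),
                    class = "kinetic_densities")
  expect_equal(gbp_entropy(f3, kd3l, g), -1.5 * cc$c * 3, tolerance = 1e-5)
})

test_that("GBP entropy of a Gaussian orbital matches the radial oracle", {
  g <- grid_1atom_fine()
  alpha <- 1
  val <- gbp_entropy(gaussian_density(1, alpha), NULL, g)
  cc <- gbp_constants()
  oracle <- radial_oracle(function(r) {
    rho <- (alpha / pi)^1.5 * exp(-alpha * r^2)
    t <- 0.75 * alpha * rho          # analytic orbital KE density
    t_tf <- cc$c_K * rho^(5 / 3)
    -1.5 * rho * (cc$c + log(t / t_tf))
  }, rmax = 12)
  expect_equal(val, oracle, tolerance = 1e-4)
})

test_that("Onicescu energies match Gaussian closed forms", {
  g <- grid_1atom_fine()
  f <- gaussian_density(1, 1)
  expect_equal(onicescu_energy(f, g, 2), (1 / (2 * pi))^1.5,
               tolerance = 1e-5)
  expect_equal(onicescu_energy(f, g, 3), 0.5 * (1 / (3 * pi^2))^1.5,
               tolerance = 1e-5)
  # homogeneity of degree n in the density
  f2 <- gaussian_density(2, 1)
  expect_equal(onicescu_energy(f2, g, 2), 4 * onicescu_energy(f, g, 2),
               tolerance = 1e-10)
  expect_error(onicescu_energy(f, g, 4), "unsupported order")
})

test_that("relative Renyi entropy hits self-reference limits", {
  g <- grid_1atom_fine()
  f1 <- gaussian_density(1, 1)
  expect_equal(relative_renyi(f1, f1, g, 2), 0, tolerance = 1e-10)
  f10 <- gaussian_density(10, 1)
  expect_equal(relative_renyi(f10, f10, g, 2), -1, tolerance = 1e-6)
  expect_equal(relative_renyi(f10, f10, g, 3), -0.5 * log10(10),
               tolerance = 1e-6)
})

test_that("relative Renyi entropy matches the Gaussian ratio oracle", {
  # sharper density against a broader reference (the ratio integral
  # converges only for 2*alpha > alpha0)
  g <- grid_1atom_fine()
  val <- relative_renyi(gaussian_density(1, 2), gaussian_density(1, 1), g, 2)
  oracle <- (1 / (1 - 2)) * log10(radial_oracle(function(r) {
    rho <- (2 / pi)^1.5 * exp(-2 * r^2)
    rho0 <- pi^-1.5 * exp(-r^2)
    rho^2 / rho0
  }, rmax = 12))
  expect_equal(val, oracle, tolerance = 1e-4)
})

test_that("information gain matches the Gaussian KL closed form", {
  g <- grid_1atom_fine()
  expect_equal(information_gain(gaussian_density(1, 1),
                                gaussian_density(1, 1), g), 0,
               tolerance = 1e-10)
  val <- information_gain(gaussian_density(1, 2), gaussian_density(1, 1), g)
  expect_equal(val, 1.5 * (log(2) - 0.5), tolerance = 1e-5)
})

test_that("G functionals vanish at self-reference and G3 is non-negative", {
  tq <- make_toy_quinone(1, 0)
  g <- build_molecular_grid(tq$atoms, 30, 98)
  p <- hirshfeld_partition(tq$field, tq$atoms, tq$ref, g)
  gf <- g_functions(p, g)
  expect_lt(abs(gf$G3), 1e-10)
  expect_lt(abs(gf$G2), 1e-6)
  expect_lt(abs(gf$G1), 0.1)  # Laplacian quadrature noise only
  tqp <- make_toy_quinone(1, 0.4)
  pp <- hirshfeld_partition(tqp$field, tqp$atoms, tqp$ref, g)
  gfp <- g_functions(pp, g)
  expect_gte(gfp$G3, 0)
  expect_true(all(gfp$G3_atomic >= -1e-14))
})

test_that("G functionals match the one-atom radial oracle", {
  # one 'atom' whose reference is a unit Gaussian alpha0 = 1 while the
  # molecular density is a unit Gaussian alpha = 2
  ref <- gaussian_reference(c(X = 1), c(X = 1))
  a <- atoms("H", matrix(0, 1, 3)); a$element <- "X"
  g <- grid_1atom_fine()
  f <- gaussian_density(1, 2)
  p <- hirshfeld_partition(f, a, ref, g)
  gf <- g_functions(p, g)
  rho <- function(r) (2 / pi)^1.5 * exp(-2 * r^2)
  rho0 <- function(r) pi^-1.5 * exp(-r^2)
  lap <- function(r, al) (4 * al^2 * r^2 - 6 * al) *
    (al / pi)^1.5 * exp(-al * r^2)
  # d/dr ln(rho/rho0) = -2 (alpha - alpha0) r
  o_g3 <- radial_oracle(function(r) rho(r) * (2 * (2 - 1) * r)^2, rmax = 12)
  o_g1 <- radial_oracle(function(r) lap(r, 2) * rho(r) / rho0(r), rmax = 12)
  o_g2 <- radial_oracle(function(r) lap(r, 2) - rho(r) * lap(r, 1) / rho0(r),
                        rmax = 12)
  expect_equal(gf$G3, o_g3, tolerance = 1e-4)
  expect_equal(gf$G1, o_g1, tolerance = 1e-3)
  expect_equal(gf$G2, o_g2, tolerance = 1e-3)
})

test_that("the 11-component descriptor vector is consistent", {
  tq <- make_toy_quinone(1, 0.3)
  g <- build_molecular_grid(tq$atoms, 30, 98)
  v <- compute_ita_vector(tq$field, tq$atoms, tq$ref, g)
  expect_s3_class(v, "ita_vector")
  expect_length(v, 11)
  expect_identical(names(v), ita_names())
  # component-wise agreement with individually computed quantities
  s <- evaluate_field(tq$field, g)
  N <- grid_integrate(s$rho, g)
  pm <- normalize_reference(build_promolecule(tq$atoms, tq$ref), N, g)
  expect_equal(v[["S_S"]], shannon_entropy(s, g), tolerance = 1e-12)
  expect_equal(v[["I_F"]], fisher_information(s, g), tolerance = 1e-12)
  expect_equal(v[["E2"]], onicescu_energy(s, g, 2), tolerance = 1e-12)
  expect_equal(v[["rR2"]], relative_renyi(s, evaluate_field(pm, g), g, 2),
               tolerance = 1e-12)
  expect_equal(v[["I_G"]], information_gain(s, evaluate_field(pm, g), g),
               tolerance = 1e-12)
  # identical call is deterministic
  expect_identical(unclass(v),
                   unclass(compute_ita_vector(tq$field, tq$atoms, tq$ref, g)))
})

test_that("self-referenced single-center system hits all limits", {
  tq <- make_toy_quinone(1, 0)
  g <- build_molecular_grid(tq$atoms, 30, 98)
  v <- compute_ita_vector(tq$field, tq$atoms, tq$ref, g)
  N <- 40
  expect_equal(v[["rR2"]], -log10(N), tolerance = 1e-4)
  expect_equal(v[["rR3"]], -0.5 * log10(N), tolerance = 1e-4)
  expect_lt(abs(v[["I_G"]]), 1e-6)
  expect_lt(abs(v[["G3"]]), 1e-10)
  expect_lt(abs(v[["G2"]]), 1e-6)
})

test_that("collinear descriptor blocks emerge on a Gaussian family", {
  # smoke test of the qualitative collinearity of ITA descriptors: across a
  # one-parameter family of densities, entropy-type measures move together
  g <- grid_1atom_coarse()
  alphas <- seq(0.6, 2.4, length.out = 9)
  vals <- t(vapply(alphas, function(al) {
    f <- gaussian_density(2, al)
    c(S = shannon_entropy(f, g), E2 = onicescu_energy(f, g, 2),
      IF = fisher_information(f, g))
  }, numeric(3)))
  expect_gt(abs(cor(vals[, "S"], log(vals[, "E2"]))), 0.95)
  expect_gt(abs(cor(vals[, "S"], log(vals[, "IF"]))), 0.95)
})
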