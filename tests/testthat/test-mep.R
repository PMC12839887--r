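# Electrostatic-potential descriptors and carbonyl-oxygen identification.

test_that("nuclei-only potential is the bare Coulomb sum", {
  a <- atoms(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(mep_at_nucleus(a, NULL, NULL, 1), 0.5, tolerance = 1e-12)
  expect_error(mep_at_nucleus(a, NULL, NULL, 5), "out of range")
})

test_that("potential of a Gaussian charge matches closed forms", {
  a <- atoms("H", matrix(0, 1, 3))
  g <- grid_1atom_fine()
  f <- gaussian_density(1, 1)
  # at the distribution center (self-nucleus excluded): -2 sqrt(alpha/pi)
  expect_equal(mep_at_nucleus(a, f, g, 1), -2 * sqrt(1 / pi),
               tolerance = 1e-5)
  # displaced probe: -erf(sqrt(alpha) d) / d plus the nuclear term Z/d
  d <- 2.5
  probe <- atoms(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
  gp <- build_molecular_grid(probe, 75, 288)
  v <- mep_at_nucleus(probe, f, gp, 2)
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  expect_equal(v, 1 / d - erf(sqrt(1) * d) / d, tolerance = 1e-5)
})

test_that("neutral-atom potential is screened beyond Coulomb", {
  # Slater hydrogen: V(r) = exp(-2 r) (1 + 1/r); decays faster than 1/r^2
  f <- slater_1s_density(1)
  a <- atoms("H", matrix(0, 1, 3))
  vals <- vapply(c(5, 10, 20), function(d) {
    sys <- atoms(c("H", "H"), rbind(c(0, 0, 0), c(d, 0, 0)))
    g <- build_molecular_grid(sys, 75, 288)
    mep_at_nucleus(sys, f, g, 2) * d^2
  }, 0)
  # V r^2 -> 0: exponential screening beats the bare-charge 1/r^2 decay
  expect_lt(abs(vals[2]), abs(vals[1]) / 10)
  expect_lt(abs(vals[3]), 1e-4)
  expect_equal(vals[1], exp(-10) * 30, tolerance = 1e-3)
})

test_that("carbonyl oxygens are identified by the bond-count rule", {
  ang <- seq(0, 300, by = 60) * pi / 180
  B <- 1 / 0.52917721092
  ring <- cbind(1.4 * B * cos(ang), 1.4 * B * sin(ang), 0)
  # para-benzoquinone-like: two C=O at 1.22 A on atoms 1 and 4
  bq <- atoms(c(rep("C", 6), "O", "O", rep("H", 4)),
              rbind(ring,
                    c((1.4 + 1.22) * B, 0, 0),
                    c(-(1.4 + 1.22) * B, 0, 0),
                    cbind((1.4 + 1.08) * B * cos(ang[c(2, 3, 5, 6)]),
                          (1.4 + 1.08) * B * sin(ang[c(2, 3, 5, 6)]), 0)))
  expect_identical(identify_carbonyl_oxygens(bq), c(7L, 8L))

  # add a methoxy-like ether oxygen (two bonds): excluded by bond count
  u2 <- c(cos(ang[2]), sin(ang[2]), 0)
  ome <- rbind(ring,
               c((1.4 + 1.22) * B, 0, 0),
               c(-(1.4 + 1.22) * B, 0, 0),
               u2 * (1.4 + 1.43) * B,          # ether O on C2
               u2 * (1.4 + 1.43 + 1.43) * B)   # methyl C on the ether O
  oq <- atoms(c(rep("C", 6), "O", "O", "O", "C"), ome)
  expect_identical(identify_carbonyl_oxygens(oq), c(7L, 8L))

  # no carbonyl at all
  plain <- atoms(c("C", "H", "H", "H", "H"),
                 rbind(c(0, 0, 0), c(2.05, 0, 0), c(-2.05, 0, 0),
                       c(0, 2.05, 0), c(0, -2.05, 0)))
  expect_error(identify_carbonyl_oxygens(plain), "fewer than two")
})

test_that("descriptor rows average the two oxygen potentials exactly", {
  v <- structure(stats::rnorm(11), names = ita_names(), class = "ita_vector")
  row <- descriptor_row("000", "BQ", v, homo = -0.25, lumo = -0.12,
                        mep_o1 = -22.31, mep_o2 = -22.27)
  expect_identical(row$mep_o_avg, (row$mep_o1 + row$mep_o2) / 2)
  # all 21 schema columns plus the derived average
  expect_equal(ncol(row), 22)
})

test_that("the two oxygen potentials co-vary across a substituted family", {
  perturb <- seq(-0.45, 0.45, by = 0.15)
  mep <- t(vapply(perturb, function(d) {
    tq <- make_toy_quinone(1, d)
    g <- build_molecular_grid(tq$atoms, 30, 98)
    c(o1 = mep_at_nucleus(tq$atoms, tq$field, g, tq$oxygen_indices[1]),
      o2 = mep_at_nucleus(tq$atoms, tq$field, g, tq$oxygen_indices[2]))
  }, numeric(2)))
  expect_gt(stats::cor(mep[, "o1"], mep[, "o2"])^2, 0.9)
  # density arriving at the oxygens makes their potential more negative
  expect_true(all(diff(mep[, "o1"]) < 0))
})
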