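make_point_dimer <- function(r, type = "C2") {
  list(coords1 = matrix(0, 1, 3), coords2 = matrix(c(r, 0, 0), 1, 3),
       types1 = type, types2 = type, elements1 = "C", elements2 = "C",
       distance = r, label = sprintf("pair-%g", r))
}

test_that("nearest-atom distance is the brute-force minimum", {
  d <- nearest_atom_distance(make_point_dimer(6))
  expect_equal(d, 6)
  # translated monomer: distance bounded below by translation minus extent
  truth <- fx_truth()
  top <- fx_butane()
  base <- ideal_geometry(top)$coords
  dimer <- list(coords1 = base, coords2 = sweep(base, 2, c(7, 0, 0), "+"))
  expect_gte(nearest_atom_distance(dimer), 7 - 2 * max(dist(base)))
  # randomized brute-force cross-check
  set.seed(3)
  for (rep in 1:20) {
    a <- matrix(stats::rnorm(15, sd = 2), 5, 3)
    b <- matrix(stats::rnorm(15, sd = 2), 5, 3) + 8
    brute <- min(as.matrix(stats::dist(rbind(a, b)))[1:5, 6:10])
    expect_equal(nearest_atom_distance(list(coords1 = a, coords2 = b)),
                 brute, tolerance = 1e-12)
  }
  expect_error(nearest_atom_distance(make_point_dimer(0.05)), "overlap")
})

test_that("the dimer filter applies a closed 5-12 A window", {
  dimers <- structure(lapply(c(4.9, 5.0, 8, 12.0, 12.1), make_point_dimer),
                      class = "dimer_set")
  suppressMessages(kept <- filter_dimers(dimers))
  expect_equal(vapply(kept, `[[`, numeric(1), "distance"), c(5, 8, 12))
  expect_error(filter_dimers(dimers, d_min = 12, d_max = 5), "smaller")
})

test_that("dispersion fitting recovers ground-truth C6/C8 from energies", {
  truth <- fx_truth()
  top1 <- fx_pentane()
  dil <- make_dilute_frames(top1, n_frames = 8, n_mol = 14, span = 26,
                            seed = 3)
  dtop <- replicate_topology(top1, 14)
  dimers <- extract_dimers(dil, dtop, n = 300, seed = 4)
  expect_gte(length(dimers), 50)
  dimers <- mock_dispersion_energy(dimers, truth)
  rd_map <- setNames(truth$pairs$rd, truth$pairs$key)
  res <- fit_dispersion(dimers, rd_map)
  tr <- truth$pairs[match(res$coefficients$key, truth$pairs$key), ]
  expect_lt(max(abs(res$coefficients$C6 / tr$C6 - 1)), 1e-8)
  expect_lt(max(abs(res$coefficients$C8 / tr$C8 - 1)), 1e-8)
  expect_length(res$warnings, 0)

  # linearity: doubled energies double the coefficients
  dimers2 <- structure(lapply(dimers, function(r) {
    r$energy <- 2 * r$energy; r
  }), class = "dimer_set")
  res2 <- fit_dispersion(dimers2, rd_map)
  expect_equal(res2$coefficients$C6, 2 * res$coefficients$C6,
               tolerance = 1e-8)
  expect_equal(res2$coefficients$C8, 2 * res$coefficients$C8,
               tolerance = 1e-8)
})

test_that("a C6-only truth fits C8 to zero (nested-model exactness)", {
  rd <- 3.0; C6 <- 1000
  dimers <- structure(lapply(seq(5, 12, length.out = 12), function(r) {
    d <- make_point_dimer(r)
    d$energy <- -C6 / (r^6 + rd^6)
    d
  }), class = "dimer_set")
  res <- fit_dispersion(dimers, c("C2-C2" = rd))
  expect_equal(res$coefficients$C6, C6, tolerance = 1e-8)
  expect_lt(abs(res$coefficients$C8), 1e-6)
})

test_that("under-determined dispersion fits are refused with a count", {
  dimers <- structure(lapply(c(6, 8), make_point_dimer), class = "dimer_set")
  dimers <- structure(lapply(dimers, function(r) { r$energy <- -1; r }),
                      class = "dimer_set")
  expect_error(fit_dispersion(dimers, c("C2-C2" = 3)), "need at least 4")
})

test_that("energy design rows equal finite-difference coefficient derivatives", {
  rd_map <- c("C2-C2" = 3.0)
  rec <- make_point_dimer(7)
  row <- afmatch:::dispersion_basis_row(rec, c("C6:C2-C2", "C8:C2-C2"),
                                        rd_map)
  model <- function(C6, C8) -C6 / (7^6 + 3^6) - C8 / (7^8 + 3^8)
  h <- 1
  expect_equal(unname(row["C6:C2-C2"]), (model(h, 0) - model(-h, 0)) / (2 * h),
               tolerance = 1e-12)
  expect_equal(unname(row["C8:C2-C2"]), (model(0, h) - model(0, -h)) / (2 * h),
               tolerance = 1e-12)
})

test_that("dropping the C8 basis never lowers the residual", {
  truth <- fx_truth()
  set.seed(21)
  rd <- 3.4
  dimers <- structure(lapply(stats::runif(40, 5, 12), function(r) {
    d <- make_point_dimer(r)
    d$energy <- -600 / (r^6 + rd^6) - 5200 / (r^8 + rd^8) +
      stats::rnorm(1, sd = 1e-4)
    d
  }), class = "dimer_set")
  full <- fit_dispersion(dimers, c("C2-C2" = rd))
  # C6-only refit via the same engine: zero out the C8 column by fitting
  # against a C6-only basis
  L <- vapply(dimers, function(r) -1 / (r$distance^6 + rd^6), numeric(1))
  e <- vapply(dimers, `[[`, numeric(1), "energy")
  c6only <- solve_svd(linear_system(matrix(L, ncol = 1,
                                           dimnames = list(NULL, "C6")), e))
  expect_gte(c6only$residual_rms, full$fit$residual_rms - 1e-12)
})

test_that("1% energy noise keeps the dominant C6 within 5%", {
  # cyclopentane homodimers carry a single carbon pair, whose C6 term
  # dominates the dispersion signal in the 5-12 A window
  truth <- fx_truth()
  top1 <- fx_cyclopentane()
  dil <- make_dilute_frames(top1, n_frames = 8, n_mol = 14, span = 26,
                            seed = 13)
  dtop <- replicate_topology(top1, 14)
  dimers <- extract_dimers(dil, dtop, n = 400, seed = 14)
  expect_gte(length(dimers), 200)
  dimers <- mock_dispersion_energy(dimers, truth)
  e_rms <- sqrt(mean(vapply(dimers, `[[`, numeric(1), "energy")^2))
  dimers <- mock_dispersion_energy(dimers, truth, sigma_E = 0.01 * e_rms,
                                   seed = 15)
  res <- fit_dispersion(dimers, setNames(truth$pairs$rd, truth$pairs$key))
  tr <- truth$pairs[match(res$coefficients$key, truth$pairs$key), ]
  expect_lt(max(abs(res$coefficients$C6 / tr$C6 - 1)), 0.05)
})

test_that("repulsive dispersion coefficients trigger named warnings", {
  coefs <- data.frame(key = c("C2-C2", "C2-C3"), C6 = c(600, -4),
                      C8 = c(-50, 5000))
  w <- stability_check(coefs)
  expect_length(w, 2)
  expect_match(w[1], "C8.*C2-C2")
  expect_match(w[1], "-50")
  expect_match(w[2], "C6.*C2-C3")
  expect_length(stability_check(data.frame(key = "C2-C2", C6 = 1, C8 = 1)),
                0)
})
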