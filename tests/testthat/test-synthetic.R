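test_that("perturbation generator is deterministic and sized as requested", {
  truth <- fx_truth()
  top <- fx_pentane()
  a <- generate_conformations(top, truth, n = 20, seed = 5)
  expect_length(a, 20)
  b <- generate_conformations(top, truth, n = 20, seed = 5)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  d <- generate_conformations(top, truth, n = 20, seed = 6)
  expect_false(identical(a[[1]]$coords, d[[1]]$coords))
  # zero amplitude without conformer sampling reproduces the ideal geometry
  z <- generate_conformations(top, truth, n = 3, seed = 1, sigma0 = 0,
                              conformers = FALSE)
  ideal <- ideal_geometry(top)$coords
  for (cf in z) expect_equal(cf$coords, ideal, tolerance = 1e-12)
})

test_that("md-mode generation delegates to the Langevin sampler", {
  truth <- fx_truth()
  top <- fx_butane()
  md <- generate_conformations(top, truth, n = 4, seed = 3, mode = "md",
                               stride = 5)
  direct <- sample_conformations(truth, top, n_frames = 4, seed = 3,
                                 stride = 5)
  expect_identical(lapply(md, `[[`, "coords"),
                   lapply(direct, `[[`, "coords"))
})

test_that("mock reference forces equal the truth model exactly at zero noise", {
  truth <- fx_truth()
  top <- replicate_topology(fx_butane(), 2)
  confs <- generate_conformations(top, truth, n = 3, seed = 7)
  withf <- mock_reference_forces(confs, top, truth)
  pm <- classify_pairs(top)
  for (i in seq_along(confs)) {
    expect_identical(withf[[i]]$forces,
                     eval_forcefield(confs[[i]], top, truth,
                                     pair_map = pm)$forces)
  }
})

test_that("force-noise statistics match the configured sigma", {
  truth <- fx_truth()
  top <- replicate_topology(fx_pentane(), 2)
  confs <- generate_conformations(top, truth, n = 100, seed = 8)
  clean <- mock_reference_forces(confs, top, truth)
  noisy <- mock_reference_forces(confs, top, truth, sigma = 1.0, seed = 9)
  eps <- unlist(lapply(seq_along(confs), function(i)
    noisy[[i]]$forces - clean[[i]]$forces))
  expect_gte(length(eps), 1e4)
  expect_lt(abs(stats::sd(eps) - 1.0), 0.05)
  expect_lt(abs(mean(eps)), 0.05)
  # reproducible from seed
  noisy2 <- mock_reference_forces(confs, top, truth, sigma = 1.0, seed = 9)
  expect_identical(lapply(noisy, `[[`, "forces"),
                   lapply(noisy2, `[[`, "forces"))
})

test_that("extracted dimers honor the window, checked by brute force", {
  truth <- fx_truth()
  top1 <- fx_butane()
  dil <- make_dilute_frames(top1, n_frames = 4, n_mol = 10, span = 24,
                            seed = 10)
  dtop <- replicate_topology(top1, 10)
  dimers <- extract_dimers(dil, dtop, window = c(5, 12), n = 100, seed = 11)
  expect_gt(length(dimers), 0)
  for (rec in dimers) {
    brute <- min(as.matrix(stats::dist(rbind(rec$coords1, rec$coords2)))[
      seq_len(nrow(rec$coords1)),
      nrow(rec$coords1) + seq_len(nrow(rec$coords2))])
    expect_equal(rec$distance, brute, tolerance = 1e-12)
    expect_gte(rec$distance, 5)
    expect_lte(rec$distance, 12)
  }
  # deterministic subsampling
  d2 <- extract_dimers(dil, dtop, window = c(5, 12), n = 100, seed = 11)
  expect_identical(lapply(dimers, `[[`, "label"),
                   lapply(d2, `[[`, "label"))
  expect_error(extract_dimers(dil, dtop, window = c(12, 5)), "window")
  # single-molecule frames produce a warning and no records
  single <- generate_conformations(top1, truth, n = 1, seed = 1)
  expect_warning(empty <- extract_dimers(single, top1), "fewer than two")
  expect_length(empty, 0)
})

test_that("mock dispersion energy matches the damped pair sum", {
  truth <- fx_truth()
  # single C-C pair at 8 A with C6 = 1000, C8 = 0, rd = 3
  tt <- truth
  tt$pairs$C6 <- ifelse(tt$pairs$key == "C2-C2", 1000, 0)
  tt$pairs$C8 <- 0
  tt$pairs$rd <- ifelse(tt$pairs$key == "C2-C2", 3, tt$pairs$rd)
  rec <- list(coords1 = matrix(0, 1, 3), coords2 = matrix(c(8, 0, 0), 1, 3),
              types1 = "C2", types2 = "C2", elements1 = "C",
              elements2 = "C", distance = 8, label = "x")
  out <- mock_dispersion_energy(structure(list(rec), class = "dimer_set"), tt)
  expect_equal(out[[1]]$energy, -1000 / (8^6 + 3^6), tolerance = 1e-14)
  # zero truth -> zero energy
  t0 <- truth; t0$pairs$C6 <- 0; t0$pairs$C8 <- 0
  out0 <- mock_dispersion_energy(structure(list(rec), class = "dimer_set"), t0)
  expect_equal(out0[[1]]$energy, 0)
  # attractive for positive coefficients on any real dimer set
  top1 <- fx_butane()
  dil <- make_dilute_frames(top1, n_frames = 2, n_mol = 8, span = 22,
                            seed = 12)
  dimers <- extract_dimers(dil, replicate_topology(top1, 8), n = 30,
                           seed = 13)
  dimers <- mock_dispersion_energy(dimers, truth)
  expect_true(all(vapply(dimers, `[[`, numeric(1), "energy") <= 0))
})

test_that("cyclic ideal geometries are closed, relaxed rings", {
  top <- fx_cyclopentane()
  conf <- ideal_geometry(top)
  c_idx <- which(top$atoms$element == "C")
  ring <- c(diff(c_idx) * 0 + 1)  # consecutive ring bonds
  d <- vapply(seq_along(c_idx), function(i) {
    j <- if (i == length(c_idx)) 1 else i + 1
    sqrt(sum((conf$coords[c_idx[i], ] - conf$coords[c_idx[j], ])^2))
  }, numeric(1))
  expect_true(all(abs(d - 1.53) < 0.1))
  # relaxation leaves small residual forces
  f <- eval_forcefield(conf, top, fx_truth())$forces
  expect_lt(max(abs(f)), 1.0)
})

test_that("end-to-end synthetic pipeline recovers every parameter", {
  # dispersion fit from dimer energies, then two-pass force matching with
  # CMD on cluster forces: the complete ground truth comes back
  truth <- fx_truth()
  top1 <- fx_pentane()
  dil <- make_dilute_frames(top1, n_frames = 8, n_mol = 14, span = 26,
                            seed = 21)
  dimers <- extract_dimers(dil, replicate_topology(top1, 14), n = 300,
                           seed = 22)
  dimers <- mock_dispersion_energy(dimers, truth)
  disp <- fit_dispersion(dimers, setNames(truth$pairs$rd, truth$pairs$key))
  top <- replicate_topology(top1, 6)
  confs <- generate_conformations(top, truth, n = 12, seed = 23)
  confs <- mock_reference_forces(confs, top, truth)
  fit <- fm_fit(confs, top, truth, dispersion = disp$coefficients)
  expect_lt(max_recovery_error(fit$forcefield), 1e-6)
  tr <- truth$pairs[match(disp$coefficients$key, truth$pairs$key), ]
  expect_lt(max(abs(disp$coefficients$C6 / tr$C6 - 1)), 1e-6)
  expect_lt(max(abs(disp$coefficients$C8 / tr$C8 - 1)), 1e-6)
  expect_gt(fit$charges[["HC"]], 0)
})
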