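test_that("parameter spec enumerates type-pair parameters correctly", {
  # cyclopentane: 2 types -> 3 charge products
  spec <- build_parameter_spec(list(fx_cyclopentane()))
  expect_equal(sum(spec$kind == "qq"), 3)
  # n-pentane: 3 types -> 6 charge products, 6 repulsion prefactors
  spec <- build_parameter_spec(list(fx_pentane()))
  expect_equal(sum(spec$kind == "qq"), 6)
  expect_equal(sum(spec$kind == "A"), 6)
  # dispersion only on carbon-carbon pairs
  expect_equal(sort(spec$key[spec$kind == "C6"]),
               c("C2-C2", "C2-C3", "C3-C3"))
  # bonded composites come in pairs
  expect_equal(sum(spec$kind == "bond_k"), sum(spec$kind == "bond_kre"))
  expect_equal(sum(spec$kind == "angle_k"), sum(spec$kind == "angle_kte"))
  # fixing charge products leaves no free qq parameter
  prods <- products_from_charges(c(C2 = -0.1, C3 = -0.15, HC = 0.05))
  spec2 <- build_parameter_spec(list(fx_pentane()),
                                fix_charge_products = prods)
  expect_equal(sum(spec2$kind == "qq" & !spec2$fixed), 0)
  expect_error(build_parameter_spec(list()), "at least one")
})

test_that("design columns are the exact parameter derivatives of the model force", {
  truth <- fx_truth()
  cl <- fx_butane_cluster()
  spec <- build_parameter_spec(list(cl$top), fix_dispersion = fx_disp())
  sys <- build_design_matrix(cl$confs[1:2], cl$top, spec, truth)
  # one frame contributes 3N rows
  expect_equal(nrow(sys$L), 2 * 3 * n_atoms(cl$top))
  # finite-difference check: perturb each parameter around the truth and
  # difference the assembled model force (the model is linear, so the
  # column is exact)
  p0 <- truth_parameter_vector(spec)
  make_ff <- function(p) {
    ff <- truth
    for (nm in names(p)) {
      kv <- strsplit(nm, ":", fixed = TRUE)[[1]]
      key <- kv[2]
      switch(kv[1],
        A = { ff$pairs$A[ff$pairs$key == key] <- p[[nm]] },
        bond_k = {
          i <- ff$bonds$key == key
          r0 <- p[[paste0("bond_kre:", key)]] / p[[nm]]
          ff$bonds$k[i] <- p[[nm]]; ff$bonds$r0[i] <- r0
        },
        angle_k = {
          i <- ff$angles$key == key
          t0 <- p[[paste0("angle_kte:", key)]] / p[[nm]]
          ff$angles$k[i] <- p[[nm]]; ff$angles$theta0[i] <- t0
        },
        tors_A = { ff$torsions$A[ff$torsions$key == key] <- p[[nm]] })
    }
    ff
  }
  conf <- cl$confs[[1]]
  rows <- seq_len(3 * n_atoms(cl$top))
  for (nm in c("A:C2-HC", "tors_A:C3-C2-C2-C3")) {
    h <- max(1e-4, abs(p0[[nm]]) * 1e-4)
    pp <- p0; pp[nm] <- pp[nm] + h
    pm <- p0; pm[nm] <- pm[nm] - h
    fp <- eval_forcefield(conf, cl$top, make_ff(pp))$forces
    fm <- eval_forcefield(conf, cl$top, make_ff(pm))$forces
    expect_equal(sys$L[rows, nm], as.numeric(fp - fm) / (2 * h),
                 tolerance = 1e-8)
  }
})

test_that("the design system is consistent with the evaluator at the truth", {
  truth <- fx_truth()
  cl <- fx_butane_cluster()
  spec <- build_parameter_spec(list(cl$top), fix_dispersion = fx_disp())
  sys <- build_design_matrix(cl$confs, cl$top, spec, truth)
  p0 <- truth_parameter_vector(spec)
  expect_lt(max(abs(sys$f - as.numeric(sys$L %*% p0))), 1e-10)
})

test_that("design assembly demands reference forces", {
  truth <- fx_truth()
  top <- fx_butane()
  confs <- generate_conformations(top, truth, n = 2, seed = 1)
  spec <- build_parameter_spec(list(top), fix_dispersion = fx_disp())
  expect_error(build_design_matrix(confs, top, spec, truth),
               "reference forces")
})

test_that("neutrality constraint rows encode sum_B n_B Q_AB = 0", {
  # water-like toy: 1 O-like + 2 H-like atoms
  atoms <- data.frame(type = c("OW", "HW", "HW"),
                      element = c("O", "H", "H"), mol = 1L)
  top <- topology(atoms, matrix(c(1L, 2L, 1L, 3L), ncol = 2, byrow = TRUE))
  spec <- build_parameter_spec(list(top))
  # minimal system with the right columns
  free <- spec[!spec$fixed, ]
  L <- matrix(1e-3, 3, nrow(free), dimnames = list(NULL, free$name))
  sys <- linear_system(L, numeric(3))
  sys2 <- add_neutrality_constraints(sys, list(top), weight = 2)
  crow <- sys2$L[grep("neutrality.*OW", sys2$provenance)[1], ]
  expect_equal(unname(crow["qq:HW-OW"]), 2)  # 2 H-like per molecule
  expect_equal(unname(crow["qq:OW-OW"]), 1)
  expect_equal(unname(crow["qq:HW-HW"]), 0)
  # a neutral charge set satisfies the constraint rows exactly
  prods <- products_from_charges(c(OW = -0.8, HW = 0.4))
  pvec <- setNames(numeric(ncol(sys2$L)), colnames(sys2$L))
  pvec[paste0("qq:", names(prods))] <- prods
  crows <- grepl("^neutrality", sys2$provenance)
  expect_lt(max(abs(sys2$L[crows, ] %*% pvec)), 1e-12)
  expect_error(add_neutrality_constraints(sys, list(top), weight = -1),
               "positive")
})

test_that("the SVD solver returns minimum-norm least-squares solutions", {
  # identity system
  sys <- linear_system(diag(3), c(1, -2, 3))
  expect_equal(unname(coef(solve_svd(sys))), c(1, -2, 3))
  # consistent overdetermined system: duplicated rows, exact solution
  L <- rbind(diag(2), diag(2))
  sys <- linear_system(L, c(5, 7, 5, 7))
  fit <- solve_svd(sys)
  expect_equal(unname(coef(fit)), c(5, 7))
  expect_equal(fit$residual_rms, 0, tolerance = 1e-12)
  # rank-deficient: duplicated column -> minimum-norm solution equals the
  # explicit pseudoinverse solution
  set.seed(42)
  L <- cbind(a = stats::rnorm(10), b = stats::rnorm(10))
  L <- cbind(L, c = L[, "b"])
  f <- stats::rnorm(10)
  fit <- solve_svd(linear_system(L, f))
  sv <- svd(L)
  keep <- sv$d > 1e-10 * sv$d[1]
  pinv <- sv$v[, keep] %*% diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep])
  expect_equal(unname(coef(fit)), as.numeric(pinv %*% f), tolerance = 1e-10)
  expect_equal(fit$rank, 2)
  expect_error(solve_svd(linear_system(matrix(0, 2, 2), c(0, 0))),
               "all-zero")
})

test_that("two-pass fit recovers the ground truth exactly without noise", {
  truth <- fx_truth()
  cl <- fx_butane_cluster()
  fit <- fm_fit(cl$confs, cl$top, truth)
  expect_lt(fit$pass1$residual_rms, 1e-8)
  expect_lt(fit$pass2$residual_rms, 1e-8)
  expect_lt(max_recovery_error(fit$forcefield), 1e-6)
  # hydrogen carries the positive charge
  expect_gt(fit$charges[["HC"]], 0)
})

test_that("two atom types make CMD exact: both passes agree", {
  truth <- fx_truth()
  top <- replicate_topology(fx_cyclopentane(), 2)
  confs <- generate_conformations(top, truth, n = 6, seed = 33)
  confs <- mock_reference_forces(confs, top, truth)
  fit <- fm_fit(confs, top, truth)
  # the neutrality-constrained products are rank-1 consistent for 2 types
  expect_lt(fit$cmd$reconstruction_error, 1e-8)
  # non-Coulombic parameters agree between the passes
  p1 <- coef(fit$pass1); p2 <- coef(fit$pass2)
  shared <- intersect(names(p2), names(p1))
  expect_equal(p1[shared], p2[shared], tolerance = 1e-8)
})

test_that("zero-charge truth leaves non-Coulombic parameters unchanged by pass 2", {
  truth <- fx_truth()
  truth$atom_types$charge <- c(0, 0, 0)
  top <- replicate_topology(fx_butane(), 2)
  confs <- generate_conformations(top, truth, n = 6, seed = 52)
  confs <- mock_reference_forces(confs, top, truth)
  # the all-zero product matrix makes the dominant eigenpair degenerate
  # and the tiny fitted charges can need a neutrality shift: both warn
  fit <- suppressWarnings(fm_fit(confs, top, truth))
  expect_equal(unname(fit$charges), c(0, 0, 0), tolerance = 1e-7)
  p1 <- coef(fit$pass1); p2 <- coef(fit$pass2)
  shared <- intersect(names(p2), names(p1))
  expect_equal(p1[shared], p2[shared], tolerance = 1e-7)
})

test_that("solved residual never exceeds the ground-truth residual", {
  truth <- fx_truth()
  top <- replicate_topology(fx_butane(), 2)
  confs <- generate_conformations(top, truth, n = 6, seed = 61)
  confs <- mock_reference_forces(confs, top, truth, sigma = 0.5, seed = 62)
  spec <- build_parameter_spec(list(top), fix_dispersion = fx_disp())
  sys <- build_design_matrix(confs, top, spec, truth)
  fit <- solve_svd(sys)
  p0 <- truth_parameter_vector(spec)
  rms_truth <- sqrt(mean((sys$f - as.numeric(sys$L %*% p0))^2))
  expect_lte(fit$residual_rms, rms_truth + 1e-8)
})

test_that("raising the neutrality weight barely moves a neutral system's fit", {
  truth <- fx_truth()
  cl <- fx_butane_cluster()
  f1 <- fm_fit(cl$confs, cl$top, truth, constraint_weight = 10)
  f2 <- fm_fit(cl$confs, cl$top, truth, constraint_weight = 1000)
  expect_equal(coef(f1$pass1), coef(f2$pass1), tolerance = 1e-6)
})

test_that("parameter error shrinks with more frames under force noise", {
  truth <- fx_truth()
  top <- replicate_topology(fx_butane(), 3)
  err_at <- function(n, seed) {
    confs <- generate_conformations(top, truth, n = n, seed = seed)
    confs <- mock_reference_forces(confs, top, truth, sigma = 0.4,
                                   seed = seed + 1)
    fit <- suppressWarnings(fm_fit(confs, top, truth))
    max_recovery_error(fit$forcefield)
  }
  seeds <- c(201, 301, 401)
  e_small <- vapply(seeds, function(s) err_at(15, s), numeric(1))
  e_large <- vapply(seeds, function(s) err_at(60, s), numeric(1))
  # 4x the frames should shrink the error (about 2x in expectation);
  # compare pooled RMS errors to absorb seed-to-seed fluctuation
  expect_lt(sqrt(mean(e_large^2)), sqrt(mean(e_small^2)))
})
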