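test_that("Langevin sampling is bitwise deterministic and sized correctly", {
  truth <- fx_truth()
  top <- fx_butane()
  a <- sample_conformations(truth, top, n_frames = 5, seed = 3, stride = 5)
  b <- sample_conformations(truth, top, n_frames = 5, seed = 3, stride = 5)
  expect_identical(lapply(a, `[[`, "coords"), lapply(b, `[[`, "coords"))
  d <- sample_conformations(truth, top, n_frames = 5, seed = 4, stride = 5)
  expect_false(identical(a[[1]]$coords, d[[1]]$coords))
  # the reference protocol: 100 frames at each of two temperatures
  two_T <- lapply(c(298, 328), function(Tk)
    sample_conformations(truth, top, T_kelvin = Tk, n_frames = 10,
                         seed = 5, stride = 2))
  expect_equal(length(do.call(c, two_T)), 20)
})

test_that("sampled bond-length fluctuations satisfy equipartition", {
  truth <- fx_truth()
  top <- fx_butane()
  c_idx <- which(top$atoms$element == "C")
  vars <- vapply(1:5, function(s) {
    confs <- sample_conformations(truth, top, T_kelvin = 298,
                                  n_frames = 120, seed = s, stride = 20,
                                  friction = 10)
    r <- vapply(confs, function(cf)
      sqrt(sum((cf$coords[c_idx[2], ] - cf$coords[c_idx[1], ])^2)),
      numeric(1))
    stats::var(r)
  }, numeric(1))
  k_cc <- truth$bonds$k[truth$bonds$key == "C2-C3"]
  theory <- 0.0019872041 * 298 / (2 * k_cc)
  expect_lt(abs(mean(vars) / theory - 1), 0.10)
})

test_that("unstable starting structures abort with a step message", {
  truth <- fx_truth()
  top <- fx_butane()
  bad <- ideal_geometry(top)
  bad$coords[1, ] <- bad$coords[5, ] + 1e-4  # fused atoms
  expect_error(sample_conformations(truth, top, n_frames = 2, seed = 1,
                                    start = bad),
               "unstable|overlap|divergence")
})

test_that("training clusters pick nearest neighbors and unwrap them", {
  truth <- fx_truth()
  liq <- make_liquid_start(fx_butane(), n_mol = 8, density = 580, seed = 2)
  frame <- sample_conformations(truth, liq$topology, n_frames = 1, seed = 3,
                                start = liq$start, stride = 5)[[1]]
  cl <- make_training_cluster(frame, liq$topology, n_molecules = 6, seed = 4)
  expect_equal(cl$topology$n_molecules, 6)
  expect_equal(nrow(cl$conformation$coords), 6 * n_atoms(fx_butane()))
  expect_length(cl$molecules, 6)
  # brute-force check: selected set equals the 6 molecules closest to the
  # seed molecule by minimum-image nearest-atom distance
  mols <- split(seq_len(n_atoms(liq$topology)), liq$topology$atoms$mol)
  set.seed(4); seed_mol <- sample.int(8, 1)
  dmin <- vapply(1:8, function(mi) {
    if (mi == seed_mol) return(0)
    best <- Inf
    for (i in mols[[seed_mol]]) for (j in mols[[mi]]) {
      d <- frame$coords[i, ] - frame$coords[j, ]
      d <- d - frame$box * round(d / frame$box)
      best <- min(best, sqrt(sum(d^2)))
    }
    best
  }, numeric(1))
  expect_setequal(cl$molecules, order(dmin)[1:6])
  # unwrapped: every selected molecule within one box length of the seed
  ctr <- colMeans(cl$conformation$coords[1:n_atoms(fx_butane()), ])
  expect_lt(max(abs(sweep(cl$conformation$coords, 2, ctr))),
            1.5 * max(frame$box))
  # a frame with exactly 6 molecules retains all of them
  liq6 <- make_liquid_start(fx_butane(), n_mol = 6, density = 500, seed = 5)
  fr6 <- conformation(liq6$start$coords, box = liq6$start$box)
  cl6 <- make_training_cluster(fr6, liq6$topology, n_molecules = 6)
  expect_setequal(cl6$molecules, 1:6)
  expect_error(make_training_cluster(fr6, liq6$topology, n_molecules = 7),
               "6 molecules")
})

test_that("the RDF normalizes an ideal gas to unity", {
  set.seed(8)
  n <- 400; box <- rep(20, 3)
  atoms <- data.frame(type = "Ar", element = "C", mol = seq_len(n))
  top <- topology(atoms, matrix(integer(0), ncol = 2))
  confs <- conformation_set(lapply(1:8, function(i)
    conformation(matrix(stats::runif(n * 3, 0, 20), n, 3), box = box)))
  r <- compute_rdf(confs, top, "Ar", "Ar", r_max = 9, n_bins = 18)
  keep <- r$r > 1
  # counting noise: ~3 sigma band around 1
  counts <- 8 * n * (n - 1) / 2 * 4 / 3 * pi * diff(r$edges^3) / prod(box)
  expect_true(all(abs(r$g[keep] - 1) < 3 / sqrt(counts[keep]) + 0.05))
})

test_that("two fixed atoms give a single occupied RDF bin at their distance", {
  atoms <- data.frame(type = "X", element = "C", mol = c(1L, 2L))
  top <- topology(atoms, matrix(integer(0), ncol = 2))
  conf <- conformation(rbind(c(0, 0, 0), c(5, 0, 0)), box = rep(40, 3))
  r <- compute_rdf(conformation_set(list(conf)), top, "X", "X",
                   r_max = 8, n_bins = 16)
  expect_equal(which(r$g > 0), 10)  # bin (4.5, 5]
})

test_that("RDF histogram agrees with a brute-force double loop", {
  truth <- fx_truth()
  liq <- make_liquid_start(fx_butane(), n_mol = 4, density = 500, seed = 9)
  confs <- sample_conformations(truth, liq$topology, n_frames = 5, seed = 10,
                                start = liq$start, stride = 5)
  r_max <- min(liq$start$box) / 2 * 0.95
  r <- compute_rdf(confs, liq$topology, "C", "C", r_max = r_max, n_bins = 12)
  # brute force
  c_idx <- which(liq$topology$atoms$element == "C")
  mol <- liq$topology$atoms$mol
  edges <- seq(0, r_max, length.out = 13)
  acc <- numeric(12)
  for (cf in confs) {
    counts <- numeric(12); npairs <- 0
    for (a in seq_along(c_idx)) for (b in seq_along(c_idx)) {
      i <- c_idx[a]; j <- c_idx[b]
      if (i >= j || mol[i] == mol[j]) next
      npairs <- npairs + 1
      d <- cf$coords[i, ] - cf$coords[j, ]
      d <- d - cf$box * round(d / cf$box)
      rr <- sqrt(sum(d^2))
      if (rr < r_max) {
        bin <- findInterval(rr, edges, left.open = TRUE)
        counts[bin] <- counts[bin] + 1
      }
    }
    shell <- 4 / 3 * pi * diff(edges^3)
    acc <- acc + counts / (npairs * shell / prod(cf$box))
  }
  expect_equal(r$g, acc / length(confs), tolerance = 1e-10)
})

test_that("RDF guards and distance metric behave", {
  truth <- fx_truth()
  liq <- make_liquid_start(fx_butane(), n_mol = 4, density = 500, seed = 9)
  confs <- sample_conformations(truth, liq$topology, n_frames = 2, seed = 1,
                                start = liq$start, stride = 2)
  expect_error(compute_rdf(confs, liq$topology, "C", "C",
                           r_max = min(liq$start$box)), "half the smallest")
  a <- compute_rdf(confs, liq$topology, "C", "C", r_max = 4, n_bins = 8)
  b <- a; b$g <- a$g + 0.1
  expect_equal(rdf_distance(a, a), 0)
  expect_equal(rdf_distance(a, b), 0.1, tolerance = 1e-12)
  expect_equal(rdf_distance(a, b), rdf_distance(b, a))
  cc <- compute_rdf(confs, liq$topology, "C", "C", r_max = 4, n_bins = 10)
  expect_error(rdf_distance(a, cc), "binning")
})
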