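# Shared fixtures, built in code and memoized so expensive objects are
# constructed once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fx_truth <- function() fixture("truth", alkane_ground_truth)

fx_butane <- function() fixture("butane", function() make_alkane_topology("n-butane"))
fx_pentane <- function() fixture("pentane", function() make_alkane_topology("n-pentane"))
fx_cyclopentane <- function() fixture("cyclopentane",
                                      function() make_alkane_topology("cyclopentane"))

# small noiseless training set: 2 n-butane molecules as a cluster
fx_butane_cluster <- function() fixture("butane_cluster", function() {
  top <- replicate_topology(fx_butane(), 2)
  confs <- generate_conformations(top, fx_truth(), n = 6, seed = 101)
  list(top = top, confs = mock_reference_forces(confs, top, fx_truth()))
})

# frozen dispersion table of the ground truth (carbon pairs)
fx_disp <- function() fixture("disp", function() {
  ff <- fx_truth()
  el <- setNames(ff$atom_types$element, ff$atom_types$name)
  carbon <- vapply(strsplit(ff$pairs$key, "-", fixed = TRUE),
                   function(t_) all(el[t_] == "C"), logical(1))
  data.frame(key = ff$pairs$key[carbon], C6 = ff$pairs$C6[carbon],
             C8 = ff$pairs$C8[carbon])
})

# the truth parameter vector laid out against a parameter spec
truth_parameter_vector <- function(spec, truth = fx_truth()) {
  free <- spec[!spec$fixed, ]
  q <- setNames(truth$atom_types$charge, truth$atom_types$name)
  p <- numeric(nrow(free))
  names(p) <- free$name
  for (i in seq_len(nrow(free))) {
    key <- free$key[i]
    ts <- strsplit(key, "-", fixed = TRUE)[[1]]
    p[i] <- switch(free$kind[i],
      qq = q[ts[1]] * q[ts[2]],
      A = truth$pairs$A[match(key, truth$pairs$key)],
      C6 = truth$pairs$C6[match(key, truth$pairs$key)],
      C8 = truth$pairs$C8[match(key, truth$pairs$key)],
      bond_k = truth$bonds$k[match(key, truth$bonds$key)],
      bond_kre = {
        j <- match(key, truth$bonds$key)
        truth$bonds$k[j] * truth$bonds$r0[j]
      },
      angle_k = truth$angles$k[match(key, truth$angles$key)],
      angle_kte = {
        j <- match(key, truth$angles$key)
        truth$angles$k[j] * truth$angles$theta0[j]
      },
      tors_A = truth$torsions$A[match(key, truth$torsions$key)])
  }
  p
}

# max relative error of every fitted force-field parameter vs the truth
max_recovery_error <- function(ff, truth = fx_truth(), cmd_charges = NULL) {
  ib <- match(ff$bonds$key, truth$bonds$key)
  ia <- match(ff$angles$key, truth$angles$key)
  it <- match(ff$torsions$key, truth$torsions$key)
  ip <- match(ff$pairs$key, truth$pairs$key)
  qs <- setNames(truth$atom_types$charge, truth$atom_types$name)
  qf <- setNames(ff$atom_types$charge, ff$atom_types$name)
  errs <- c(abs(ff$bonds$k / truth$bonds$k[ib] - 1),
            abs(ff$bonds$r0 / truth$bonds$r0[ib] - 1),
            abs(ff$angles$k / truth$angles$k[ia] - 1),
            abs(ff$angles$theta0 / truth$angles$theta0[ia] - 1),
            abs(ff$torsions$A / truth$torsions$A[it] - 1),
            abs(ff$pairs$A / truth$pairs$A[ip] - 1),
            abs(qf[names(qs)] / qs - 1))
  max(errs)
}

# random symmetric matrix with labels
random_symmetric <- function(n, labels = paste0("T", seq_len(n))) {
  m <- matrix(stats::rnorm(n * n), n, n)
  m <- (m + t(m)) / 2
  dimnames(m) <- list(labels, labels)
  m
}
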