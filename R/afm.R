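# The iterative AFM driver: sample -> reference forces -> fit -> RDF
# convergence check, then a global fit pooling the last generations.

#' Mock quantum-reference oracle
#'
#' Returns a reference-force oracle backed by a ground-truth force field:
#' a function `(confs, top) -> confs-with-forces` that evaluates the truth
#' model's analytic forces, optionally with Gaussian noise. The oracle
#' interface is pluggable so real electronic-structure outputs could be
#' substituted.
#'
#' @param truth ground-truth [forcefield()]
#' @param sigma force-noise SD (kcal/mol/A)
#' @param seed RNG seed for the noise
#' @return function of `(confs, top)`
#' @export
mock_reference_oracle <- function(truth, sigma = 0, seed = 1) {
  force(truth); force(sigma); force(seed)
  function(confs, top) mock_reference_forces(confs, top, truth,
                                             sigma = sigma, seed = seed)
}

#' Default AFM driver settings
#'
#' @param temperatures sampling temperatures (K); the reference protocol
#'   samples at 298 and 328 K
#' @param n_frames_per_T training frames per temperature (reference
#'   protocol: 100)
#' @param stride,dt,friction Langevin sampling controls
#'   (see [sample_conformations()])
#' @param rdf_pairs list of length-2 selector vectors tracked for
#'   convergence (default carbon-carbon)
#' @param r_max,n_bins RDF binning
#' @param tol RDF convergence tolerance (max-abs difference)
#' @param max_generations iteration cap
#' @param global_fit_last upper bound on generations pooled in the final
#'   global fit (reference protocol: 4)
#' @param constraint_weight,rcond passed to [fm_fit()]
#' @return settings list for [run_afm()]
#' @export
afm_settings <- function(temperatures = c(298, 328), n_frames_per_T = 100,
                         stride = 20, dt = 0.001, friction = 0.5,
                         rdf_pairs = list(c("C", "C")), r_max = 6,
                         n_bins = 40, tol = 0.05, max_generations = 6,
                         global_fit_last = 4, constraint_weight = NULL,
                         rcond = 1e-10) {
  as.list(environment())
}

#' Run the iterative AFM loop
#'
#' Each generation samples conformations with the current model (Langevin
#' dynamics at each configured temperature), obtains reference forces from
#' the oracle, and refits all parameters by the two-pass force match
#' ([fm_fit()]); dispersion coefficients stay frozen at their pre-fitted
#' values throughout. Convergence is declared when, for every tracked
#' pair, the RDF sampled under the newly fitted model (same seeds)
#' differs from the training RDF by less than `tol`. After convergence a
#' single global fit pools the training frames of up to the last
#' `global_fit_last` generations.
#'
#' @param init starting [forcefield()]
#' @param oracle reference-force oracle, e.g. [mock_reference_oracle()]
#' @param top multi-molecule [topology()]
#' @param start periodic starting [conformation()]
#'   (see [make_liquid_start()])
#' @param settings list from [afm_settings()]
#' @param dispersion optional data.frame (key, C6, C8) of frozen
#'   dispersion coefficients; defaults to `init`'s values
#' @param seed master seed; all per-generation sampling seeds derive from
#'   it
#' @return object of class `"afm_run"`: `forcefield` (global fit),
#'   `generations` (list of per-generation records), `converged`,
#'   `n_generations`
#' @export
run_afm <- function(init, oracle, top, start, settings = afm_settings(),
                    dispersion = NULL, seed = 1) {
  s <- settings
  current <- init
  gens <- list()
  converged <- FALSE
  pooled <- list()
  for (g in seq_len(s$max_generations)) {
    train <- list(); rdfs_train <- list(); metric <- NA_real_
    for (ti in seq_along(s$temperatures)) {
      train[[ti]] <- sample_conformations(
        current, top, T_kelvin = s$temperatures[ti],
        n_frames = s$n_frames_per_T, seed = seed + 97L * g + ti,
        start = start, dt = s$dt, friction = s$friction, stride = s$stride)
    }
    train <- do.call(c, train)
    train <- oracle(train, top)
    fit <- fm_fit(train, top, current, dispersion = dispersion,
                  constraint_weight = s$constraint_weight, rcond = s$rcond)
    new_ff <- fit$forcefield
    # convergence: resample with the fitted model under the same seeds and
    # compare the tracked RDFs with the training RDFs
    check <- do.call(c, lapply(seq_along(s$temperatures), function(ti)
      sample_conformations(new_ff, top, T_kelvin = s$temperatures[ti],
                           n_frames = s$n_frames_per_T,
                           seed = seed + 97L * g + ti, start = start,
                           dt = s$dt, friction = s$friction,
                           stride = s$stride)))
    dists <- vapply(s$rdf_pairs, function(pp) {
      ra <- compute_rdf(train, top, pp[1], pp[2], r_max = s$r_max,
                        n_bins = s$n_bins)
      rb <- compute_rdf(check, top, pp[1], pp[2], r_max = s$r_max,
                        n_bins = s$n_bins)
      rdfs_train[[length(rdfs_train) + 1L]] <<- ra
      rdf_distance(ra, rb)
    }, numeric(1))
    metric <- max(dists)
    pooled[[g]] <- train
    gens[[g]] <- list(generation = g, forcefield_sampling = current,
                      forcefield_fitted = new_ff, fit = fit,
                      rdfs = rdfs_train, metric = metric,
                      n_frames = length(train))
    current <- new_ff
    if (metric < s$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("AFM did not converge within %d generations (last RDF metric %.3g); returning best so far",
                    s$max_generations, gens[[length(gens)]]$metric))
  # global fit pooling frames of up to the last `global_fit_last` generations
  last <- max(1, length(pooled) - s$global_fit_last + 1)
  all_frames <- do.call(c, pooled[last:length(pooled)])
  global <- fm_fit(all_frames, top, current, dispersion = dispersion,
                   constraint_weight = s$constraint_weight, rcond = s$rcond)
  structure(list(forcefield = global$forcefield, global_fit = global,
                 generations = gens, converged = converged,
                 n_generations = length(gens)), class = "afm_run")
}

#' @export
print.afm_run <- function(x, ...) {
  cat("AFM run:", x$n_generations, "generation(s),",
      if (x$converged) "converged" else "NOT converged", "\n")
  for (g in x$generations)
    cat(sprintf("  gen %d: RDF metric %.4g, pass-2 residual RMS %.4g\n",
                g$generation, g$metric, g$fit$pass2$residual_rms))
  cat("Global fit pooled", length(x$generations), "generation(s)\n")
  invisible(x)
}

#' @export
coef.afm_run <- function(object, ...) coef(object$global_fit)
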