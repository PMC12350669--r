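# Heavy pipeline fixtures shared across test files, computed once per
# test run.  Scales are the test-budget study sizes: the reference
# protocol (8 SA + 5 LA, 0.25 mm pixels, r1 = 0.5) registered up to
# end-systole for the accuracy checks, and a coarser 0.4 mm / 6-frame
# variant for the multi-run cohort study.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

fx_phantom <- function() fx_cached("phantom", generate_phantom(phantom_spec()))

fx_run <- function(key, ...) {
  fx_cached(key, suppressWarnings(
    run_pipeline(phantom = fx_phantom(), frames = 5, ...)))
}

fx_sr <- function() fx_run("sr")                       # 8 SA + 5 LA, SR-O
fx_lr <- function() fx_run("lr", n_la = 0)             # conventional baseline
fx_sr3 <- function() fx_run("sr3", n_la = 3)           # 8 SA + 3 LA
fx_srr <- function() fx_run("srr", la_mode = "radial") # SR-R

# five jittered phantoms (geometry/motion perturbed), SR and LR pipelines
# at a reduced scale
fx_cohort <- function() fx_cached("cohort", {
  lapply(1:5, function(i) {
    set.seed(300 + i)
    sp <- phantom_spec(
      r_endo = 1.5 * runif(1, 0.95, 1.05),
      r_epi = 3.2 * runif(1, 0.95, 1.05),
      eps_c = 0.13 * runif(1, 0.9, 1.1),
      eps_z = 0.15 * runif(1, 0.9, 1.1),
      n_frames = 6, seed = 500 + i)
    ph <- generate_phantom(sp)
    list(phantom = ph,
         sr = suppressWarnings(run_pipeline(phantom = ph,
                                            pixel_spacing = 0.4)),
         lr = suppressWarnings(run_pipeline(phantom = ph, n_la = 0,
                                            pixel_spacing = 0.4)))
  })
})
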