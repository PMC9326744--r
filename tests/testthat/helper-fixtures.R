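# Shared fixtures: all built in code, nothing on disk.

# default noise-free phantom, cached per test run
noiseFreePhantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generatePhantom(phantomSpec(noise_sd = 0))
    cache
  }
})

# single right-kidney spec on an isotropic 1 mm grid (oracle-friendly)
singleKidneySpec <- function(semiaxes = c(20, 15, 30),
                             grid = c(48L, 40L, 70L)) {
  phantomSpec(grid_shape = grid, spacing_mm = c(1, 1, 1),
              organ_params = list(right_kidney = list(
                center = c(-2, 0, 0), semiaxes = semiaxes, intensity = 0.45)),
              cyst_params = list(right_kidney = list(
                count = 0L, radius_mm = c(2, 4), intensity = 1)),
              noise_sd = 0)
}

# small random label map for IO round trips
randomLabelMap <- function(dims = c(16L, 12L, 5L), spacing = c(1.5, 2, 3.3),
                           seed = 7) {
  set.seed(seed)
  LabelMap(array(sample(0:4, prod(dims), replace = TRUE), dims),
           spacing = spacing)
}

# an untrained checkpoint usable by inferOrgan/runEnsemble in plumbing tests
untrainedCheckpoint <- function(organ = "kidney", seed = 1) {
  m <- buildOrganModel(organ, preset = "tiny", seed = seed)
  pp <- preprocessConfig(infer_size = 64L)
  new("OrganCheckpoint", organ = organ, arch = m$arch, params = m$params,
      preprocess = unclass(pp), bestDSC = 0, bestEpoch = 0L,
      log = data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_dsc = numeric(0)))
}
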