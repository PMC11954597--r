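# shared fixtures: built in code, kept small

# homogeneous block phantom for transport tests
homog_block <- function(n = c(50L, 50L, 50L), h = 0.04, label = 1L) {
  lab <- array(label, dim = n)
  attr(lab, "voxel") <- h
  lab
}

# short-duration config for pipeline tests (full sampling rate, fewer windows)
quick_config <- function(duration = 30, replicates = 2L, seed = 11L, ...) {
  experiment_config(pulsatile = pulsatile_config(duration = duration),
                    replicates = replicates, seed = seed, ...)
}

# reference tumor curves at the study parameters (cached per session)
study_curves <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      kp <- kinetic_params()
      kp0 <- kinetic_params(kon = 0)
      cache <<- list(
        tar = tumor_model(pif_aby029(), kp),
        con_eq = tumor_model(pif_aby029(), kp0),
        con_df = tumor_model(pif_irdye680lt(), kp0))
    }
    cache
  }
})
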