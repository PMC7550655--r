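# Shared fixtures, all built in code.

base_tumor_truth <- function() {
  ivimParams(S0 = 1000, D = 0.556e-3, Dstar = 8.53e-3, f = 0.1675)
}

# region parameters with zero voxelwise heterogeneity (deterministic truth)
constant_region <- function(S0 = 1000, D = 0.556e-3, Dstar = 8.53e-3,
                            f = 0.1675, R2star = 24.74) {
  regionParams(mean = c(S0 = S0, D = D, Dstar = Dstar, f = f,
                        R2star = R2star),
               sd = c(S0 = 0, D = 0, Dstar = 0, f = 0, R2star = 0))
}

small_phantom <- function(tumor = defaultTumorParams()) {
  phantomSpec(grid = c(10L, 10L, 6L), center = c(4.5, 4.5, 2.5),
              semi_axes = c(3, 3, 2), tumor = tumor,
              background = constant_region(S0 = 600, D = 1.1e-3,
                                           Dstar = 6e-3, f = 0.05,
                                           R2star = 30))
}

no_noise <- function() noiseSpec("none", 0)
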