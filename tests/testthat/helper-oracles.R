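# brute-force oracle for the perfusion step: exhaustive D* x f lattice with
# the closed-form optimal scale at each lattice point, then one local zoom
# of the lattice around the coarse argmin so lattice quantisation does not
# dominate the comparison
grid_search_rss <- function(signal, protocol, D_fixed,
                            n_Dstar = 200L, n_f = 101L) {
  b <- bValues(protocol)
  sweep_ <- function(Dstar_grid, f_grid) {
    best <- Inf; arg <- c(NA, NA)
    for (Ds in Dstar_grid) for (f in f_grid) {
      m <- (1 - f) * exp(-b * D_fixed) + f * exp(-b * Ds)
      S0 <- sum(signal * m) / sum(m^2)
      rss <- sum((signal - S0 * m)^2)
      if (rss < best) { best <- rss; arg <- c(f, Ds) }
    }
    list(rss = best, f = arg[1L], Dstar = arg[2L])
  }
  Dstar_grid <- exp(seq(log(D_fixed * 1.01), log(0.2), length.out = n_Dstar))
  f_grid <- seq(0, 1, length.out = n_f)
  coarse <- sweep_(Dstar_grid, f_grid)
  step_Ds <- log(Dstar_grid[2L]) - log(Dstar_grid[1L])
  step_f <- f_grid[2L] - f_grid[1L]
  fine <- sweep_(
    exp(seq(log(coarse$Dstar) - step_Ds, log(coarse$Dstar) + step_Ds,
            length.out = 41L)),
    seq(max(0, coarse$f - step_f), min(1, coarse$f + step_f),
        length.out = 41L))
  min(coarse$rss, fine$rss)
}
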