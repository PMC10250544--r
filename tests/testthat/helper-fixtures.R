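# Shared fixtures, built once per test run. Everything is generated in
# code under fixed seeds; no files are read.

# small autocorrelated two-layer landscape reused across modules
fix_landscape <- local({
  st <- NULL
  function() {
    if (is.null(st)) {
      st <<- make_landscape(landscape_spec(
        60, 60, cell_size = 1, n_layers = 2, autocorr_range = 5, seed = 7))
    }
    st
  }
})

# two moderately separated Gaussian niches in 2-D environment space
fix_species_pair <- function() {
  list(a = virtual_species(c(0.4, 0.3), diag(c(0.25, 0.25)), label = "a"),
       b = virtual_species(c(-0.4, -0.3), diag(c(0.25, 0.25)), label = "b"))
}

# uniform environmental background cloud for direct E-space tests
fix_uniform_bg <- function(n = 4000, lim = 3, seed = 99) {
  set.seed(seed)
  cbind(runif(n, -lim, lim), runif(n, -lim, lim))
}

# degenerate "posterior" whose every draw is exactly (mu, Sigma); used to
# test the overlap integrator against closed-form oracles without data noise
fixed_ellipsoid_niche <- function(mu, Sigma, n_draws = 2000) {
  k <- length(mu)
  structure(
    list(mu = matrix(rep(mu, each = n_draws), n_draws, k),
         Sigma = array(rep(as.matrix(Sigma), n_draws), c(k, k, n_draws)),
         n_draws = n_draws, k = k,
         data_summary = list(n = Inf, mean = mu, cov = as.matrix(Sigma))),
    class = "ellipsoid_niche")
}

# unit cube corner points in 3-D
cube_points <- function(offset = c(0, 0, 0)) {
  sweep(as.matrix(expand.grid(0:1, 0:1, 0:1)), 2, offset, `+`)
}
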