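# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# full default thorax, noise-free
thorax_default <- function() {
  fixture("thorax_default", function() make_thorax(phantom_spec(seed = 1L)))
}

# symmetric lungs-only phantom (no heart; left/right mirror images)
thorax_lungs_only <- function() {
  fixture("thorax_lungs_only", function()
    make_thorax(phantom_spec(include_heart = FALSE, seed = 2L)))
}

# compact heart-only phantom at 2 mm for cavity segmentation tests
heart_only <- function(noise_sigma = 0, ef = 35, seed = 7L) {
  key <- sprintf("heart_%g_%g_%d", noise_sigma, ef, seed)
  fixture(key, function()
    make_thorax(phantom_spec(shape = c(76, 60, 76), spacing = c(2, 2, 2),
                             true_rv_edv = 150,
                             true_rv_esv = 150 * (1 - ef / 100),
                             include_lungs = FALSE,
                             noise_sigma = noise_sigma, seed = seed)))
}

# small arbitrary-valued grid for I/O and masked-statistic tests
random_grid <- function(dims = c(7, 6, 5), seed = 42,
                        spacing = c(1.5, 2, 2.5), origin = c(-3, 0, 4.5)) {
  set.seed(seed)
  voxel_grid(array(rnorm(prod(dims)), dims), spacing = spacing,
             origin = origin)
}

# random binary mask with at least one voxel set
random_mask <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  v <- array(as.numeric(runif(length(grid$values)) < p), dim(grid$values))
  if (sum(v) == 0) v[1] <- 1
  voxel_grid(v, spacing = grid$spacing, origin = grid$origin)
}
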