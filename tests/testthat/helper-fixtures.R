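# Shared fixtures: everything is generated in code at test time.

# small, fast model used across decoder/training tests
tiny_test_model <- function(side = 64L, latent_width = 16L, hidden = c(64L, 64L),
                            seed = 1L) {
  efanet_model("tiny", latent_width = latent_width, hidden = hidden,
               input_side = side, seed = seed)
}

# a small phantom batch at model resolution
phantom_batch <- function(n = 4L, side = 64L, raw_side = 128L, seed = 7L, ...) {
  spec <- phantom_spec(n_samples = n, side = raw_side, seed = seed, ...)
  phantom_tensors(spec, side = side)
}

# random latent grids for decoder unit tests
random_grids <- function(dims = c(16L, 8L, 4L, 2L, 2L), C = 5L, seed = 99L) {
  set.seed(seed)
  lapply(seq_along(dims), function(i) {
    latent_grid(array(rnorm(dims[i]^2 * C), c(dims[i], dims[i], C)), level = i)
  })
}

# independent brute-force nearest-code search with the documented tie rule:
# smallest Euclidean distance, ties to smallest row then smallest column
brute_nearest <- function(grid, x_q) {
  d <- dim(grid$codes)
  best <- NULL
  best_d <- Inf
  for (r in seq_len(d[1])) {
    for (cc in seq_len(d[2])) {
      dist <- (x_q[1] - grid$row_coords[r])^2 + (x_q[2] - grid$col_coords[cc])^2
      if (dist < best_d - 1e-15) {
        best_d <- dist
        best <- c(r, cc)
      }
    }
  }
  best
}
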