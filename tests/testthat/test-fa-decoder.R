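# Feature-alignment decoder: coordinate frame, nearest-code lookup with the
# documented tie rule, sinusoidal encoding, and grid decoding.

test_that("latent coordinates are pixel centers in (0,1)^2", {
  expect_equal(pixel_centers(2), c(0.25, 0.75))
  g <- latent_grid(array(0, c(8, 8, 3)), level = 5)
  expect_length(g$row_coords, 8)
  expect_true(all(g$row_coords > 0 & g$row_coords < 1))
  expect_equal(g$row_coords[1], 0.5 / 8)
  # 64 coordinate pairs for a side-8 level
  expect_equal(length(g$row_coords) * length(g$col_coords), 64)
})

test_that("projection with identity weights returns the input features", {
  pyr <- structure(lapply(1:5, function(i) {
    side <- 2^(6 - i)
    list(values = array(rnorm(side * side * 4), c(side, side, 4)),
         level = i, stride = 2^i, channels = 4L)
  }), class = "feature_pyramid")
  proj <- lapply(1:5, function(i) list(W = diag(4), b = numeric(4)))
  grids <- project_to_latents(pyr, latent_width = 4L, proj = proj)
  for (i in 1:5) {
    expect_equal(grids[[i]]$codes, pyr[[i]]$values)
  }
  expect_error(project_to_latents(pyr[1:4]), "5-level")
})

test_that("nearest_latent matches brute-force search on all grid sizes up to 16", {
  set.seed(21)
  for (side in c(1:8, 12, 16)) {
    g <- latent_grid(array(rnorm(side * side * 2), c(side, side, 2)))
    queries <- matrix(runif(60), 30, 2)
    for (k in seq_len(nrow(queries))) {
      got <- nearest_latent(g, queries[k, ])
      expect_equal(got$index, brute_nearest(g, queries[k, ]))
    }
  }
  # 1000 random queries on one grid
  g <- latent_grid(array(rnorm(9 * 9 * 2), c(9, 9, 2)))
  queries <- matrix(runif(2000), 1000, 2)
  got_idx <- t(apply(queries, 1, function(q) nearest_latent(g, q)$index))
  ora_idx <- t(apply(queries, 1, function(q) brute_nearest(g, q)))
  expect_equal(got_idx, ora_idx)
})

test_that("exact hits and four-way ties follow the documented rules", {
  g <- latent_grid(array(seq_len(4 * 4 * 2), c(4, 4, 2)))
  # query exactly at a code coordinate
  hit <- nearest_latent(g, c(g$row_coords[2], g$col_coords[3]))
  expect_equal(hit$index, c(2, 3))
  expect_equal(hit$delta, c(0, 0))
  expect_equal(hit$z_star, g$codes[2, 3, ])
  # center of four codes: top-left wins
  mid <- nearest_latent(g, c(2 / 4, 3 / 4))
  expect_equal(mid$index, c(2, 3))
  expect_error(nearest_latent(g, c(1.5, 0.2)), "0,1")
})

test_that("offset magnitudes are bounded by half a cell", {
  set.seed(22)
  for (side in c(2, 5, 8)) {
    g <- latent_grid(array(0, c(side, side, 1)))
    queries <- matrix(runif(400), 200, 2)
    for (k in seq_len(nrow(queries))) {
      d <- nearest_latent(g, queries[k, ])$delta
      expect_true(all(abs(d) <= 0.5 / side + 1e-12))
    }
  }
})

test_that("position encoding matches the sinusoid formula with omega_l = 2 e^l", {
  spec <- pe_spec(L = 8)
  expect_equal(spec$omega, 2 * exp(1:8))
  # zero offset: alternating (0, 1)
  z <- position_encode(c(0, 0), spec)
  expect_equal(z, rep(c(0, 1), 16))
  # quarter period of the first band in one component
  u <- pi / (2 * spec$omega[1])
  v <- position_encode(c(u, 0), spec)
  expect_equal(v[1:2], c(1, 0), tolerance = 1e-12)
  # random offsets against an independently coded evaluation
  set.seed(23)
  for (k in 1:50) {
    delta <- runif(2, -0.5, 0.5)
    got <- position_encode(delta, spec)
    expected <- unlist(lapply(1:2, function(comp) {
      as.vector(rbind(sin(2 * exp(1:8) * delta[comp]),
                      cos(2 * exp(1:8) * delta[comp])))
    }))
    expect_equal(got, expected, tolerance = 1e-12)
    expect_true(all(abs(got) <= 1))
  }
  expect_length(position_encode(c(0.1, 0.2), pe_spec(L = 3)), 12)
  expect_error(pe_spec(L = 0), "L must be")
})

test_that("decoder input width follows 5 (C + 4L + 2) and level order matters", {
  cfg <- decoder_mlp_config(latent_width = 64L, pe = pe_spec(L = 8))
  expect_equal(cfg$input_width, 5 * (64 + 32 + 2))
  expect_equal(cfg$input_width, 490)

  grids <- random_grids(C = 3L)
  spec <- pe_spec(L = 2)
  set.seed(30)
  Wmat <- matrix(rnorm(5 * (3 + 8 + 2) * 2, sd = 0.3), 5 * 13, 2)
  mlp <- function(X) X %*% Wmat
  x_q <- c(0.31, 0.77)
  base <- decode_point(x_q, grids, spec, mlp)
  swapped <- decode_point(x_q, grids[c(2, 1, 3, 4, 5)], spec, mlp)
  expect_false(isTRUE(all.equal(base, swapped)))
  # explicit concatenation oracle
  concat <- unlist(lapply(grids, function(g) {
    nc <- nearest_latent(g, x_q)
    c(nc$z_star, position_encode(nc$delta, spec), nc$delta)
  }))
  expect_equal(base, as.vector(concat %*% Wmat))
})

test_that("alignment identity: decoding at a code's own coordinate returns the code", {
  grids <- random_grids(dims = c(16L, 8L, 4L, 2L, 2L), C = 4L)
  spec <- pe_spec(L = 2)
  C <- 4L; span <- C + 4L * spec$L + 2L
  for (lev in 1:5) {
    # identity read-out slicing out level lev's latent block
    sel <- matrix(0, 5 * span, C)
    sel[(lev - 1L) * span + seq_len(C), ] <- diag(C)
    mlp <- function(X) X %*% sel
    g <- grids[[lev]]
    for (r in seq_len(dim(g$codes)[1])) {
      for (cc in seq_len(dim(g$codes)[2])) {
        out <- decode_point(c(g$row_coords[r], g$col_coords[cc]), grids, spec, mlp)
        expect_equal(out, g$codes[r, cc, ], tolerance = 1e-14)
      }
    }
  }
})

test_that("decode_grid equals a per-point loop and supports any resolution", {
  grids <- random_grids(dims = c(8L, 4L, 2L, 2L, 2L), C = 3L)
  spec <- pe_spec(L = 2)
  set.seed(31)
  W1 <- matrix(rnorm(5 * 13 * 4, sd = 0.4), 65, 4)
  W2 <- matrix(rnorm(4 * 2, sd = 0.4), 4, 2)
  mlp <- function(X) pmax(X %*% W1, 0) %*% W2
  out <- decode_grid(grids, spec, mlp, target_shape = c(6, 5))
  expect_equal(dim(out), c(6L, 5L, 2L))
  for (i in 1:6) for (j in 1:5) {
    pt <- decode_point(c((i - 0.5) / 6, (j - 0.5) / 5), grids, spec, mlp)
    expect_equal(out[i, j, ], pt, tolerance = 1e-5)
  }
  # chunked evaluation agrees with single-block
  out2 <- decode_grid(grids, spec, mlp, target_shape = c(6, 5), chunk = 7L)
  expect_equal(out, out2)
  # different resolutions from the same grids
  expect_equal(dim(decode_grid(grids, spec, mlp, target_shape = c(12, 12))), c(12L, 12L, 2L))
  expect_equal(dim(decode_grid(grids, spec, mlp, target_shape = c(3, 9))), c(3L, 9L, 2L))
})

test_that("decoding is a pure function of the query coordinate across grids", {
  grids <- random_grids(dims = c(8L, 4L, 2L, 2L, 2L), C = 3L)
  spec <- pe_spec(L = 2)
  set.seed(32)
  W1 <- matrix(rnorm(65 * 2, sd = 0.4), 65, 2)
  mlp <- function(X) X %*% W1
  qs <- matrix(runif(40), 20, 2)
  a <- decode_grid(grids, spec, mlp, queries = qs)
  b <- t(apply(qs, 1, function(q) decode_point(q, grids, spec, mlp)))
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("predict_mask is per-pixel argmax with ties to background", {
  logits <- array(0, c(4, 4, 2))
  logits[, , 1] <- 5
  expect_equal(predict_mask(logits), matrix(0L, 4, 4))
  # exact ties -> class 0
  expect_equal(predict_mask(array(1, c(3, 3, 2))), matrix(0L, 3, 3))
  set.seed(33)
  lg <- array(rnorm(6 * 7 * 2), c(6, 7, 2))
  got <- predict_mask(lg)
  for (i in 1:6) for (j in 1:7) {
    expect_equal(got[i, j], as.integer(which.max(lg[i, j, ]) - 1L))
  }
})
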