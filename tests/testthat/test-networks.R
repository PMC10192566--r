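# The layer engine has no reference implementation to lean on, so every
# layer's backward pass is checked against central finite differences.

check_layers <- function(layers, x, tol = 1e-6) {
  lossfun <- function(out) sum(out^2) / 2
  out <- seizefuse:::net_forward(layers, x, train = FALSE)
  gin <- seizefuse:::net_backward(layers, out)
  gnum <- num_grad(function(xx) lossfun(seizefuse:::net_forward(layers, xx, FALSE)), x)
  expect_lt(max(abs(gin - gnum)) / max(1e-8, max(abs(gnum))), tol)
  for (e in seizefuse:::net_params(layers)) {
    p0 <- e$layer[[e$name]]
    f <- function(v) {
      e$layer[[e$name]] <- array(v, if (is.null(dim(p0))) length(p0) else dim(p0))
      r <- lossfun(seizefuse:::net_forward(layers, x, FALSE))
      e$layer[[e$name]] <- p0
      r
    }
    gnum <- num_grad(f, p0)
    seizefuse:::net_backward(layers,
                             seizefuse:::net_forward(layers, x, FALSE))
    ga <- e$layer[[paste0("g_", e$name)]]
    expect_lt(max(abs(ga - gnum)) / max(1e-8, max(abs(gnum))), tol)
  }
}

test_that("every layer type backpropagates exact gradients", {
  set.seed(1)
  check_layers(list(seizefuse:::layer_dense(5, 3), seizefuse:::layer_relu()),
               matrix(rnorm(4 * 5), 4, 5))
  check_layers(list(seizefuse:::layer_conv1d(3, 4), seizefuse:::layer_relu(),
                    seizefuse:::layer_maxpool1d()),
               array(rnorm(2 * 3 * 8), c(2, 3, 8)))
  check_layers(list(seizefuse:::layer_conv2d(2, 3),
                    seizefuse:::layer_maxpool2d()),
               array(rnorm(2 * 2 * 6 * 5), c(2, 2, 6, 5)))
  check_layers(list(seizefuse:::layer_bilstm(3, 4)),
               array(rnorm(2 * 6 * 3), c(2, 6, 3)))
})

test_that("softmax + cross-entropy gradient matches finite differences", {
  set.seed(2)
  xl <- matrix(rnorm(5 * 4), 5, 4)
  labs <- sample(0:3, 5, TRUE)
  sm <- seizefuse:::layer_softmax()
  p <- sm$forward(xl)
  ga <- sm$backward(seizefuse:::ce_grad_probs(p, labs))
  gnum <- num_grad(function(z) {
    pp <- exp(z - apply(z, 1, max)); pp <- pp / rowSums(pp)
    seizefuse:::ce_from_probs(pp, labs)
  }, xl)
  expect_lt(max(abs(ga - gnum)) / max(abs(gnum)), 1e-6)
})

test_that("branch outputs have the contracted shapes and normalization", {
  set.seed(4)
  cfg <- compact_branch_config()
  br <- build_eeg_branch(cfg, 8, 64)
  x <- array(rnorm(8 * 8 * 64), c(8, 8, 64))
  out <- branch_forward(br, x)
  expect_equal(dim(out$features), c(8, cfg$feature_dim))
  expect_equal(dim(out$prob), c(8, 2))
  expect_equal(rowSums(out$prob), rep(1, 8))
  expect_true(all(out$prob > 0 & out$prob < 1))

  br2 <- build_ecg_branch(cfg, 32, 16)
  s <- array(rnorm(8 * 32 * 16), c(8, 32, 16))
  out2 <- branch_forward(br2, s)
  expect_equal(dim(out2$prob), c(8, 2))
  expect_equal(rowSums(out2$prob), rep(1, 8))

  # all-zero input stays finite
  z <- branch_forward(br, array(0, c(2, 8, 64)))
  expect_true(all(is.finite(z$prob)))
})

test_that("construction is deterministic under a fixed seed", {
  cfg <- compact_branch_config()
  set.seed(9); a <- build_eeg_branch(cfg, 8, 64)
  set.seed(9); b <- build_eeg_branch(cfg, 8, 64)
  expect_identical(seizefuse:::net_get_params(a$extractor),
                   seizefuse:::net_get_params(b$extractor))
  expect_identical(seizefuse:::net_get_params(a$head),
                   seizefuse:::net_get_params(b$head))
})

test_that("eval-mode outputs are batch-independent", {
  set.seed(5)
  cfg <- compact_branch_config()
  br <- build_ecg_branch(cfg, 32, 16)
  s <- array(rnorm(6 * 32 * 16), c(6, 32, 16))
  full <- branch_forward(br, s)$prob
  halves <- rbind(branch_forward(br, s[1:3, , , drop = FALSE])$prob,
                  branch_forward(br, s[4:6, , , drop = FALSE])$prob)
  expect_equal(full, halves, tolerance = 1e-12)
})

test_that("parameter counts are pure functions of the configuration", {
  set.seed(1)
  cfg <- compact_branch_config()
  expect_equal(n_parameters(build_eeg_branch(cfg, 8, 64)), 4242)
  expect_equal(n_parameters(build_ecg_branch(cfg, 32, 16)), 2846)
  expect_equal(n_parameters(build_discriminator(cfg)), 306)
  expect_equal(n_parameters(build_eeg_branch(branch_config(), 29, 512)),
               353026)
})

test_that("configuration invariants are enforced", {
  expect_error(branch_config(conv1d_channels = c(8, 8, 8)), "length 4")
  expect_error(branch_config(conv2d_channels = c(8, 8, 8)), "length 5")
  expect_error(branch_config(fc_sizes = c(16, 8, 2)), "length 2")
  expect_error(branch_config(dropout = 1), "dropout")
  expect_error(build_eeg_branch(compact_branch_config(), 8, 8),
               "pooling")
})

test_that("shape mismatches give constructive errors", {
  set.seed(6)
  br <- build_eeg_branch(compact_branch_config(), 8, 64)
  bad <- array(rnorm(2 * 5 * 64), c(2, 5, 64))
  expect_error(seizefuse:::net_forward(br$extractor, bad), "expected")
})

test_that("gradient reversal is the identity forward and -lambda backward", {
  g <- gradient_reversal(1)
  x <- matrix(rnorm(12), 3, 4)
  expect_identical(g$forward(x), x)
  expect_equal(g$backward(x), -x)
  expect_equal(gradient_reversal(0)$backward(x), 0 * x)
  expect_error(gradient_reversal(-1), "lambda")
})
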