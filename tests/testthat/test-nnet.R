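tiny_cfg <- function(...) {
  net_config(n_stages = 1, base_channels = 4, in_channels = 1, out_channels = 1,
             patch_size = c(8, 8, 8), head = "regression", ...)
}

test_that("configuration invariants are enforced, naming the offending axis", {
  expect_error(net_config(n_stages = 3, patch_size = c(32, 30, 32)), "axis 2")
  cfg <- net_config(n_stages = 3, patch_size = c(32, 32, 32))
  expect_s3_class(cfg, "cortrec_net_config")
})

test_that("a 1-stage network is a conv stack preserving shape", {
  net <- build_network(tiny_cfg(), seed = 2)
  x <- array(rnorm(8^3), c(8, 8, 8, 1))
  out <- cortrec:::net_forward(net, x)$out
  expect_equal(dim(out), c(8, 8, 8, 1))
})

test_that("segmentation outputs are voxel-wise probabilities, regression unbounded", {
  scfg <- net_config(n_stages = 2, base_channels = 4, in_channels = 1,
                     out_channels = 3, patch_size = c(8, 8, 8), head = "segmentation")
  snet <- build_network(scfg, seed = 3)
  img <- volume(array(rnorm(8^3), c(8, 8, 8)), diag(4))
  p <- predict_sliding(snet, img)
  sums <- apply(p, c(1, 2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  rnet <- build_network(tiny_cfg(), seed = 4)
  big <- volume(array(1e4 * rnorm(8^3), c(8, 8, 8)), diag(4))
  out <- predict_sliding(rnet, big)
  expect_true(any(out$data > 1 | out$data < 0))
})

test_that("analytic gradients match finite differences on a micro network", {
  cfg <- net_config(n_stages = 2, base_channels = 2, in_channels = 1,
                    out_channels = 1, patch_size = c(4, 4, 4), head = "regression")
  net <- build_network(cfg, seed = 5)
  x <- array(rnorm(64), c(4, 4, 4, 1))
  tgt <- array(rnorm(64), c(4, 4, 4))
  fw <- cortrec:::net_forward(net, x, cache = TRUE)
  ls <- cortrec:::net_loss(cfg, fw$out, tgt)
  g <- cortrec:::net_backward(net, fw$cache, ls$gout)
  # convolutions run in single precision, so finite differences need a wide
  # step and a correspondingly loose tolerance
  eps <- 1e-3
  for (nm in c("enc1", "dec1", "head")) {
    for (slot in seq_len(min(3, length(net$weights[[nm]]$w)))) {
      net2 <- net
      net2$weights[[nm]]$w[slot] <- net2$weights[[nm]]$w[slot] + eps
      l2 <- cortrec:::net_loss(cfg, cortrec:::net_forward(net2, x)$out, tgt)$loss
      net2$weights[[nm]]$w[slot] <- net2$weights[[nm]]$w[slot] - 2 * eps
      l1 <- cortrec:::net_loss(cfg, cortrec:::net_forward(net2, x)$out, tgt)$loss
      expect_lt(abs((l2 - l1) / (2 * eps) - g[[nm]]$w[slot]),
                5e-3 * max(1, abs(g[[nm]]$w[slot])))
    }
  }
})

test_that("zero-epoch training returns unchanged weights", {
  net <- build_network(tiny_cfg(), seed = 6)
  ds <- list(list(input = array(0.5, c(8, 8, 8, 1)), target = array(0.1, c(8, 8, 8))))
  out <- train_network(net, ds, train_config(max_epochs = 0, convergence_window = 0))
  expect_identical(out$weights, net$weights)
})

test_that("loss decreases monotonically on a tiny constant-target problem", {
  net <- build_network(tiny_cfg(), seed = 7)
  set.seed(1)
  ds <- list(list(input = array(rnorm(8^3, 1, 0.1), c(8, 8, 8, 1)),
                  target = array(0.4, c(8, 8, 8))))
  out <- train_network(net, ds, train_config(batch_size = 1, max_epochs = 10,
                                             convergence_window = 10, seed = 2))
  expect_true(all(diff(out$training_log$loss) < 0))
})

test_that("the recorded learning-rate schedule is the closed form", {
  net <- build_network(tiny_cfg(), seed = 8)
  ds <- list(list(input = array(0.1, c(8, 8, 8, 1)), target = array(0, c(8, 8, 8))))
  tc <- train_config(batch_size = 1, initial_lr = 1e-3, lr_decrement_per_epoch = 1e-6,
                     max_epochs = 120, convergence_window = 120,
                     convergence_tolerance = 0)
  out <- train_network(net, ds, tc)
  expect_equal(out$training_log$lr, 1e-3 - out$training_log$epoch * 1e-6)
  expect_equal(out$training_log$lr[out$training_log$epoch == 100], 9e-4)
})

test_that("training rejects mismatched grids and reports divergence", {
  net <- build_network(tiny_cfg(), seed = 9)
  bad <- list(list(input = array(0, c(8, 8, 8, 1)), target = array(0, c(4, 8, 8))))
  expect_error(train_network(net, bad, train_config(max_epochs = 1,
                                                    convergence_window = 1)), "grid")
  blow <- build_network(tiny_cfg(), seed = 10)
  ds <- list(list(input = array(1e30, c(8, 8, 8, 1)), target = array(0, c(8, 8, 8))))
  expect_error(train_network(blow, ds, train_config(max_epochs = 3, convergence_window = 1,
                                                    initial_lr = 1e10)), "loss")
})

test_that("sliding-window prediction blends consistently", {
  cfg <- tiny_cfg()
  net <- build_network(cfg, seed = 11)
  # patch-sized input: single window equals a direct forward pass
  img <- volume(array(rnorm(8^3), c(8, 8, 8)), diag(4))
  direct <- cortrec:::net_forward(net, array(img$data, c(8, 8, 8, 1)))$out
  slid <- predict_sliding(net, img)
  expect_equal(slid$data, array(direct, c(8, 8, 8)), tolerance = 1e-12)
  # constant-output model: zero all weights, set head bias
  cnet <- net
  for (nm in names(cnet$weights)) cnet$weights[[nm]]$w[] <- 0
  cnet$weights$head$b <- 1.75
  big <- volume(array(rnorm(20 * 11 * 9), c(20, 11, 9)), diag(4))
  out <- predict_sliding(cnet, big)
  expect_true(all(abs(out$data - 1.75) < 1e-12))
  # stride-translation equivariance away from window boundaries
  set.seed(3)
  base <- array(rnorm(24 * 8 * 8), c(24, 8, 8))
  shift <- 4  # one full stride of the 8-voxel patch
  v1 <- volume(base, diag(4))
  shifted <- base
  shifted[(shift + 1):24, , ] <- base[1:(24 - shift), , ]
  shifted[1:shift, , ] <- 0
  v2 <- volume(shifted, diag(4))
  p1 <- predict_sliding(net, v1)$data
  p2 <- predict_sliding(net, v2)$data
  interior <- (shift + 5):(24 - 5)
  expect_equal(p2[interior, , ], p1[interior - shift, , ], tolerance = 1e-6)
})

test_that("models survive a save/load round trip with identical predictions", {
  net <- build_network(tiny_cfg(), seed = 12)
  ds <- list(list(input = array(rnorm(8^3), c(8, 8, 8, 1)),
                  target = array(0, c(8, 8, 8))))
  net <- train_network(net, ds, train_config(batch_size = 1, max_epochs = 2,
                                             convergence_window = 2))
  dir <- tempfile("model_")
  save_model(net, dir)
  net2 <- load_model(dir)
  img <- volume(array(rnorm(8^3), c(8, 8, 8)), diag(4))
  expect_identical(predict_sliding(net, img)$data, predict_sliding(net2, img)$data)
  expect_equal(net2$training_log$loss, net$training_log$loss)
})

test_that("channel mismatches are rejected at prediction time", {
  net <- build_network(tiny_cfg(), seed = 13)
  img <- volume(array(0.3, c(8, 8, 8)), diag(4))
  expect_error(predict_sliding(net, img, mask = img), "channel")
  expect_error(segment_hemispheres(net, img), "segmentation")
})

test_that("intensity normalization matches its definition", {
  v <- volume(array(runif(6^3, 10, 200), c(6, 6, 6)), diag(4))
  n <- normalize_intensity(v)
  expect_lt(abs(mean(n$data)), 1e-6)
  expect_lt(abs(sd(n$data) - 1), 1e-6)
  two <- volume(array(c(0, rep(100, 6^3 - 1)), c(6, 6, 6)), diag(4))
  r <- normalize_intensity(two)
  expect_equal(length(unique(as.vector(r$data))), 2)
  expect_error(normalize_intensity(volume(array(5, c(4, 4, 4)), diag(4))), "constant")
  # idempotent: both steps are equivariant under positive affine maps
  expect_equal(normalize_intensity(n)$data, n$data, tolerance = 1e-12)
})
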