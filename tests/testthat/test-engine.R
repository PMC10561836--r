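sf <- function(name) get(name, envir = asNamespace("simplifruit"))

test_that("im2col + GEMM convolution equals naive convolution", {
  set.seed(31)
  C <- 3L; H <- 7L; W <- 6L; O <- 4L
  x_arr <- array(rnorm(C * H * W), c(C, H, W))
  xm <- matrix(0, C, H * W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    xm[, (y - 1) * W + x] <- x_arr[, y, x]
  }
  for (k in c(1L, 3L)) for (stride in c(1L, 2L)) {
    pad <- k %/% 2L
    w_arr <- array(rnorm(O * C * k * k), c(O, C, k, k))
    # weight rows in the engine's channel-major, kernel-minor layout
    Wm <- matrix(0, O, C * k * k)
    for (o in seq_len(O)) for (c in seq_len(C)) for (ky in seq_len(k)) {
      for (kx in seq_len(k)) {
        Wm[o, (c - 1) * k * k + (ky - 1) * k + kx] <- w_arr[o, c, ky, kx]
      }
    }
    cols <- sf("im2col_cpp")(xm, H, W, k, stride, pad)
    got <- Wm %*% cols
    want <- oracle_conv(x_arr, w_arr, stride, pad)
    Ho <- dim(want)[2]; Wo <- dim(want)[3]
    for (y in seq_len(Ho)) for (x in seq_len(Wo)) {
      expect_equal(got[, (y - 1) * Wo + x], want[, y, x], tolerance = 1e-12)
    }
  }
})

test_that("max-pooling matches a naive oracle and backward routes to argmax", {
  set.seed(32)
  H <- 6L; W <- 6L
  xm <- matrix(rnorm(2 * H * W), 2, H * W)
  r <- sf("maxpool_cpp")(xm, H, W, 2L, 2L, 0L)
  for (c in 1:2) for (yo in 0:2) for (xo in 0:2) {
    vals <- c(xm[c, (2 * yo) * W + 2 * xo + 1], xm[c, (2 * yo) * W + 2 * xo + 2],
              xm[c, (2 * yo + 1) * W + 2 * xo + 1],
              xm[c, (2 * yo + 1) * W + 2 * xo + 2])
    expect_equal(r$y[c, yo * 3 + xo + 1], max(vals))
  }
  dY <- matrix(1, 2, 9)
  dX <- sf("maxpool_bwd_cpp")(dY, r$idx, H * W)
  expect_equal(sum(dX), sum(dY))
  expect_true(all(dX[dX != 0] == 1))
})

test_that("nearest upsample doubles each cell and backward sums the quad", {
  xm <- matrix(as.numeric(1:8), 2, 4)  # 2 channels on a 2x2 map
  y <- sf("upsample2_cpp")(xm, 2L, 2L)
  expect_equal(y[1, ], c(1, 1, 3, 3, 1, 1, 3, 3, 5, 5, 7, 7, 5, 5, 7, 7))
  dX <- sf("upsample2_bwd_cpp")(matrix(1, 2, 16), 2L, 2L)
  expect_true(all(dX == 4))
})

test_that("bilinear resize preserves constants and average brightness", {
  img <- array(0.37, c(10, 14, 3))
  out <- sf("resize_image_cpp")(img, 23L, 9L)
  expect_equal(dim(out), c(23L, 9L, 3L))
  expect_true(all(abs(out - 0.37) < 1e-12))
  set.seed(33)
  img2 <- array(runif(20 * 20 * 3), c(20, 20, 3))
  out2 <- sf("resize_image_cpp")(img2, 40L, 40L)
  expect_equal(mean(out2), mean(img2), tolerance = 0.01)
})

test_that("batch norm standardizes channels in training mode", {
  topo <- tiny_topology()
  plan <- sf("compile_plan")(topo)
  params <- sf("init_params")(plan, seed = 2)
  set.seed(34)
  imgs <- replicate(3, array(runif(32 * 32 * 3), c(32, 32, 3)),
                    simplify = FALSE)
  mats <- sf("prepare_batch_mats")(imgs, 32L)
  fw <- sf("forward_net")(plan, params, mats, train = TRUE)
  # node 2 is the stem conv; its cached xhat must be ~N(0,1) per channel
  xh <- do.call(cbind, fw$acts[[2]]$xhat)
  expect_lt(max(abs(rowMeans(xh))), 1e-8)
  expect_lt(max(abs(apply(xh, 1, stats::sd) - 1)), 1e-2)
})

test_that("backpropagation matches finite differences through the graph", {
  topo <- tiny_topology()
  plan <- sf("compile_plan")(topo)
  params <- sf("init_params")(plan, seed = 3)
  set.seed(35)
  imgs <- replicate(2, array(runif(32 * 32 * 3), c(32, 32, 3)),
                    simplify = FALSE)
  mats <- sf("prepare_batch_mats")(imgs, 32L)
  out_nodes <- unlist(lapply(plan$head, function(h) c(h$box, h$cls)))
  fw0 <- sf("forward_net")(plan, params, mats, train = TRUE)
  G <- lapply(out_nodes, function(nd) {
    lapply(fw0$acts[[nd]]$out, function(m) {
      matrix(rnorm(length(m)), nrow(m))
    })
  })
  loss_of <- function(p) {
    fw <- sf("forward_net")(plan, p, mats, train = TRUE)
    tot <- 0
    for (k in seq_along(out_nodes)) {
      for (m in 1:2) {
        tot <- tot + sum(fw$acts[[out_nodes[k]]]$out[[m]] * G[[k]][[m]])
      }
    }
    tot
  }
  seeds <- lapply(seq_along(out_nodes), function(k) {
    list(node = out_nodes[k], grad = G[[k]])
  })
  pg <- sf("backward_net")(plan, params, fw0$acts, seeds)
  set.seed(36)
  checked <- 0L
  for (nd in which(!vapply(pg, is.null, TRUE))) {
    if (checked >= 12L) break
    nm <- sample(names(pg[[nd]]), 1)
    i <- sample(length(params[[nd]][[nm]]), 1)
    eps <- 1e-5
    p2 <- params
    p2[[nd]][[nm]][i] <- p2[[nd]][[nm]][i] + eps
    l1 <- loss_of(p2)
    p2[[nd]][[nm]][i] <- p2[[nd]][[nm]][i] - 2 * eps
    l0 <- loss_of(p2)
    fd <- (l1 - l0) / (2 * eps)
    an <- pg[[nd]][[nm]][i]
    expect_equal(an, fd, tolerance = 5e-3)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("DFL expectation decoding matches the softmax-expectation oracle", {
  expect_equal(dfl_expectation(rep(0, 16)), 7.5)
  one_hot <- rep(-30, 16); one_hot[4] <- 30
  expect_equal(dfl_expectation(one_hot), 3, tolerance = 1e-9)
  set.seed(37)
  z <- matrix(rnorm(16 * 50), 16, 50)
  p <- apply(z, 2, function(col) exp(col - max(col)) / sum(exp(col - max(col))))
  oracle <- colSums(p * (0:15))
  expect_equal(dfl_expectation(z), oracle, tolerance = 1e-12)
})

test_that("encoding then decoding a distance is exact to sub-pixel", {
  set.seed(38)
  d <- runif(100, 0, 14.9)
  probs <- encode_dfl(d, 16L)
  back <- dfl_expectation(log(probs + 1e-12))
  expect_lt(max(abs(back - d) * 32), 0.5)  # worst case at stride 32
})
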