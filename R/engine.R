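# From-scratch compute engine for the simplified detector. Feature maps are
# C x (H*W) matrices with spatial index j = y*W + x; convolutions run as
# im2col + GEMM; batch norm is computed over the whole batch; SiLU is the
# activation everywhere except the final prediction convs.

sigmoid <- function(z) stats::plogis(z)
silu <- function(z) z * stats::plogis(z)
silu_grad <- function(z) {
  s <- stats::plogis(z)
  s * (1 + z * (1 - s))
}

image_to_mat <- function(image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  rbind(as.vector(t(image[, , 1])),
        as.vector(t(image[, , 2])),
        as.vector(t(image[, , 3])))
}

conv_node <- function(role, src, k, in_c, out_c, stride = 1L,
                      bn = TRUE, act = TRUE) {
  list(role = role, op = "conv", src = src, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(k %/% 2L),
       in_c = as.integer(in_c), out_c = as.integer(out_c),
       bn = bn, act = act)
}

# Compile a topology into a flat plan of primitive nodes (SPPF and the
# detect head expanded). Node 1 is the image input.
compile_plan <- function(topology) {
  nodes <- list(list(role = "input", op = "input", src = integer(),
                     out_c = 3L))
  add <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  blocks <- topology$blocks
  block_id <- integer(nrow(blocks))
  src_ids <- function(i, blk) {
    src <- blk$sources[[1]]
    if (length(src) == 0L) {
      if (i == 1L) 1L else block_id[i - 1L]
    } else {
      block_id[match(src, blocks$index)]
    }
  }
  for (i in seq_len(nrow(blocks))) {
    blk <- blocks[i, ]
    s <- src_ids(i, blk)
    role <- sprintf("block%d", blk$index)
    block_id[i] <- switch(blk$kind,
      conv = add(conv_node(role, s, blk$kernel, blk$in_channels,
                           blk$out_channels, blk$stride)),
      maxpool = add(list(role = role, op = "maxpool", src = s, k = 2L,
                         stride = 2L, pad = 0L)),
      upsample = add(list(role = role, op = "upsample", src = s)),
      concat = add(list(role = role, op = "concat", src = s)),
      sppf = {
        cv1 <- add(conv_node(paste0(role, ".cv1"), s, 1L, blk$in_channels,
                             blk$hidden_channels))
        p1 <- add(list(role = paste0(role, ".p1"), op = "maxpool", src = cv1,
                       k = 5L, stride = 1L, pad = 2L))
        p2 <- add(list(role = paste0(role, ".p2"), op = "maxpool", src = p1,
                       k = 5L, stride = 1L, pad = 2L))
        p3 <- add(list(role = paste0(role, ".p3"), op = "maxpool", src = p2,
                       k = 5L, stride = 1L, pad = 2L))
        cat <- add(list(role = paste0(role, ".cat"), op = "concat",
                        src = c(cv1, p1, p2, p3)))
        add(conv_node(paste0(role, ".cv2"), cat, 1L,
                      4L * blk$hidden_channels, blk$out_channels))
      })
  }
  head <- list()
  w <- topology$head_width
  r4 <- 4L * topology$reg_max
  nc <- topology$num_classes
  feats <- block_id[match(topology$detect_scales, blocks$index)]
  for (sc in seq_along(feats)) {
    ci <- head_in_channels(topology)[sc]
    b1 <- add(conv_node(sprintf("head%d.box1", sc), feats[sc], 3L, ci, w))
    b2 <- add(conv_node(sprintf("head%d.box2", sc), b1, 3L, w, w))
    b3 <- add(conv_node(sprintf("head%d.box3", sc), b2, 1L, w, r4,
                        bn = FALSE, act = FALSE))
    c1 <- add(conv_node(sprintf("head%d.cls1", sc), feats[sc], 3L, ci, w))
    c2 <- add(conv_node(sprintf("head%d.cls2", sc), c1, 3L, w, w))
    c3 <- add(conv_node(sprintf("head%d.cls3", sc), c2, 1L, w, nc,
                        bn = FALSE, act = FALSE))
    head[[sc]] <- list(box = b3, cls = c3)
  }
  list(nodes = nodes, block_id = block_id, head = head,
       strides = c(8L, 16L, 32L))
}

init_params <- function(plan, seed = 0L) {
  set.seed(as.integer(seed))
  params <- vector("list", length(plan$nodes))
  for (i in seq_along(plan$nodes)) {
    nd <- plan$nodes[[i]]
    if (nd$op != "conv") next
    fan_in <- nd$in_c * nd$k^2
    p <- list(W = matrix(rnorm(nd$out_c * fan_in, 0, sqrt(2 / fan_in)),
                         nd$out_c, fan_in))
    if (nd$bn) {
      p$gamma <- rep(1, nd$out_c)
      p$beta <- rep(0, nd$out_c)
      p$run_mean <- rep(0, nd$out_c)
      p$run_var <- rep(1, nd$out_c)
    } else {
      # prediction convs: small positive box prior, rare-class prior
      p$b <- if (grepl("cls3$", nd$role)) rep(-4.6, nd$out_c)
             else rep(1, nd$out_c)
    }
    params[[i]] <- p
  }
  params
}

# count trainable entries of an initialized parameter set (the brute-force
# oracle for count_params)
enumerate_param_sizes <- function(params) {
  sum(vapply(params, function(p) {
    if (is.null(p)) return(0L)
    length(p[["W"]]) + length(p[["b"]]) + length(p[["gamma"]]) +
      length(p[["beta"]])
  }, 0L))
}

#' @keywords internal
forward_net <- function(plan, params, images, train = TRUE,
                        bn_momentum = 0.1, keep_cache = train) {
  n_img <- length(images)
  nodes <- plan$nodes
  acts <- vector("list", length(nodes))
  h0 <- attr(images, "height"); w0 <- attr(images, "width")
  acts[[1]] <- list(out = images, H = h0, W = w0)
  for (i in seq_along(nodes)[-1]) {
    nd <- nodes[[i]]
    src <- acts[nd$src]
    x <- src[[1]]
    if (nd$op == "conv") {
      p <- params[[i]]
      Ho <- (x$H + 2L * nd$pad - nd$k) %/% nd$stride + 1L
      Wo <- (x$W + 2L * nd$pad - nd$k) %/% nd$stride + 1L
      z <- vector("list", n_img)
      for (m in seq_len(n_img)) {
        cols <- if (nd$k == 1L && nd$stride == 1L) x$out[[m]]
                else im2col_cpp(x$out[[m]], x$H, x$W, nd$k, nd$stride, nd$pad)
        z[[m]] <- p$W %*% cols
      }
      if (nd$bn) {
        if (train) {
          mu <- Reduce(`+`, lapply(z, rowMeans)) / n_img
          ex2 <- Reduce(`+`, lapply(z, function(m) rowMeans(m^2))) / n_img
          vr <- pmax(ex2 - mu^2, 0)
          params[[i]]$run_mean <- (1 - bn_momentum) * p$run_mean + bn_momentum * mu
          params[[i]]$run_var <- (1 - bn_momentum) * p$run_var + bn_momentum * vr
        } else {
          mu <- p$run_mean; vr <- p$run_var
        }
        inv_sd <- 1 / sqrt(vr + 1e-5)
        xhat <- lapply(z, function(m) (m - mu) * inv_sd)
        pre <- lapply(xhat, function(m) m * p$gamma + p$beta)
      } else {
        xhat <- NULL
        pre <- lapply(z, function(m) m + p$b)
      }
      out <- if (nd$act) lapply(pre, silu) else pre
      acts[[i]] <- list(out = out, H = Ho, W = Wo)
      if (keep_cache) {
        acts[[i]]$pre <- pre
        acts[[i]]$xhat <- xhat
        if (nd$bn) acts[[i]]$inv_sd <- inv_sd
      }
    } else if (nd$op == "maxpool") {
      Ho <- (x$H + 2L * nd$pad - nd$k) %/% nd$stride + 1L
      Wo <- (x$W + 2L * nd$pad - nd$k) %/% nd$stride + 1L
      out <- vector("list", n_img); idx <- vector("list", n_img)
      for (m in seq_len(n_img)) {
        r <- maxpool_cpp(x$out[[m]], x$H, x$W, nd$k, nd$stride, nd$pad)
        out[[m]] <- r$y; idx[[m]] <- r$idx
      }
      acts[[i]] <- list(out = out, H = Ho, W = Wo)
      if (keep_cache) acts[[i]]$idx <- idx
    } else if (nd$op == "upsample") {
      out <- lapply(x$out, function(m) upsample2_cpp(m, x$H, x$W))
      acts[[i]] <- list(out = out, H = 2L * x$H, W = 2L * x$W)
    } else if (nd$op == "concat") {
      hs <- vapply(src, function(s) as.numeric(s$H), 0)
      if (length(unique(hs)) != 1L) {
        abort(sprintf("concat at node %d: mismatched spatial sizes", i))
      }
      out <- vector("list", n_img)
      for (m in seq_len(n_img)) {
        out[[m]] <- do.call(rbind, lapply(src, function(s) s$out[[m]]))
      }
      acts[[i]] <- list(out = out, H = src[[1]]$H, W = src[[1]]$W,
                        split = cumsum(vapply(src, function(s)
                          nrow(s$out[[1]]), 0L)))
    }
  }
  list(acts = acts, params = params)
}

#' @keywords internal
backward_net <- function(plan, params, acts, seed_grads) {
  nodes <- plan$nodes
  n_img <- length(acts[[1]]$out)
  grads <- vector("list", length(nodes))
  pgrads <- vector("list", length(nodes))
  add_grad <- function(i, m, g) {
    if (is.null(grads[[i]])) grads[[i]] <<- vector("list", n_img)
    if (is.null(grads[[i]][[m]])) grads[[i]][[m]] <<- g
    else grads[[i]][[m]] <<- grads[[i]][[m]] + g
  }
  for (s in seed_grads) {
    for (m in seq_len(n_img)) add_grad(s$node, m, s$grad[[m]])
  }
  for (i in rev(seq_along(nodes)[-1])) {
    if (is.null(grads[[i]])) next
    nd <- nodes[[i]]
    a <- acts[[i]]
    x <- acts[[nd$src[1]]]
    if (nd$op == "conv") {
      p <- params[[i]]
      g <- grads[[i]]
      if (nd$act) {
        g <- lapply(seq_len(n_img), function(m) g[[m]] * silu_grad(a$pre[[m]]))
      }
      if (nd$bn) {
        m_tot <- n_img * ncol(g[[1]])
        dgamma <- Reduce(`+`, lapply(seq_len(n_img), function(m)
          rowSums(g[[m]] * a$xhat[[m]])))
        dbeta <- Reduce(`+`, lapply(g, rowSums))
        gz <- lapply(seq_len(n_img), function(m) {
          (p$gamma * a$inv_sd) *
            (g[[m]] - dbeta / m_tot - a$xhat[[m]] * (dgamma / m_tot))
        })
        pgrads[[i]] <- list(gamma = dgamma, beta = dbeta)
      } else {
        gz <- g
        pgrads[[i]] <- list(b = Reduce(`+`, lapply(g, rowSums)))
      }
      dW <- matrix(0, nrow(p$W), ncol(p$W))
      for (m in seq_len(n_img)) {
        if (nd$k == 1L && nd$stride == 1L) {
          dW <- dW + gz[[m]] %*% t(x$out[[m]])
          add_grad(nd$src[1], m, crossprod(p$W, gz[[m]]))
        } else {
          cols <- im2col_cpp(x$out[[m]], x$H, x$W, nd$k, nd$stride, nd$pad)
          dW <- dW + gz[[m]] %*% t(cols)
          dcols <- crossprod(p$W, gz[[m]])
          add_grad(nd$src[1], m,
                   col2im_cpp(dcols, x$H, x$W, nd$in_c, nd$k, nd$stride,
                              nd$pad))
        }
      }
      pgrads[[i]]$W <- dW
    } else if (nd$op == "maxpool") {
      for (m in seq_len(n_img)) {
        add_grad(nd$src[1], m,
                 maxpool_bwd_cpp(grads[[i]][[m]], a$idx[[m]], x$H * x$W))
      }
    } else if (nd$op == "upsample") {
      for (m in seq_len(n_img)) {
        add_grad(nd$src[1], m, upsample2_bwd_cpp(grads[[i]][[m]], x$H, x$W))
      }
    } else if (nd$op == "concat") {
      starts <- c(0L, head(a$split, -1L)) + 1L
      for (m in seq_len(n_img)) {
        g <- grads[[i]][[m]]
        for (k in seq_along(nd$src)) {
          add_grad(nd$src[k], m,
                   g[starts[k]:a$split[k], , drop = FALSE])
        }
      }
    }
    grads[[i]] <- NULL  # free as we go
  }
  pgrads
}

sgd_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
           function(x) x * 0)
  })
}

sgd_step <- function(params, pgrads, velocity, lr, momentum = 0.937,
                     weight_decay = 5e-4) {
  for (i in seq_along(params)) {
    if (is.null(pgrads[[i]])) next
    for (nm in names(pgrads[[i]])) {
      g <- pgrads[[i]][[nm]]
      if (nm == "W") g <- g + weight_decay * params[[i]][[nm]]
      velocity[[i]][[nm]] <- momentum * velocity[[i]][[nm]] - lr * g
      params[[i]][[nm]] <- params[[i]][[nm]] + velocity[[i]][[nm]]
    }
  }
  list(params = params, velocity = velocity)
}
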