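# Forward/backward passes of the nine-layer classifier. Convolutions and
# pooling run through the compiled im2col/gemm kernels; everything else is
# vectorized R. Layer order: conv1, conv2, pool, conv3, pool, conv4, pool,
# fc (hidden), fc (softmax output). Dropout 1/3 after each pool, 1/2 after
# the hidden fc; leaky rectifier after every layer except the output.

# leaky rectifier via |x|: 0.5*((1+a)x + (1-a)|x|) avoids slow logical
# indexing on multi-million-element activation arrays
lrelu <- function(x, a) {
  y <- 0.5 * ((1 + a) * x + (1 - a) * abs(x))
  dim(y) <- dim(x)
  y
}

lrelu_grad <- function(x, a) {
  g <- a + (1 - a) * (x > 0)
  dim(g) <- dim(x)
  g
}

drop_mask <- function(n, p_drop) {
  keep <- 1 - p_drop
  (runif(n) < keep) / keep
}

# Forward pass. `params` is the flat parameter list; dropout masks are
# drawn from the current RNG stream when dropout = TRUE.
nn_forward <- function(spec, params, x, dropout = FALSE) {
  a <- spec$leaky_slope
  cache <- list(x = x, dropout = dropout)
  h1 <- cpp_conv_full_forward(x, params$W1, params$b1)
  z1 <- lrelu(h1, a)
  h2 <- cpp_conv_full_forward(z1, params$W2, params$b2)
  z2 <- lrelu(h2, a)
  p1 <- cpp_maxpool2_forward(z2)
  d1 <- p1$y
  if (dropout) {
    m1 <- array(drop_mask(length(d1), spec$dropout_pool), dim(d1))
    d1 <- d1 * m1
    cache$m1 <- m1
  }
  h3 <- cpp_conv_full_forward(d1, params$W3, params$b3)
  z3 <- lrelu(h3, a)
  p2 <- cpp_maxpool2_forward(z3)
  d2 <- p2$y
  if (dropout) {
    m2 <- array(drop_mask(length(d2), spec$dropout_pool), dim(d2))
    d2 <- d2 * m2
    cache$m2 <- m2
  }
  h4 <- cpp_conv_full_forward(d2, params$W4, params$b4)
  z4 <- lrelu(h4, a)
  p3 <- cpp_maxpool2_forward(z4)
  d3 <- p3$y
  if (dropout) {
    m3 <- array(drop_mask(length(d3), spec$dropout_pool), dim(d3))
    d3 <- d3 * m3
    cache$m3 <- m3
  }
  B <- dim(x)[4]
  flat <- matrix(d3, ncol = B)
  f1 <- params$Wf1 %*% flat + params$bf1
  z5 <- lrelu(f1, a)
  d4 <- z5
  if (dropout) {
    m4 <- matrix(drop_mask(length(z5), spec$dropout_fc), nrow(z5))
    d4 <- d4 * m4
    cache$m4 <- m4
  }
  logits <- params$Wf2 %*% d4 + params$bf2
  mx <- if (nrow(logits) == 2L) pmax(logits[1, ], logits[2, ]) else
    apply(logits, 2, max)
  e <- exp(sweep(logits, 2, mx))
  probs <- sweep(e, 2, colSums(e), "/")
  cache <- c(cache, list(h1 = h1, z1 = z1, h2 = h2, z2 = z2, p1 = p1,
                         d1 = d1, h3 = h3, z3 = z3, p2 = p2, d2 = d2,
                         h4 = h4, z4 = z4, p3 = p3, d3 = d3, flat = flat,
                         f1 = f1, z5 = z5, d4 = d4))
  list(probs = probs, cache = cache)
}

nn_weight_sq <- function(params) {
  sum(vapply(params[c("W1", "W2", "W3", "W4", "Wf1", "Wf2")],
             function(w) sum(w^2), numeric(1)))
}

# Cross-entropy (+ L2) and hard predictions. Row 2 of `probs` is the
# tumour class; labels are 0/1.
nn_loss <- function(probs, labels, params, l2) {
  B <- ncol(probs)
  p_true <- probs[cbind(labels + 1L, seq_len(B))]
  ce <- -mean(log(pmax(p_true, 1e-12)))
  list(ce = ce, loss = ce + 0.5 * l2 * nn_weight_sq(params),
       pred = as.integer(probs[2, ] > probs[1, ]))
}

nn_backward <- function(spec, params, fw, labels, l2) {
  a <- spec$leaky_slope
  cc <- fw$cache
  B <- ncol(fw$probs)
  y <- matrix(0, 2, B)
  y[cbind(labels + 1L, seq_len(B))] <- 1
  dlogits <- (fw$probs - y) / B
  g <- list()
  g$Wf2 <- dlogits %*% t(cc$d4) + l2 * params$Wf2
  g$bf2 <- rowSums(dlogits)
  dd4 <- t(params$Wf2) %*% dlogits
  if (cc$dropout) dd4 <- dd4 * cc$m4
  df1 <- dd4 * lrelu_grad(cc$f1, a)
  g$Wf1 <- df1 %*% t(cc$flat) + l2 * params$Wf1
  g$bf1 <- rowSums(df1)
  dflat <- t(params$Wf1) %*% df1
  dd3 <- array(dflat, dim(cc$d3))
  if (cc$dropout) dd3 <- dd3 * cc$m3
  dz4 <- pool_backward(dd3, cc$p3, dim(cc$z4))
  dh4 <- dz4 * lrelu_grad(cc$h4, a)
  b4 <- cpp_conv_full_backward(cc$d2, params$W4, dh4)
  g$W4 <- b4$dw + l2 * params$W4
  g$b4 <- b4$db
  dd2 <- b4$dx
  if (cc$dropout) dd2 <- dd2 * cc$m2
  dz3 <- pool_backward(dd2, cc$p2, dim(cc$z3))
  dh3 <- dz3 * lrelu_grad(cc$h3, a)
  b3 <- cpp_conv_full_backward(cc$d1, params$W3, dh3)
  g$W3 <- b3$dw + l2 * params$W3
  g$b3 <- b3$db
  dd1 <- b3$dx
  if (cc$dropout) dd1 <- dd1 * cc$m1
  dz2 <- pool_backward(dd1, cc$p1, dim(cc$z2))
  dh2 <- dz2 * lrelu_grad(cc$h2, a)
  b2 <- cpp_conv_full_backward(cc$z1, params$W2, dh2)
  g$W2 <- b2$dw + l2 * params$W2
  g$b2 <- b2$db
  dz1 <- b2$dx
  dh1 <- dz1 * lrelu_grad(cc$h1, a)
  b1 <- cpp_conv_full_backward(cc$x, params$W1, dh1)
  g$W1 <- b1$dw + l2 * params$W1
  g$b1 <- b1$db
  g
}

# Route pooled gradients back to the argmax positions (2x2/stride-2 pooling
# windows never overlap, so direct assignment is exact).
pool_backward <- function(dy, pool, in_dim) {
  dx <- numeric(prod(in_dim))
  dx[as.vector(pool$idx)] <- as.vector(dy)
  array(dx, in_dim)
}

adadelta_init <- function(params) {
  list(Eg = lapply(params, function(p) p * 0),
       Ed = lapply(params, function(p) p * 0))
}

# One Adadelta step: accumulate squared gradients, scale by the RMS ratio,
# accumulate squared updates. `lr` multiplies the update.
adadelta_update <- function(params, grads, state, config) {
  rho <- config$rho
  eps <- config$eps
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$Eg[[nm]] <- rho * state$Eg[[nm]] + (1 - rho) * gr^2
    dx <- -config$lr * sqrt(state$Ed[[nm]] + eps) /
      sqrt(state$Eg[[nm]] + eps) * gr
    state$Ed[[nm]] <- rho * state$Ed[[nm]] + (1 - rho) * dx^2
    params[[nm]] <- params[[nm]] + dx
  }
  list(params = params, state = state)
}
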