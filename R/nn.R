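# Internal neural-network plumbing for the adversarial denoiser: convolution
# layers over im2col/BLAS, leaky-ReLU, nearest-neighbour up/down sampling and
# Adam. Parameters are nested lists of W (Cout x kh*kw*Cin) and b vectors.

conv_init <- function(cin, cout, k = 3, gain = 1, rng = stats::rnorm) {
  list(W = matrix(rng(cout * k * k * cin), cout) *
         gain * sqrt(2 / (k * k * cin)),
       b = numeric(cout))
}

as_cube <- function(x) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  x
}

conv_fwd <- function(x, layer, stride = 1L) {
  cpp_conv_fwd(as_cube(x), layer$W, layer$b, 3L, 3L, as.integer(stride), 1L)
}

conv_bwd <- function(x, layer, gy, stride = 1L) {
  cpp_conv_bwd(as_cube(x), layer$W, as_cube(gy), 3L, 3L,
               as.integer(stride), 1L)
}

lrelu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
lrelu_bwd <- function(x, g, slope = 0.2) g * (slope + (1 - slope) * (x > 0))

# nearest-neighbour 2x upsampling of an (H, W, C) cube and its adjoint
up2 <- function(x) {
  x <- as_cube(x)
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

up2_bwd <- function(g) {
  g <- as_cube(g)
  d <- dim(g)
  o1 <- seq(1, d[1], by = 2)
  o2 <- seq(1, d[2], by = 2)
  g[o1, o2, , drop = FALSE] + g[o1 + 1, o2, , drop = FALSE] +
    g[o1, o2 + 1, , drop = FALSE] + g[o1 + 1, o2 + 1, , drop = FALSE]
}

cat_c <- function(a, b) {
  a <- as_cube(a); b <- as_cube(b)
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

# params/grads/state share structure: leaves are numeric W matrices/b vectors
adam_step <- function(params, grads, state, lr, b1, b2, t, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      return(list(p = out_p, s = out_s))
    }
    m <- b1 * s$m + (1 - b1) * g
    v <- b2 * s$v + (1 - b2) * g^2
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = list(m = m, v = v))
  }
  walk(params, grads, state)
}

# a "leaf" for adam_init/adam_step is a W or b; wrap each conv layer so the
# recursion bottoms out on numeric arrays
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) return(lapply(p, walk))
    list(m = p * 0, v = p * 0)
  }
  walk(params)
}
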