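## Minimal reverse-mode automatic differentiation on a tape of environments.
## Feature maps are numeric 3-D arrays dim = c(H, W, C); the compiled
## kernels in src/ provide the heavy forward/adjoint pairs.  Internal only;
## gradients are validated against finite differences in the test suite.

agTape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

agNode <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

agLeaf <- function(tape, value) agNode(tape, value)

agAccum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

## Seeds the output node with gradient 1 and sweeps the tape in reverse
## creation order (a valid topological order for define-by-run graphs).
agBackward <- function(tape, node) {
  node$grad <- array(1, dim = if (is.null(dim(node$value))) 1L
                     else dim(node$value))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents))
      if (!is.null(gs[[j]])) agAccum(nd$parents[[j]], gs[[j]])
  }
  invisible(NULL)
}

## --- operations ------------------------------------------------------------

## x: (H,W,Cin) node; w: (kh,kw,Cin,Cout) node; b: (Cout) node.
agConv2d <- function(tape, x, w, b, stride = 1L, pad = 1L) {
  wd <- dim(w$value)
  wmat <- matrix(w$value, nrow = wd[1] * wd[2] * wd[3], ncol = wd[4])
  y <- .conv2d_fwd(x$value, wmat, b$value, wd[1], wd[2], stride, pad)
  agNode(tape, y, parents = list(x, w, b), backward = function(g) {
    bw <- .conv2d_bwd(x$value, wmat, g, wd[1], wd[2], stride, pad)
    list(bw$gx, array(bw$gw, dim = wd), as.numeric(bw$gb))
  })
}

agInstanceNorm <- function(tape, x, gamma, beta, eps = 1e-5) {
  d <- dim(x$value)
  n <- d[1] * d[2]
  xm <- matrix(x$value, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  s <- sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, s, "/")
  y <- sweep(sweep(xhat, 2, gamma$value, "*"), 2, beta$value, "+")
  agNode(tape, array(y, d), parents = list(x, gamma, beta),
         backward = function(g) {
    gm <- matrix(g, n, d[3])
    dg <- colSums(gm * xhat)
    db <- colSums(gm)
    gh <- sweep(gm, 2, gamma$value, "*")
    dx <- sweep(gh, 2, colMeans(gh)) -
      sweep(xhat, 2, colSums(gh * xhat) / n, "*")
    dx <- sweep(dx, 2, s, "/")
    list(array(dx, d), dg, db)
  })
}

agLeakyRelu <- function(tape, x, slope = 0.2) {
  pos <- x$value > 0
  y <- ifelse(pos, x$value, slope * x$value)
  agNode(tape, array(y, dim = dim(x$value)), parents = list(x),
         backward = function(g) list(g * ifelse(pos, 1, slope)))
}

agDropout <- function(tape, x, rate, training) {
  if (!training || rate <= 0) return(x)
  keep <- (stats::runif(length(x$value)) >= rate) / (1 - rate)
  keep <- array(keep, dim = dim(x$value))
  agNode(tape, x$value * keep, parents = list(x),
         backward = function(g) list(g * keep))
}

agMaxPool <- function(tape, x, k) {
  d <- dim(x$value)
  if (d[1] < k || d[2] < k)
    stop("feature map (", d[1], "x", d[2], ") smaller than pooling kernel ",
         k, call. = FALSE)
  fw <- .maxpool_fwd(x$value, k)
  agNode(tape, fw$out, parents = list(x),
         backward = function(g) list(.maxpool_bwd(g, fw$idx, d[1], d[2], d[3])))
}

agAvgPool2 <- function(tape, x) {
  agNode(tape, .avgpool2_fwd(x$value), parents = list(x),
         backward = function(g) list(.avgpool2_bwd(g)))
}

agResize <- function(tape, x, ho, wo) {
  d <- dim(x$value)
  agNode(tape, .resize_bilinear_fwd(x$value, ho, wo), parents = list(x),
         backward = function(g) list(.resize_bilinear_bwd(g, d[1], d[2])))
}

## Sub-pixel rearrangement (H, W, C*r^2) -> (H*r, W*r, C); pure permutation.
pixelShuffleArray <- function(x, r) {
  d <- dim(x)
  if (d[3] %% (r * r) != 0L)
    stop("channel count (", d[3], ") not divisible by r^2 = ", r * r,
         call. = FALSE)
  if (r == 1L) return(x)
  cout <- d[3] %/% (r * r)
  y <- aperm(array(x, c(d[1], d[2], r, r, cout)), c(4, 1, 3, 2, 5))
  dim(y) <- c(d[1] * r, d[2] * r, cout)
  y
}

pixelUnshuffleArray <- function(y, r) {
  d <- dim(y)
  if (r == 1L) return(y)
  h <- d[1] %/% r; w <- d[2] %/% r
  x <- aperm(array(y, c(r, h, r, w, d[3])), c(2, 4, 3, 1, 5))
  dim(x) <- c(h, w, d[3] * r * r)
  x
}

agPixelShuffle <- function(tape, x, r) {
  agNode(tape, pixelShuffleArray(x$value, r), parents = list(x),
         backward = function(g) list(pixelUnshuffleArray(g, r)))
}

agConcat <- function(tape, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  v <- array(c(x$value, y$value), dim = c(dx[1], dx[2], dx[3] + dy[3]))
  agNode(tape, v, parents = list(x, y), backward = function(g) {
    list(g[, , seq_len(dx[3]), drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), drop = FALSE])
  })
}

agAdd <- function(tape, x, y) {
  agNode(tape, x$value + y$value, parents = list(x, y),
         backward = function(g) list(g, g))
}

## y = a * x + b with scalar constants (used to undo input standardization).
agAffine <- function(tape, x, a, b) {
  agNode(tape, a * x$value + b, parents = list(x),
         backward = function(g) list(a * g))
}

## Mean absolute deviation from a constant target array.
agL1 <- function(tape, x, target) {
  r <- x$value - target
  agNode(tape, mean(abs(r)), parents = list(x),
         backward = function(g) list(array(as.numeric(g) * sign(r) / length(r),
                                           dim = dim(r))))
}
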