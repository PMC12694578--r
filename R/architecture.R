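#' Describe a truncated 3D residual classifier
#'
#' The architecture family is a 3D residual network: a single wide-kernel stem
#' convolution, optional max pooling, a sequence of stages of basic residual
#' blocks (two 3x3x3 convolutions each, batch normalization after every
#' convolution, strided 1x1x1 projection shortcuts where shape changes), then
#' a head of spatial dropout, global average pooling and a fully connected
#' layer with one output per class. The learnable-layer count follows the
#' usual residual-network convention: stem + two convolutions per basic block
#' + the fully connected layer, excluding projection shortcuts.
#'
#' @param in_channels number of input channels (1 for grayscale volumes).
#' @param stem_channels,stem_kernel,stem_stride stem convolution geometry.
#' @param stem_pool logical; apply a 3x3x3 stride-2 max pool after the stem.
#' @param stages list of `c(n_blocks, channels)` pairs; the first block of
#'   every stage after the first uses stride 2.
#' @param dropout spatial dropout probability in the head.
#' @param n_classes number of output classes.
#' @return An object of class `voxsal_arch`.
#' @examples
#' spec <- architecture_spec()
#' learnable_layers(spec)  # 12
#' @export
architecture_spec <- function(in_channels = 1L,
                              stem_channels = 64L,
                              stem_kernel = 7L,
                              stem_stride = 2L,
                              stem_pool = TRUE,
                              stages = list(c(2L, 64L), c(2L, 128L), c(1L, 256L)),
                              dropout = 0.4,
                              n_classes = 2L) {
  stopifnot(in_channels >= 1, stem_channels >= 1, stem_kernel >= 1,
            length(stages) >= 1, dropout >= 0, dropout < 1, n_classes >= 2)
  stages <- lapply(stages, function(s) {
    stopifnot(length(s) == 2, s[1] >= 1, s[2] >= 1)
    as.integer(s)
  })
  structure(list(in_channels = as.integer(in_channels),
                 stem_channels = as.integer(stem_channels),
                 stem_kernel = as.integer(stem_kernel),
                 stem_stride = as.integer(stem_stride),
                 stem_pool = isTRUE(stem_pool),
                 stages = stages,
                 dropout = as.numeric(dropout),
                 n_classes = as.integer(n_classes)),
            class = "voxsal_arch")
}

#' The full-depth 18-layer 3D residual variant
#' @return A `voxsal_arch` with stages of (2,2,2,2) blocks at 64/128/256/512
#'   channels and a 512-to-2 head.
#' @export
architecture_spec_18 <- function() {
  architecture_spec(stages = list(c(2L, 64L), c(2L, 128L),
                                  c(2L, 256L), c(2L, 512L)))
}

#' Count of learnable layers in an architecture
#'
#' Stem convolution + two convolutions per basic block + the fully connected
#' layer; projection shortcuts are excluded by the standard counting
#' convention (their parameters still count in [count_parameters()]).
#' @param spec a `voxsal_arch`.
#' @export
learnable_layers <- function(spec) {
  stopifnot(inherits(spec, "voxsal_arch"))
  1L + 2L * sum(vapply(spec$stages, `[`, integer(1), 1L)) + 1L
}

#' Replicate a 2D convolution kernel along depth to build a 3D kernel
#'
#' Each depth slice of the output equals the source 2D kernel, so the
#' parameter count is multiplied by the spatial kernel size. An optional
#' 1/k rescaling preserves the activation scale of the source layer on
#' depth-constant inputs.
#'
#' @param kernel2d array of shape `k x k x Cin x Cout` (square spatial kernel).
#' @param scale logical; divide the replicated weights by k.
#' @return array of shape `k x k x k x Cin x Cout`.
#' @examples
#' w2 <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
#' w3 <- inflate_2d_to_3d(w2)
#' stopifnot(length(w3) == 3 * length(w2))
#' @export
inflate_2d_to_3d <- function(kernel2d, scale = FALSE) {
  d <- dim(kernel2d)
  if (length(d) != 4) stop("kernel2d must be a k x k x Cin x Cout array")
  if (d[1] != d[2]) stop("spatial kernel must be square")
  k <- d[1]
  out <- array(0, c(k, k, k, d[3], d[4]))
  for (kd in seq_len(k)) out[kd, , , , ] <- kernel2d
  if (isTRUE(scale)) out <- out / k
  out
}

make_block <- function(cin, cout, stride, weights2d = NULL, scale = FALSE) {
  takeW <- function(k, ci, co) {
    if (is.null(weights2d)) return(NULL)
    w2 <- weights2d$pop()
    if (!identical(dim(w2), as.integer(c(k, k, ci, co))))
      stop("supplied 2D weight block has the wrong shape")
    inflate_2d_to_3d(w2, scale = scale)
  }
  blk <- list(type = "block",
              conv1 = new_conv3d(3L, cin, cout, stride = stride,
                                 W = takeW(3L, cin, cout)),
              bn1 = new_bn(cout),
              conv2 = new_conv3d(3L, cout, cout, stride = 1L,
                                 W = takeW(3L, cout, cout)),
              bn2 = new_bn(cout))
  if (stride != 1L || cin != cout) {
    blk$proj <- new_conv3d(1L, cin, cout, stride = stride, pad = 0L)
    blk$proj_bn <- new_bn(cout)
  }
  blk
}

#' Build a 3D residual classifier
#'
#' @param spec a `voxsal_arch` description.
#' @param init `"glorot"` for Glorot-uniform random weights everywhere (head
#'   biases zero), or `"inflated-from-2d"` to construct every convolution by
#'   replicating a user-supplied 2D kernel along depth.
#' @param weights2d when `init = "inflated-from-2d"`: a list of 2D kernel
#'   arrays (`k x k x Cin x Cout`), one per convolution in network order
#'   (stem, then each block's two convolutions; projection shortcuts and the
#'   head remain randomly initialized).
#' @param inflate_scale divide inflated kernels by the kernel size k.
#' @return A model object (class `voxsal_model`).
#' @export
build_model <- function(spec = architecture_spec(),
                        init = c("glorot", "inflated-from-2d"),
                        weights2d = NULL, inflate_scale = FALSE) {
  stopifnot(inherits(spec, "voxsal_arch"))
  init <- match.arg(init)
  supply <- NULL
  if (init == "inflated-from-2d") {
    if (is.null(weights2d)) stop("init = 'inflated-from-2d' needs weights2d")
    env <- new.env()
    env$i <- 0L
    env$pop <- function() {
      env$i <- env$i + 1L
      if (env$i > length(weights2d)) stop("too few 2D weight blocks supplied")
      weights2d[[env$i]]
    }
    supply <- env
  }
  stemW <- NULL
  if (!is.null(supply)) {
    w2 <- supply$pop()
    if (!identical(dim(w2), as.integer(c(spec$stem_kernel, spec$stem_kernel,
                                         spec$in_channels, spec$stem_channels))))
      stop("stem 2D weight block has the wrong shape")
    stemW <- inflate_2d_to_3d(w2, scale = inflate_scale)
  }
  model <- list(spec = spec,
                stem = new_conv3d(spec$stem_kernel, spec$in_channels,
                                  spec$stem_channels, stride = spec$stem_stride,
                                  W = stemW),
                stem_bn = new_bn(spec$stem_channels),
                pool = spec$stem_pool,
                blocks = list(),
                dropout_p = spec$dropout,
                fc = new_fc(spec$stages[[length(spec$stages)]][2],
                            spec$n_classes))
  cin <- spec$stem_channels
  for (s in seq_along(spec$stages)) {
    nb <- spec$stages[[s]][1]
    cout <- spec$stages[[s]][2]
    for (b in seq_len(nb)) {
      stride <- if (s > 1L && b == 1L) 2L else 1L
      model$blocks[[length(model$blocks) + 1L]] <-
        make_block(cin, cout, stride, weights2d = supply, scale = inflate_scale)
      cin <- cout
    }
  }
  class(model) <- "voxsal_model"
  model
}

# Paths to every trainable array, with learning-rate multiplier and whether
# L2 weight decay applies (convolution/fully-connected weights only).
param_table <- function(model) {
  entries <- list(
    list(path = list("stem", "W"), lr_mult = 1, decay = TRUE),
    list(path = list("stem_bn", "gamma"), lr_mult = 1, decay = FALSE),
    list(path = list("stem_bn", "beta"), lr_mult = 1, decay = FALSE))
  for (i in seq_along(model$blocks)) {
    blk <- model$blocks[[i]]
    add <- function(field, sub, decay) {
      entries[[length(entries) + 1L]] <<-
        list(path = list("blocks", i, field, sub), lr_mult = 1, decay = decay)
    }
    add("conv1", "W", TRUE)
    add("bn1", "gamma", FALSE); add("bn1", "beta", FALSE)
    add("conv2", "W", TRUE)
    add("bn2", "gamma", FALSE); add("bn2", "beta", FALSE)
    if (!is.null(blk$proj)) {
      add("proj", "W", TRUE)
      add("proj_bn", "gamma", FALSE); add("proj_bn", "beta", FALSE)
    }
  }
  entries[[length(entries) + 1L]] <-
    list(path = list("fc", "W"), lr_mult = model$fc$lr_mult, decay = TRUE)
  entries[[length(entries) + 1L]] <-
    list(path = list("fc", "b"), lr_mult = model$fc$lr_mult, decay = FALSE)
  entries
}

get_path <- function(obj, path) Reduce(`[[`, path, obj)

set_path <- function(obj, path, value) {
  if (length(path) == 1L) {
    obj[[path[[1L]]]] <- value
    return(obj)
  }
  obj[[path[[1L]]]] <- set_path(obj[[path[[1L]]]], path[-1L], value)
  obj
}

#' Count trainable parameters of a model
#'
#' Sums the sizes of all trainable arrays: convolution weights (including
#' projection shortcuts), batch-normalization scale/shift, and fully
#' connected weights and biases. Running batch-norm moments are not
#' trainable and are excluded. The count is invariant to initialization mode
#' and input grid size.
#' @param model a `voxsal_model` from [build_model()].
#' @return integer parameter count.
#' @examples
#' \donttest{
#' round(count_parameters(build_model(architecture_spec())) / 1e6, 1)  # 4.7
#' }
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "voxsal_model"))
  sum(vapply(param_table(model),
             function(e) length(get_path(model, e$path)), numeric(1)))
}

# Cumulative spatial stride from the input grid to the designated feature
# layer (stem stride x optional pool stride x one stride-2 block per stage
# after the first).
model_stride <- function(model) {
  spec <- model$spec
  spec$stem_stride * (if (spec$stem_pool) 2L else 1L) *
    2L^(length(spec$stages) - 1L)
}

# Forward pass. Returns class scores (N x n_classes), per-layer caches
# (for backward and GradCAM), and the model with updated running moments.
net_forward <- function(model, x, training = FALSE) {
  stopifnot(length(dim(x)) == 5)
  caches <- list(x = x)
  z <- conv_fwd(model$stem, x)
  r <- bn_fwd(model$stem_bn, z, training)
  model$stem_bn <- r$layer
  caches$stem_bn <- r$cache
  a <- relu_fwd(r$out)
  caches$stem_mask <- a$mask
  a <- a$out
  if (model$pool) {
    caches$pool_in_dim <- dim(a)
    p <- cpp_maxpool_fwd(a, dim(a), 3L, 2L, 1L)
    caches$pool_argmax <- p$argmax
    a <- p$out
  }
  caches$blocks <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    rb <- block_fwd(model$blocks[[i]], a, training)
    model$blocks[[i]] <- rb$layer
    caches$blocks[[i]] <- rb$cache
    a <- rb$out
  }
  caches$features <- a
  dr <- sdropout_fwd(a, model$dropout_p, training)
  caches$drop_mask <- dr$mask
  gp <- gap_fwd(dr$out)
  caches$gap <- gp
  scores <- fc_fwd(model$fc, gp$G)
  list(scores = scores, caches = caches, model = model)
}

block_fwd <- function(blk, x, training) {
  z1 <- conv_fwd(blk$conv1, x)
  r1 <- bn_fwd(blk$bn1, z1, training)
  blk$bn1 <- r1$layer
  a1 <- relu_fwd(r1$out)
  z2 <- conv_fwd(blk$conv2, a1$out)
  r2 <- bn_fwd(blk$bn2, z2, training)
  blk$bn2 <- r2$layer
  cache <- list(x = x, bn1 = r1$cache, mask1 = a1$mask, a1 = a1$out,
                bn2 = r2$cache)
  if (!is.null(blk$proj)) {
    zp <- conv_fwd(blk$proj, x)
    rp <- bn_fwd(blk$proj_bn, zp, training)
    blk$proj_bn <- rp$layer
    cache$bnp <- rp$cache
    sc <- rp$out
  } else {
    sc <- x
  }
  s <- r2$out + sc
  out <- relu_fwd(s)
  cache$mask_out <- out$mask
  list(out = out$out, layer = blk, cache = cache)
}

block_bwd <- function(blk, cache, gout) {
  g <- gout * cache$mask_out
  r2 <- bn_bwd(blk$bn2, cache$bn2, g)
  c2 <- conv_bwd(blk$conv2, cache$a1, r2$gx)
  g1 <- c2$gx * cache$mask1
  r1 <- bn_bwd(blk$bn1, cache$bn1, g1)
  c1 <- conv_bwd(blk$conv1, cache$x, r1$gx)
  gx <- c1$gx
  grads <- list(conv1 = list(W = c1$gw),
                bn1 = r1$grads,
                conv2 = list(W = c2$gw),
                bn2 = r2$grads)
  if (!is.null(blk$proj)) {
    rp <- bn_bwd(blk$proj_bn, cache$bnp, g)
    cp <- conv_bwd(blk$proj, cache$x, rp$gx)
    gx <- gx + cp$gx
    grads$proj <- list(W = cp$gw)
    grads$proj_bn <- rp$grads
  } else {
    gx <- gx + g
  }
  list(gx = gx, grads = grads)
}

# Backward pass from score gradients; returns a grads structure parallel to
# the model so param_table() paths index both.
net_backward <- function(model, caches, gscores) {
  fb <- fc_bwd(model$fc, caches$gap$G, gscores)
  ga <- gap_bwd(fb$gG, caches$gap)
  if (!is.null(caches$drop_mask)) {
    S <- caches$gap$S
    ga <- as.numeric(ga) * rep(caches$drop_mask, each = S)
    dim(ga) <- caches$gap$d
  }
  grads <- list(fc = fb$grads, blocks = vector("list", length(model$blocks)))
  g <- ga
  for (i in rev(seq_along(model$blocks))) {
    rb <- block_bwd(model$blocks[[i]], caches$blocks[[i]], g)
    grads$blocks[[i]] <- rb$grads
    g <- rb$gx
  }
  if (model$pool) {
    g <- cpp_maxpool_bwd(g, caches$pool_argmax, caches$pool_in_dim)
  }
  g <- g * caches$stem_mask
  rs <- bn_bwd(model$stem_bn, caches$stem_bn, g)
  cs <- conv_bwd(model$stem, caches$x, rs$gx, need_gx = FALSE)
  grads$stem <- list(W = cs$gw)
  grads$stem_bn <- rs$grads
  grads
}

# Class score vector from designated-layer activations A ([D,H,W,C] or
# [D,H,W,C,1]): runs only the head (dropout in eval mode, global average
# pooling, fully connected). Used by GradCAM diagnostics.
#' Compute class scores from designated-layer feature maps
#'
#' Runs only the classifier head (deterministic dropout, global average
#' pooling, fully connected layer) on a stack of feature maps, bypassing the
#' convolutional trunk. This is the forward map whose gradient GradCAM's
#' channel weights summarize.
#' @param model a `voxsal_model`.
#' @param A feature-map array `D x H x W x C` (or with a trailing singleton
#'   batch axis) at the designated layer.
#' @return numeric vector of pre-softmax class scores.
#' @export
score_from_features <- function(model, A) {
  if (length(dim(A)) == 4) dim(A) <- c(dim(A), 1L)
  gp <- gap_fwd(A)
  drop(fc_fwd(model$fc, gp$G))
}
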