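# Minimal feed-forward network engine used as the DRF feature extractor.
#
# A network is a named list of "arms" (one per input block, e.g. the cell
# image and the drug image), each a stack of layers, followed by a shared
# "trunk" operating on the concatenated arm outputs. Layers are plain lists;
# supported types:
#   dense: W (in x out), b, act
#   conv:  single-channel g x g input (flattened row-major), valid k x k
#          convolution with f filters; K (k^2 x f), b, act
# All parameters are reachable through nn_get_params()/nn_set_params() as a
# flat named list, which is what federated averaging operates on.

act_fun <- function(z, act) {
  switch(act,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z),
         identity = z,
         stop_input("unknown activation '%s'", act))
}

act_grad <- function(z, a, act) {
  switch(act,
         relu = (z > 0) * 1,
         sigmoid = a * (1 - a),
         tanh = 1 - a^2,
         identity = matrix(1, nrow(z), ncol(z)),
         stop_input("unknown activation '%s'", act))
}

# patch index map for a valid k x k convolution over a g x g image stored
# row-major as a length-g^2 vector; rows = output positions, cols = taps
conv_patch_index <- function(g, k) {
  og <- g - k + 1L
  idx <- matrix(0L, og * og, k * k)
  pos <- 1L
  for (r in seq_len(og)) for (c in seq_len(og)) {
    taps <- integer(k * k); tt <- 1L
    for (dr in 0:(k - 1L)) for (dc in 0:(k - 1L)) {
      taps[tt] <- (r + dr - 1L) * g + (c + dc)
      tt <- tt + 1L
    }
    idx[pos, ] <- taps
    pos <- pos + 1L
  }
  idx
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# instantiate layer parameters for one stack of layer specs
init_stack <- function(specs, n_in) {
  layers <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    if (sp$type == "dense") {
      layers[[i]] <- list(type = "dense", W = glorot(n_in, sp$units),
                          b = numeric(sp$units), act = sp$act %||% "relu")
      n_in <- sp$units
    } else if (sp$type == "conv") {
      g <- as.integer(sqrt(n_in))
      if (g * g != n_in)
        stop_input("conv layer needs a square image input, got %d units", n_in)
      if (sp$ksize >= g) stop_input("conv kernel (%d) too large for %dx%d image",
                                    sp$ksize, g, g)
      k2 <- sp$ksize^2
      layers[[i]] <- list(type = "conv", g = g, ksize = sp$ksize,
                          filters = sp$filters,
                          pidx = conv_patch_index(g, sp$ksize),
                          K = glorot(k2, sp$filters),
                          b = numeric(sp$filters), act = sp$act %||% "relu")
      og <- g - sp$ksize + 1L
      n_in <- og * og * sp$filters
    } else stop_input("unknown layer type '%s'", sp$type)
  }
  list(layers = layers, n_out = n_in)
}

# Build a network. arch: list(arms = named list of layer-spec lists,
# trunk = layer-spec list ending in the linear head, inputs = named vector
# of input widths matching arms).
nn_init <- function(arch, seed) {
  with_seed(seed, {
    arms <- list()
    width <- 0L
    for (nm in names(arch$arms)) {
      st <- init_stack(arch$arms[[nm]], arch$inputs[[nm]])
      arms[[nm]] <- st$layers
      width <- width + st$n_out
    }
    trunk <- init_stack(arch$trunk, width)
    structure(list(arms = arms, trunk = trunk$layers, arch = arch,
                   head_size = trunk$n_out),
              class = "fedrf_net")
  })
}

forward_stack <- function(layers, A) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      Z <- A %*% ly$W + matrix(ly$b, nrow(A), length(ly$b), byrow = TRUE)
    } else {
      np <- nrow(ly$pidx); f <- ly$filters
      Z <- matrix(0, nrow(A), np * f)
      for (j in seq_len(np)) {
        Z[, (j - 1L) * f + seq_len(f)] <-
          A[, ly$pidx[j, ], drop = FALSE] %*% ly$K +
          matrix(ly$b, nrow(A), f, byrow = TRUE)
      }
    }
    Aout <- act_fun(Z, ly$act)
    caches[[i]] <- list(A_in = A, Z = Z, A_out = Aout)
    A <- Aout
  }
  list(out = A, caches = caches)
}

backward_stack <- function(layers, caches, dA) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]; ca <- caches[[i]]
    dZ <- dA * act_grad(ca$Z, ca$A_out, ly$act)
    if (ly$type == "dense") {
      grads[[i]] <- list(W = crossprod(ca$A_in, dZ), b = colSums(dZ))
      dA <- dZ %*% t(ly$W)
    } else {
      np <- nrow(ly$pidx); f <- ly$filters
      dK <- matrix(0, nrow(ly$K), f); db <- numeric(f)
      dAin <- matrix(0, nrow(ca$A_in), ncol(ca$A_in))
      for (j in seq_len(np)) {
        dZj <- dZ[, (j - 1L) * f + seq_len(f), drop = FALSE]
        dK <- dK + crossprod(ca$A_in[, ly$pidx[j, ], drop = FALSE], dZj)
        db <- db + colSums(dZj)
        dAin[, ly$pidx[j, ]] <- dAin[, ly$pidx[j, ], drop = FALSE] +
          dZj %*% t(ly$K)
      }
      grads[[i]] <- list(K = dK, b = db)
      dA <- dAin
    }
  }
  list(grads = grads, dA_in = dA)
}

# forward pass through arms + trunk; x is a named list of matrices
nn_forward <- function(net, x) {
  outs <- list(); caches <- list(); widths <- integer(0)
  for (nm in names(net$arms)) {
    if (is.null(x[[nm]])) stop_input("input block '%s' missing", nm)
    fs <- forward_stack(net$arms[[nm]], x[[nm]])
    outs[[nm]] <- fs$out
    caches[[nm]] <- fs$caches
    widths[nm] <- ncol(fs$out)
  }
  H <- do.call(cbind, unname(outs))
  ft <- forward_stack(net$trunk, H)
  list(out = ft$out,
       cache = list(arms = caches, trunk = ft$caches, widths = widths))
}

# backward pass; dout is the gradient of the loss w.r.t. the head output
nn_backward <- function(net, cache, dout) {
  bt <- backward_stack(net$trunk, cache$trunk, dout)
  grads <- list(trunk = bt$grads, arms = list())
  dH <- bt$dA_in
  off <- 0L
  for (nm in names(net$arms)) {
    w <- cache$widths[[nm]]
    ba <- backward_stack(net$arms[[nm]], cache$arms[[nm]],
                         dH[, off + seq_len(w), drop = FALSE])
    grads$arms[[nm]] <- ba$grads
    off <- off + w
  }
  grads
}

sgd_step <- function(net, grads, lr) {
  for (nm in names(net$arms)) {
    for (i in seq_along(net$arms[[nm]])) {
      for (p in names(grads$arms[[nm]][[i]]))
        net$arms[[nm]][[i]][[p]] <- net$arms[[nm]][[i]][[p]] -
          lr * grads$arms[[nm]][[i]][[p]]
    }
  }
  for (i in seq_along(net$trunk)) {
    for (p in names(grads$trunk[[i]]))
      net$trunk[[i]][[p]] <- net$trunk[[i]][[p]] - lr * grads$trunk[[i]][[p]]
  }
  net
}

param_names_of <- function(ly) intersect(c("W", "K", "b"), names(ly))

#' Extract all trainable parameters as a flat named list
#'
#' Names follow \code{"<arm>.<layer>.<param>"} / \code{"trunk.<layer>.<param>"};
#' this flat view is the unit of exchange in federated averaging.
#'
#' @param net a network built by the package's model constructors.
#' @return named list of numeric arrays.
#' @keywords internal
nn_get_params <- function(net) {
  out <- list()
  for (nm in names(net$arms)) {
    for (i in seq_along(net$arms[[nm]])) {
      ly <- net$arms[[nm]][[i]]
      for (p in param_names_of(ly))
        out[[paste(nm, i, p, sep = ".")]] <- ly[[p]]
    }
  }
  for (i in seq_along(net$trunk)) {
    ly <- net$trunk[[i]]
    for (p in param_names_of(ly))
      out[[paste("trunk", i, p, sep = ".")]] <- ly[[p]]
  }
  out
}

nn_set_params <- function(net, params) {
  for (nm in names(net$arms)) {
    for (i in seq_along(net$arms[[nm]])) {
      for (p in param_names_of(net$arms[[nm]][[i]])) {
        key <- paste(nm, i, p, sep = ".")
        if (is.null(params[[key]])) stop_input("missing parameter '%s'", key)
        net$arms[[nm]][[i]][[p]] <- params[[key]]
      }
    }
  }
  for (i in seq_along(net$trunk)) {
    for (p in param_names_of(net$trunk[[i]])) {
      key <- paste("trunk", i, p, sep = ".")
      if (is.null(params[[key]])) stop_input("missing parameter '%s'", key)
      net$trunk[[i]][[p]] <- params[[key]]
    }
  }
  net
}

# names of the parameters in the final trunk layer (the personalized layer)
last_layer_names <- function(net) {
  i <- length(net$trunk)
  paste("trunk", i, param_names_of(net$trunk[[i]]), sep = ".")
}

#' Extractor architecture presets
#'
#' Returns the layer-spec architecture for the two-arm image extractor (or a
#' flat dense network for the ANN baseline). Presets:
#' \describe{
#'   \item{default}{per arm: 3x3 conv with 4 filters + dense(16), trunk
#'     dense(16) + linear head — the full REFINED-CNN style extractor.}
#'   \item{reduced}{conv layers removed from both arms and a single hidden
#'     dense layer, the lower-complexity configuration used for
#'     individually trained client models.}
#'   \item{tiny}{dense(4) arms, head-only trunk; test-scale.}
#'   \item{ann}{single flat input arm with two hidden dense layers (no
#'     image mapping).}
#' }
#'
#' @param preset one of \code{"default"}, \code{"reduced"}, \code{"tiny"},
#'   \code{"ann"}.
#' @param inputs named integer vector of input widths (e.g.
#'   \code{c(cell = 64, drug = 64)} for 8x8 images, or \code{c(x = p)} for
#'   the ANN).
#' @param head_size width of the linear output head (\code{T * n_internal}
#'   for a DRF head, 1 for direct regression).
#' @return an architecture list consumed by the model constructors.
#' @export
extractor_spec <- function(preset = c("default", "reduced", "tiny", "ann"),
                           inputs, head_size) {
  preset <- match.arg(preset)
  dense <- function(u, act = "relu") list(type = "dense", units = u, act = act)
  conv <- function(k, f) list(type = "conv", ksize = k, filters = f, act = "relu")
  head <- dense(head_size, "identity")
  arms <- switch(preset,
    default = lapply(inputs, function(w) list(conv(3L, 4L), dense(16L))),
    reduced = lapply(inputs, function(w) list(dense(8L))),
    tiny = lapply(inputs, function(w) list(dense(4L))),
    ann = lapply(inputs, function(w) list(dense(32L), dense(16L))))
  trunk <- switch(preset,
    default = list(dense(16L), head),
    reduced = list(dense(8L), head),
    tiny = list(head),
    ann = list(head))
  list(arms = arms, trunk = trunk, inputs = as.list(inputs), preset = preset)
}
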