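# Minimal reverse-mode automatic differentiation on dense matrices.
#
# A computation graph node holds a value, its parents and a backward closure;
# ad_backward() seeds the output gradient and propagates in reverse creation
# order. Values are numeric matrices (scalars are 1 x 1). Only the operations
# the conformation and foreignness engines need are provided.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

new_node <- function(val, parents = list(), backfn = NULL, requires = FALSE) {
  .ad_env$counter <- .ad_env$counter + 1L
  node <- new.env(parent = emptyenv())
  node$val <- as_mat(val)
  node$parents <- parents
  node$backfn <- backfn
  node$grad <- NULL
  node$id <- .ad_env$counter
  node$requires <- requires || any(vapply(parents, function(p) p$requires,
                                          logical(1)))
  class(node) <- "ad_node"
  node
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = if (length(x) > 1) length(x) else 1)
}

is_node <- function(x) inherits(x, "ad_node")
wrap <- function(x) if (is_node(x)) x else ad_const(x)

#' Create a constant (non-trainable) graph node
#' @param x numeric vector or matrix.
#' @return an `ad_node`.
#' @export
ad_const <- function(x) new_node(x, requires = FALSE)

#' Create a trainable parameter node
#' @param x numeric vector or matrix of initial values.
#' @return an `ad_node` participating in gradients.
#' @export
ad_param <- function(x) new_node(x, requires = TRUE)

#' Value of a graph node
#' @param x an `ad_node`.
#' @return numeric matrix.
#' @export
ad_value <- function(x) x$val

#' Accumulated gradient of a node after [ad_backward()]
#' @param x an `ad_node`.
#' @return numeric matrix (zeros if the node was not reached).
#' @export
ad_grad <- function(x) {
  if (is.null(x$grad)) matrix(0, nrow(x$val), ncol(x$val)) else x$grad
}

# reduce a gradient to the shape of the target value (scalar broadcast case)
unbroadcast <- function(g, val) {
  if (identical(dim(g), dim(val))) return(g)
  if (length(val) == 1L) return(matrix(sum(g), 1, 1))
  stop("internal: incompatible gradient shape")
}

#' Elementwise/broadcast addition
#' @param a,b `ad_node`s or numerics (scalars broadcast).
#' @return an `ad_node`.
#' @export
ad_add <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  va <- a$val; vb <- b$val
  val <- if (length(va) == 1L) va[1] + vb else if (length(vb) == 1L)
    va + vb[1] else va + vb
  new_node(val, list(a, b), function(g)
    list(unbroadcast(g, va), unbroadcast(g, vb)))
}

#' Elementwise subtraction
#' @inheritParams ad_add
#' @return an `ad_node`.
#' @export
ad_sub <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  va <- a$val; vb <- b$val
  val <- if (length(va) == 1L) va[1] - vb else if (length(vb) == 1L)
    va - vb[1] else va - vb
  new_node(val, list(a, b), function(g)
    list(unbroadcast(g, va), unbroadcast(-g, vb)))
}

#' Elementwise multiplication
#' @inheritParams ad_add
#' @return an `ad_node`.
#' @export
ad_mul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  va <- a$val; vb <- b$val
  val <- if (length(va) == 1L) va[1] * vb else if (length(vb) == 1L)
    va * vb[1] else va * vb
  new_node(val, list(a, b), function(g) {
    ga <- if (length(vb) == 1L) g * vb[1] else g * vb
    gb <- if (length(va) == 1L) g * va[1] else g * va
    list(unbroadcast(ga, va), unbroadcast(gb, vb))
  })
}

#' Matrix product
#' @param a,b `ad_node`s (or numerics) with conformable dimensions.
#' @return an `ad_node`.
#' @export
ad_matmul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  new_node(a$val %*% b$val, list(a, b), function(g)
    list(if (a$requires) g %*% t(b$val) else NULL,
         if (b$requires) t(a$val) %*% g else NULL))
}

#' Transpose
#' @param a an `ad_node`.
#' @return an `ad_node`.
#' @export
ad_t <- function(a) {
  a <- wrap(a)
  new_node(t(a$val), list(a), function(g) list(t(g)))
}

#' Add a column vector to every column of a matrix
#' @param m r x c node; `b` r x 1 node.
#' @param b bias column.
#' @return an `ad_node`.
#' @export
ad_add_bias <- function(m, b) {
  m <- wrap(m); b <- wrap(b)
  new_node(m$val + as.vector(b$val), list(m, b), function(g)
    list(g, matrix(rowSums(g), ncol = 1)))
}

#' Rectified linear unit
#' @param a an `ad_node`.
#' @return an `ad_node`.
#' @export
ad_relu <- function(a) {
  a <- wrap(a)
  mask <- a$val > 0
  new_node(a$val * mask, list(a), function(g) list(g * mask))
}

#' Logistic sigmoid
#' @param a an `ad_node`.
#' @return an `ad_node`.
#' @export
ad_sigmoid <- function(a) {
  a <- wrap(a)
  s <- 1 / (1 + exp(-a$val))
  new_node(s, list(a), function(g) list(g * s * (1 - s)))
}

#' Hyperbolic tangent
#' @param a an `ad_node`.
#' @return an `ad_node`.
#' @export
ad_tanh <- function(a) {
  a <- wrap(a)
  s <- tanh(a$val)
  new_node(s, list(a), function(g) list(g * (1 - s^2)))
}

#' Elementwise absolute value (subgradient 0 at 0)
#' @param a an `ad_node`.
#' @return an `ad_node`.
#' @export
ad_abs <- function(a) {
  a <- wrap(a)
  s <- sign(a$val)
  new_node(abs(a$val), list(a), function(g) list(g * s))
}

#' Elementwise square
#' @param a an `ad_node`.
#' @return an `ad_node`.
#' @export
ad_square <- function(a) {
  a <- wrap(a)
  new_node(a$val^2, list(a), function(g) list(2 * g * a$val))
}

#' Smoothed square root, sqrt(x + eps)
#' @param a an `ad_node` (nonnegative values expected).
#' @param eps smoothing constant keeping the gradient finite at zero.
#' @return an `ad_node`.
#' @export
ad_sqrt <- function(a, eps = 1e-12) {
  a <- wrap(a)
  s <- sqrt(a$val + eps)
  new_node(s, list(a), function(g) list(g / (2 * s)))
}

#' Elementwise minimum with a constant (clamping from above)
#' @param a an `ad_node`.
#' @param cap clamp value.
#' @return an `ad_node`.
#' @export
ad_pmin <- function(a, cap) {
  a <- wrap(a)
  mask <- a$val < cap
  new_node(pmin(a$val, cap), list(a), function(g) list(g * mask))
}

#' Elementwise maximum with a constant (one-sided hinge when cap = 0)
#' @param a an `ad_node`.
#' @param floor_ clamp value.
#' @return an `ad_node`.
#' @export
ad_pmax <- function(a, floor_) {
  a <- wrap(a)
  mask <- a$val > floor_
  new_node(pmax(a$val, floor_), list(a), function(g) list(g * mask))
}

#' Sum of all elements
#' @param a an `ad_node`.
#' @return a scalar `ad_node`.
#' @export
ad_sum <- function(a) {
  a <- wrap(a)
  new_node(sum(a$val), list(a), function(g)
    list(matrix(g[1], nrow(a$val), ncol(a$val))))
}

#' Mean of all elements
#' @param a an `ad_node`.
#' @return a scalar `ad_node`.
#' @export
ad_mean <- function(a) {
  a <- wrap(a)
  n <- length(a$val)
  new_node(mean(a$val), list(a), function(g)
    list(matrix(g[1] / n, nrow(a$val), ncol(a$val))))
}

#' Stack nodes by rows
#' @param ... `ad_node`s with equal column counts.
#' @return an `ad_node`.
#' @export
ad_rbind <- function(...) {
  nodes <- lapply(list(...), wrap)
  rows <- vapply(nodes, function(n) nrow(n$val), integer(1))
  new_node(do.call(rbind, lapply(nodes, ad_value)), nodes, function(g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[at + seq_len(rows[i]), , drop = FALSE]
      at <- at + rows[i]
    }
    out
  })
}

#' Stack nodes by columns
#' @param ... `ad_node`s with equal row counts.
#' @return an `ad_node`.
#' @export
ad_cbind <- function(...) {
  nodes <- lapply(list(...), wrap)
  cols <- vapply(nodes, function(n) ncol(n$val), integer(1))
  new_node(do.call(cbind, lapply(nodes, ad_value)), nodes, function(g) {
    out <- vector("list", length(nodes))
    at <- 0L
    for (i in seq_along(nodes)) {
      out[[i]] <- g[, at + seq_len(cols[i]), drop = FALSE]
      at <- at + cols[i]
    }
    out
  })
}

#' Row subset (gradient scattered back)
#' @param a an `ad_node`.
#' @param idx integer row indices (may repeat).
#' @return an `ad_node`.
#' @export
ad_rows <- function(a, idx) {
  a <- wrap(a)
  new_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    agg <- rowsum(g, idx, reorder = FALSE)
    ga[as.integer(rownames(agg)), ] <- agg
    list(ga)
  })
}

#' Column Euclidean norms of a 3 x N matrix
#' @param a an `ad_node` (3 x N).
#' @param eps smoothing constant.
#' @return 1 x N `ad_node` of norms.
#' @export
ad_colnorms <- function(a, eps = 1e-9) {
  a <- wrap(a)
  nr <- sqrt(colSums(a$val^2) + eps)
  new_node(matrix(nr, nrow = 1), list(a), function(g) {
    list(sweep(a$val, 2, as.vector(g) / nr, "*"))
  })
}

#' Row-wise softmax
#' @param a an `ad_node` (n x K logits).
#' @return an `ad_node` of row-stochastic probabilities.
#' @export
ad_softmax_rows <- function(a) {
  a <- wrap(a)
  z <- a$val - apply(a$val, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  new_node(p, list(a), function(g) {
    dot <- rowSums(g * p)
    list(p * (g - dot))
  })
}

#' Mean softmax cross-entropy against integer targets
#' @param logits n x K `ad_node`.
#' @param target length-n integer vector of true class indices (1-based).
#' @param weights optional per-row weights (averaged with these weights).
#' @return scalar `ad_node`.
#' @export
ad_cross_entropy <- function(logits, target, weights = NULL) {
  logits <- wrap(logits)
  if (any(!is.finite(logits$val))) stop("numeric error: non-finite logits")
  n <- nrow(logits$val)
  if (is.null(weights)) weights <- rep(1, n)
  wsum <- sum(weights)
  z <- logits$val - apply(logits$val, 1, max)
  e <- exp(z)
  p <- e / rowSums(e)
  sel <- cbind(seq_len(n), target)
  val <- sum(-log(pmax(p[sel], 1e-300)) * weights) / wsum
  new_node(val, list(logits), function(g) {
    gp <- p * weights / wsum
    gp[sel] <- gp[sel] - weights / wsum
    list(g[1] * gp)
  })
}

#' All-pairs additive expansion
#'
#' Builds the (n*m) x K matrix whose row (i, j) is `A[i, ] + B[j, ]`
#' (row-major in i), used for pairwise logits without materializing
#' concatenations.
#'
#' @param a n x K `ad_node`.
#' @param b m x K `ad_node`.
#' @return (n*m) x K `ad_node`.
#' @export
ad_outer_add <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  n <- nrow(a$val); m <- nrow(b$val)
  ia <- rep(seq_len(n), times = m)
  ib <- rep(seq_len(m), each = n)
  val <- a$val[ia, , drop = FALSE] + b$val[ib, , drop = FALSE]
  new_node(val, list(a, b), function(g) {
    ga <- rowsum(g, ia, reorder = TRUE)
    gb <- rowsum(g, ib, reorder = TRUE)
    dimnames(ga) <- NULL
    dimnames(gb) <- NULL
    list(ga, gb)
  })
}

#' Elementwise reciprocal
#' @param a an `ad_node` with nonzero entries.
#' @return an `ad_node`.
#' @export
ad_recip <- function(a) {
  a <- wrap(a)
  v <- 1 / a$val
  new_node(v, list(a), function(g) list(-g * v^2))
}

#' Reciprocal square root, 1/sqrt(x + eps)
#' @param a an `ad_node` (nonnegative values expected).
#' @param eps smoothing constant.
#' @return an `ad_node`.
#' @export
ad_rsqrt <- function(a, eps = 1e-12) {
  a <- wrap(a)
  v <- 1 / sqrt(a$val + eps)
  new_node(v, list(a), function(g) list(-0.5 * g * v^3))
}

#' Reshape a node (column-major, like `dim<-`)
#' @param a an `ad_node`.
#' @param nrow,ncol target dimensions.
#' @return an `ad_node`.
#' @export
ad_reshape <- function(a, nrow, ncol) {
  a <- wrap(a)
  stopifnot(length(a$val) == nrow * ncol)
  new_node(matrix(a$val, nrow, ncol), list(a), function(g)
    list(matrix(g, nrow(a$val), ncol(a$val))))
}

#' Column subset (gradient scattered back)
#' @param a an `ad_node`.
#' @param idx integer column indices.
#' @return an `ad_node`.
#' @export
ad_cols <- function(a, idx) {
  a <- wrap(a)
  new_node(a$val[, idx, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$val), ncol(a$val))
    for (k in seq_along(idx)) ga[, idx[k]] <- ga[, idx[k]] + g[, k]
    list(ga)
  })
}

#' Scale each column of a matrix by a row vector
#' @param a r x c `ad_node`.
#' @param s 1 x c `ad_node` of per-column scales.
#' @return an `ad_node`.
#' @export
ad_scale_cols <- function(a, s) {
  a <- wrap(a); s <- wrap(s)
  sv <- as.vector(s$val)
  new_node(sweep(a$val, 2, sv, "*"), list(a, s), function(g)
    list(sweep(g, 2, sv, "*"),
         matrix(colSums(g * a$val), nrow = 1)))
}

#' Column norms over stacked 3-row groups
#'
#' For a (3F) x N matrix viewed as F stacked 3 x N blocks, returns the F x N
#' matrix of per-block column norms. Used to evaluate frame-aligned point
#' errors over all frames at once.
#'
#' @param a (3F) x N `ad_node`.
#' @param eps smoothing constant.
#' @return F x N `ad_node`.
#' @export
ad_group_colnorms <- function(a, eps = 1e-9) {
  a <- wrap(a)
  F3 <- nrow(a$val)
  stopifnot(F3 %% 3L == 0L)
  Fn <- F3 %/% 3L
  grp <- rep(seq_len(Fn), each = 3L)
  sq <- rowsum(a$val^2, grp, reorder = TRUE)
  nr <- sqrt(sq + eps)
  dimnames(nr) <- NULL
  new_node(nr, list(a), function(g) {
    list(a$val * (g / nr)[grp, , drop = FALSE])
  })
}

#' Column-group mean pooling via a constant matrix
#'
#' Convenience constructor for the (cells x groups) averaging matrix used to
#' pool convolution outputs per example.
#'
#' @param groups integer vector assigning each column to a group.
#' @param n_groups number of groups.
#' @return numeric pooling matrix.
#' @export
pool_matrix <- function(groups, n_groups) {
  M <- matrix(0, length(groups), n_groups)
  M[cbind(seq_along(groups), groups)] <- 1
  sweep(M, 2, pmax(colSums(M), 1), "/")
}

#' Column-group mean pooling
#'
#' For an F x N node whose columns belong to groups, returns the F x G matrix
#' of per-group column means.
#'
#' @param a F x N `ad_node`.
#' @param groups integer vector (length N) of group labels in 1..n_groups.
#' @param n_groups number of groups.
#' @return F x G `ad_node`.
#' @export
ad_group_colmeans <- function(a, groups, n_groups) {
  a <- wrap(a)
  cnt <- tabulate(groups, n_groups)
  cnt[cnt == 0L] <- 1L
  sums <- rowsum(t(a$val), groups, reorder = TRUE)
  val <- matrix(0, nrow(a$val), n_groups)
  val[, as.integer(rownames(sums))] <- t(sums)
  val <- sweep(val, 2, cnt, "/")
  new_node(val, list(a), function(g) {
    list(sweep(g[, groups, drop = FALSE], 2, cnt[groups], "/"))
  })
}

#' Column-group max pooling
#'
#' For an F x N node whose columns belong to groups, returns the F x G matrix
#' of per-group maxima; gradients flow to the arg-max entries.
#'
#' @param a F x N `ad_node`.
#' @param groups integer vector (length N) of group labels in 1..n_groups.
#' @param n_groups number of groups.
#' @return F x G `ad_node`.
#' @export
ad_group_colmax <- function(a, groups, n_groups) {
  a <- wrap(a)
  Fn <- nrow(a$val)
  val <- matrix(-Inf, Fn, n_groups)
  arg <- matrix(NA_integer_, Fn, n_groups)
  for (j in seq_along(groups)) {
    g <- groups[j]
    upd <- a$val[, j] > val[, g]
    val[upd, g] <- a$val[upd, j]
    arg[upd, g] <- j
  }
  new_node(val, list(a), function(gr) {
    ga <- matrix(0, Fn, ncol(a$val))
    for (g in seq_len(n_groups)) {
      ok <- !is.na(arg[, g])
      ga[cbind(which(ok), arg[ok, g])] <-
        ga[cbind(which(ok), arg[ok, g])] + gr[ok, g]
    }
    list(ga)
  })
}

#' Cross product of two 3-vectors
#' @param a,b 3 x 1 `ad_node`s.
#' @return 3 x 1 `ad_node`.
#' @export
ad_cross3 <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  av <- as.vector(a$val); bv <- as.vector(b$val)
  val <- c(av[2] * bv[3] - av[3] * bv[2],
           av[3] * bv[1] - av[1] * bv[3],
           av[1] * bv[2] - av[2] * bv[1])
  cross_vec <- function(x, y) c(x[2] * y[3] - x[3] * y[2],
                                x[3] * y[1] - x[1] * y[3],
                                x[1] * y[2] - x[2] * y[1])
  new_node(matrix(val, 3, 1), list(a, b), function(g) {
    gv <- as.vector(g)
    list(matrix(cross_vec(bv, gv), 3, 1), matrix(cross_vec(gv, av), 3, 1))
  })
}

#' Dot product (sum of elementwise products)
#' @param a,b `ad_node`s of equal shape.
#' @return scalar `ad_node`.
#' @export
ad_dot <- function(a, b) ad_sum(ad_mul(a, b))

#' Backpropagate gradients from a scalar output
#'
#' Seeds the output gradient at 1 and accumulates gradients into every
#' ancestor node (accessible via [ad_grad()]). Clears any gradients from a
#' previous call over the reachable subgraph first.
#'
#' @param loss scalar `ad_node`.
#' @return `loss`, invisibly.
#' @export
ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$val) == 1L)
  nodes <- collect_nodes(loss)
  for (nd in nodes) nd$grad <- NULL
  loss$grad <- matrix(1, 1, 1)
  ids <- vapply(nodes, function(n) n$id, integer(1))
  for (nd in nodes[order(ids, decreasing = TRUE)]) {
    if (is.null(nd$grad) || is.null(nd$backfn) || !nd$requires) next
    pg <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$requires) next
      if (is.null(pg[[k]])) next
      p$grad <- if (is.null(p$grad)) pg[[k]] else p$grad + pg[[k]]
    }
  }
  invisible(loss)
}

collect_nodes <- function(root) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    out[[length(out) + 1L]] <- nd
    if (nd$requires) for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  out
}

#' Gradient-descent-with-momentum optimizer state
#' @param params list of `ad_param` nodes.
#' @param lr learning rate.
#' @param momentum momentum coefficient.
#' @param weight_decay L2 penalty coefficient added to every gradient.
#' @return optimizer state for [sgd_step()].
#' @export
sgd_optimizer <- function(params, lr = 1e-3, momentum = 0.9,
                          weight_decay = 0) {
  vel <- lapply(params, function(p) matrix(0, nrow(p$val), ncol(p$val)))
  list(params = params, vel = vel, lr = lr, momentum = momentum,
       weight_decay = weight_decay)
}

#' One optimizer update from the current gradients
#' @param opt state from [sgd_optimizer()].
#' @return updated state.
#' @export
sgd_step <- function(opt) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- ad_grad(p)
    if (opt$weight_decay > 0) g <- g + opt$weight_decay * p$val
    opt$vel[[i]] <- opt$momentum * opt$vel[[i]] - opt$lr * g
    dimnames(opt$vel[[i]]) <- NULL
    p$val <- p$val + opt$vel[[i]]
  }
  opt
}

#' Numerical-vs-analytic gradient check
#'
#' Central finite differences on randomly chosen parameter entries, compared
#' with the gradients produced by [ad_backward()].
#'
#' @param loss_fn zero-argument closure rebuilding the scalar loss node from
#'   the current parameter values.
#' @param params list of `ad_param` nodes used inside `loss_fn`.
#' @param n_checks number of parameter entries probed.
#' @param h finite-difference step.
#' @param seed RNG seed for entry selection.
#' @return max relative discrepancy over the probed entries.
#' @export
ad_gradient_check <- function(loss_fn, params, n_checks = 20L, h = 1e-5,
                              seed = 1L) {
  set.seed(seed)
  loss <- loss_fn()
  ad_backward(loss)
  grads <- lapply(params, ad_grad)
  worst <- 0
  for (chk in seq_len(n_checks)) {
    pi_ <- sample(seq_along(params), 1)
    p <- params[[pi_]]
    ei <- sample(length(p$val), 1)
    orig <- p$val[ei]
    p$val[ei] <- orig + h
    lp <- ad_value(loss_fn())[1]
    p$val[ei] <- orig - h
    lm <- ad_value(loss_fn())[1]
    p$val[ei] <- orig
    num <- (lp - lm) / (2 * h)
    ana <- grads[[pi_]][ei]
    rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-4)
    worst <- max(worst, rel)
  }
  worst
}
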