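# Minimal tape-based reverse-mode automatic differentiation on matrices.
#
# The network components in this package (mixture density heads, the
# interaction module) are small MLPs; their training and the
# finite-difference gradient checks both run through this engine.
# Nodes are environments carrying a value, an accumulated gradient, parent
# references and a backward closure. Ops record onto the currently active
# tape; with no active tape the same ops run as plain forward computation.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' Start recording an autodiff tape
#'
#' Subsequent `ad_*` operations are recorded so that [ad_backward()] can
#' propagate gradients. Call [ad_tape_stop()] (or let `on.exit` do it) when
#' the forward pass is complete.
#' @return Invisibly, the tape environment.
#' @keywords internal
ad_tape_start <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  .ad$tape <- t
  invisible(t)
}

#' @rdname ad_tape_start
#' @keywords internal
ad_tape_stop <- function() {
  t <- .ad$tape
  .ad$tape <- NULL
  invisible(t)
}

ad_is_node <- function(x) is.environment(x) && !is.null(x$.ad_node)

# Create a node. `back` takes the output gradient and returns a list of
# gradients aligned with `parents`.
ad_node <- function(value, parents = list(), back = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$.ad_node <- TRUE
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$back <- back
  t <- .ad$tape
  if (!is.null(t) && !is.null(back)) {
    t$n <- t$n + 1L
    if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
    t$nodes[[t$n]] <- nd
  }
  nd
}

#' Wrap a parameter matrix as an autodiff leaf
#' @param value numeric matrix (or vector, kept as-is)
#' @keywords internal
ad_leaf <- function(value) ad_node(value)

ad_value <- function(x) if (ad_is_node(x)) x$value else x

# Coerce plain numerics to constant leaves so parent bookkeeping is uniform.
as_ad <- function(x) if (ad_is_node(x)) x else ad_node(x)

ad_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

#' Backpropagate from a scalar loss node
#'
#' Seeds the gradient of `loss` with 1 and sweeps the active tape in reverse
#' creation order, accumulating gradients into every upstream node
#' (including leaves created with [ad_leaf()]).
#' @param loss node holding a 1x1 (scalar) value
#' @keywords internal
ad_backward <- function(loss) {
  t <- .ad$tape
  if (is.null(t)) stop("ad_backward: no active tape")
  loss$grad <- matrix(1, nrow = 1L, ncol = 1L)
  if (t$n > 0L) for (i in t$n:1L) {
    nd <- t$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$back)) next
    gs <- nd$back(nd$grad)
    for (k in seq_along(gs)) {
      if (!is.null(gs[[k]])) ad_accum(nd$parents[[k]], gs[[k]])
    }
  }
  invisible(NULL)
}

#' Read the accumulated gradient of a leaf, zero-filled if untouched
#' @keywords internal
ad_grad <- function(node) {
  if (!is.null(node$grad)) return(node$grad)
  v <- node$value
  if (is.matrix(v)) matrix(0, nrow(v), ncol(v)) else 0 * v
}

## ---- primitive operations -------------------------------------------------

ad_matmul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  av <- a$value; bv <- b$value
  ad_node(av / bv, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

# x + scalar constant
ad_addc <- function(x, c) {
  x <- as_ad(x)
  ad_node(x$value + c, list(x), function(g) list(g))
}

# x * scalar constant
ad_scale <- function(x, c) {
  x <- as_ad(x)
  ad_node(x$value * c, list(x), function(g) list(g * c))
}

# add a 1 x d row vector to every row of an n x d matrix (bias add)
ad_add_rvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  xv <- x$value
  bv <- as.numeric(b$value)
  ad_node(sweep(xv, 2L, bv, "+"), list(x, b), function(g) {
    list(g, matrix(colSums(g), nrow = 1L))
  })
}

# subtract a 1 x d row-vector node from every row
ad_sub_rvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  ad_node(sweep(x$value, 2L, as.numeric(b$value), "-"), list(x, b), function(g) {
    list(g, matrix(-colSums(g), nrow = 1L))
  })
}

# multiply every row elementwise by a 1 x d row-vector node
ad_mul_rvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  xv <- x$value; bv <- as.numeric(b$value)
  ad_node(sweep(xv, 2L, bv, "*"), list(x, b), function(g) {
    list(sweep(g, 2L, bv, "*"), matrix(colSums(g * xv), nrow = 1L))
  })
}

# divide every row elementwise by a 1 x d row-vector node
ad_div_rvec <- function(x, b) {
  x <- as_ad(x); b <- as_ad(b)
  xv <- x$value; bv <- as.numeric(b$value)
  yv <- sweep(xv, 2L, bv, "/")
  ad_node(yv, list(x, b), function(g) {
    list(sweep(g, 2L, bv, "/"),
         matrix(-colSums(g * yv) / bv, nrow = 1L))
  })
}

# subtract an n x 1 column-vector node from every column of an n x d matrix
ad_sub_cvec <- function(x, v) {
  x <- as_ad(x); v <- as_ad(v)
  vv <- as.numeric(v$value)
  ad_node(x$value - vv, list(x, v), function(g) {
    list(g, matrix(-rowSums(g), ncol = 1L))
  })
}

# multiply every column elementwise by an n x 1 column-vector node
ad_mul_cvec <- function(x, v) {
  x <- as_ad(x); v <- as_ad(v)
  xv <- x$value; vv <- as.numeric(v$value)
  ad_node(xv * vv, list(x, v), function(g) {
    list(g * vv, matrix(rowSums(g * xv), ncol = 1L))
  })
}

ad_relu <- function(x) {
  x <- as_ad(x)
  m <- x$value > 0
  ad_node(x$value * m, list(x), function(g) list(g * m))
}

# numerically stable softplus log(1 + e^x)
softplus <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

ad_softplus <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  ad_node(softplus(xv), list(x), function(g) list(g * s))
}

# shifted softplus: SSP(x) = ln(e^x + 1) - ln 2, so SSP(0) = 0
ad_ssp <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  s <- 1 / (1 + exp(-xv))
  ad_node(softplus(xv) - log(2), list(x), function(g) list(g * s))
}

ad_exp <- function(x) {
  x <- as_ad(x)
  ev <- exp(x$value)
  ad_node(ev, list(x), function(g) list(g * ev))
}

ad_log <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  ad_node(log(xv), list(x), function(g) list(g / xv))
}

ad_sqrt <- function(x) {
  x <- as_ad(x)
  sv <- sqrt(x$value)
  ad_node(sv, list(x), function(g) list(g / (2 * sv)))
}

ad_abs <- function(x) {
  x <- as_ad(x)
  sg <- sign(x$value)
  ad_node(abs(x$value), list(x), function(g) list(g * sg))
}

ad_sum <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  ad_node(matrix(sum(xv), 1L, 1L), list(x), function(g) {
    list(matrix(as.numeric(g), nrow(xv), ncol(xv)))
  })
}

ad_mean <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  n <- length(xv)
  ad_node(matrix(mean(xv), 1L, 1L), list(x), function(g) {
    list(matrix(as.numeric(g) / n, nrow(xv), ncol(xv)))
  })
}

# column means of an n x d matrix -> 1 x d
ad_colmeans <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  n <- nrow(xv)
  ad_node(matrix(colMeans(xv), nrow = 1L), list(x), function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), nrow = n))
  })
}

# row-wise log-sum-exp of an n x K matrix -> n x 1 (stable)
ad_logsumexp_rows <- function(x) {
  x <- as_ad(x)
  xv <- x$value
  m <- apply(xv, 1L, max)
  lse <- m + log(rowSums(exp(xv - m)))
  sm <- exp(xv - lse)  # row-wise softmax
  ad_node(matrix(lse, ncol = 1L), list(x), function(g) {
    list(sm * as.numeric(g))
  })
}

ad_concat_cols <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  na <- ncol(a$value)
  ad_node(cbind(a$value, b$value), list(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE])
  })
}

# select rows (with repetition allowed); back scatters-adds
ad_index_rows <- function(x, idx) {
  x <- as_ad(x)
  xv <- x$value
  ad_node(xv[idx, , drop = FALSE], list(x), function(g) {
    out <- matrix(0, nrow(xv), ncol(xv))
    # rowsum aggregates duplicate indices
    agg <- rowsum(g, group = idx)
    out[as.integer(rownames(agg)), ] <- agg
    list(out)
  })
}

# segment sum: rows of x summed within groups (group = integer vector);
# returns G x d where G = number of distinct groups in sorted order
ad_rowsum_by <- function(x, group) {
  x <- as_ad(x)
  xv <- x$value
  gf <- as.integer(factor(group))
  ad_node(rowsum(xv, gf), list(x), function(g) {
    list(g[gf, , drop = FALSE])
  })
}

# scatter rows of x (m x d) into a zero (G x d) matrix at positions idx
ad_embed_rows <- function(x, idx, G) {
  x <- as_ad(x)
  xv <- x$value
  ad_node({
    out <- matrix(0, G, ncol(xv)); out[idx, ] <- xv; out
  }, list(x), function(g) {
    list(g[idx, , drop = FALSE])
  })
}

# inverted dropout with an externally supplied mask (NULL = identity)
ad_dropout <- function(x, mask) {
  if (is.null(mask)) return(as_ad(x))
  x <- as_ad(x)
  ad_node(x$value * mask, list(x), function(g) list(g * mask))
}
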