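# Tape-based reverse-mode automatic differentiation.
#
# Every differentiable operation appends a node (an environment) to a global
# tape. A node holds its value `v`, accumulated gradient `g`, a backward
# closure `bk` and a flag `req` saying whether any ancestor is a parameter.
# Operations whose inputs are all constants skip the backward closure, so
# pure inference pays only for the forward values.

.tape <- new.env(parent = emptyenv())
.tape$nodes <- vector("list", 1024L)
.tape$n <- 0L

#' Reset the autodiff tape
#'
#' Drops all recorded nodes. Called at the start of every training step and
#' by the plain (non-differentiating) wrappers around network forwards.
#' @return Invisibly `NULL`.
#' @keywords internal
tape_reset <- function() {
  .tape$nodes <- vector("list", 1024L)
  .tape$n <- 0L
  invisible(NULL)
}

is_node <- function(x) inherits(x, "swinreg_node")

node_new <- function(value, backward = NULL, req = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$v <- value
  nd$g <- NULL
  nd$bk <- backward
  nd$req <- req
  class(nd) <- "swinreg_node"
  n <- .tape$n + 1L
  if (n > length(.tape$nodes)) {
    .tape$nodes <- c(.tape$nodes, vector("list", length(.tape$nodes)))
  }
  .tape$nodes[[n]] <- nd
  nd$ix <- n
  .tape$n <- n
  nd
}

#' Wrap an array as a constant (no gradient) tape node
#' @param value Numeric array.
#' @keywords internal
ad_const <- function(value) {
  if (is_node(value)) return(value)
  node_new(value, req = FALSE)
}

#' Wrap an array as a parameter (gradient-carrying) tape node
#' @param value Numeric array.
#' @keywords internal
ad_param <- function(value) node_new(value, req = TRUE)

# Accumulate gradient `g` into node `nd` (no-op for constants).
acc <- function(nd, g) {
  if (!nd$req) return(invisible(NULL))
  if (is.null(nd$g)) nd$g <- g else nd$g <- nd$g + g
  invisible(NULL)
}

any_req <- function(...) {
  for (x in list(...)) if (x$req) return(TRUE)
  FALSE
}

#' Run the backward pass from a scalar loss node
#'
#' Seeds the loss gradient with 1 and walks the tape in reverse creation
#' order, invoking each node's backward closure. Parameter nodes end up with
#' their gradient in `$g`.
#' @param loss A scalar tape node.
#' @return Invisibly `NULL`.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(is_node(loss), length(loss$v) == 1L)
  loss$g <- 1
  nodes <- .tape$nodes
  for (i in seq.int(loss$ix, 1L)) {
    nd <- nodes[[i]]
    if (!is.null(nd$g) && !is.null(nd$bk)) nd$bk(nd)
  }
  invisible(NULL)
}

# Value extractor usable on nodes and plain arrays.
vv <- function(x) if (is_node(x)) x$v else x

# --- Adam optimizer over flat named parameter lists --------------------------

#' Create Adam optimizer state for a flat parameter list
#' @param params Named list of numeric arrays.
#' @param lr Learning rate.
#' @param beta1,beta2 Exponential decay rates for the moment estimates. The
#'   defaults follow common GAN practice.
#' @param eps Numerical fuzz in the update denominator.
#' @keywords internal
adam_new <- function(params, lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                     eps = 1e-8) {
  zeros_like <- function(p) {
    z <- p
    z[] <- 0
    z
  }
  list(m = lapply(params, zeros_like), v = lapply(params, zeros_like),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

#' One Adam update step
#' @param params Named list of numeric arrays.
#' @param grads Named list of gradients (entries may be `NULL` for unused
#'   parameters; those are left untouched apart from moment decay).
#' @param st State from [adam_new()].
#' @return `list(params = updated params, st = updated state)`.
#' @keywords internal
adam_step <- function(params, grads, st) {
  st$t <- st$t + 1L
  bc1 <- 1 - st$beta1^st$t
  bc2 <- 1 - st$beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g * g
    mhat <- st$m[[nm]] / bc1
    vhat <- st$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
  }
  list(params = params, st = st)
}

# Wrap a flat parameter list as tape nodes.
wrap_params <- function(params) lapply(params, ad_param)

# Wrap as constants (e.g. the frozen discriminator during the G step).
const_params <- function(params) lapply(params, ad_const)

# Collect gradients from wrapped parameter nodes.
collect_grads <- function(pnodes) lapply(pnodes, function(nd) nd$g)
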