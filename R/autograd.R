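# Reverse-mode automatic differentiation on a dynamically built graph.
# Nodes are environments carrying a value, an accumulated gradient, their
# parents and a backward closure; node ids increase in creation order, so
# reverse topological order is simply decreasing id among the ancestors
# of the loss. Only what the network needs is implemented.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L
.ag$no_grad <- FALSE

ag_is_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (ag_is_node(x)) x$v else x

new_node <- function(v, parents = list(), bw = NULL, param = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$param <- param
  e$requires <- param ||
    any(vapply(parents, function(p) ag_is_node(p) && p$requires, logical(1)))
  .ag$counter <- .ag$counter + 1L
  e$id <- .ag$counter
  class(e) <- "ag_node"
  e
}

ag_const <- function(v) new_node(v)

ag_param <- function(v, decay = TRUE) {
  e <- new_node(v, param = TRUE)
  e$decay <- decay
  e
}

# run expr with gradient recording disabled (inference mode)
no_grad <- function(expr) {
  old <- .ag$no_grad
  .ag$no_grad <- TRUE
  on.exit(.ag$no_grad <- old)
  force(expr)
}

ag_op <- function(v, parents, bw) {
  if (.ag$no_grad) return(new_node(v))
  node <- new_node(v, parents = parents, bw = bw)
  if (!node$requires) node$bw <- NULL
  node
}

add_grad <- function(p, g) {
  if (ag_is_node(p) && p$requires) {
    p$grad <- if (is.null(p$grad)) g else p$grad + g
  }
  invisible(NULL)
}

# backpropagate from a scalar loss node
ag_backward <- function(loss) {
  stopifnot(ag_is_node(loss), length(loss$v) == 1L)
  # collect ancestors that require grad
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]]) || !nd$requires) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (ag_is_node(p)) stack[[length(stack) + 1L]] <- p
  }
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  loss$grad <- 1
  for (nd in nodes) {
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd)
    # free the backward closure, cached tensors and intermediate
    # values/gradients as we go: consumers (higher ids) have already run
    nd$bw <- NULL
    if (!nd$param) {
      nd$v <- NULL
      nd$grad <- NULL
    }
  }
  invisible(NULL)
}
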