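# Reverse-mode array engine.
#
# A node (class "ag") is an environment holding a value array `v`, an
# accumulated gradient `grad`, its input nodes `parents` and a backward
# closure `bw` mapping the node's gradient to a list of parent gradients.
# Graphs are rebuilt on every forward pass; `ag_backward()` runs a
# depth-first topological sort and propagates gradients once per node.
# Nodes whose inputs carry no gradient requirement record nothing, so
# inference pays no tape overhead.

ag_new <- function(v, parents = NULL, bw = NULL, rq = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  n$rq <- rq
  class(n) <- "ag"
  n
}

is_ag <- function(x) inherits(x, "ag")

# value of a node or pass-through for plain arrays
ag_v <- function(x) if (is_ag(x)) x$v else x

ag_const <- function(v) ag_new(v)

# leaf bound to a parameter environment; gradients accumulate into par$grad
ag_leaf <- function(par) {
  n <- ag_new(par$value, rq = isTRUE(par$trainable))
  n$par <- par
  n
}

ag_rq <- function(...) {
  for (x in list(...)) if (is_ag(x) && x$rq) return(TRUE)
  FALSE
}

# Record an op: `v` the computed value, `inputs` the argument list (ag nodes
# or constants), `bw` a function(grad) -> list of per-input gradients (NULL
# entries for constants).  When no input requires gradients the tape is
# skipped entirely.
ag_op <- function(v, inputs, bw) {
  if (!any(vapply(inputs, function(i) is_ag(i) && i$rq, logical(1)))) {
    return(ag_new(v))
  }
  ag_new(v, parents = inputs, bw = bw, rq = TRUE)
}

#' @export
print.ag <- function(x, ...) {
  d <- dim(x$v)
  cat("<ag ", if (is.null(d)) length(x$v) else paste(d, collapse = "x"),
      if (x$rq) " grad", ">\n", sep = "")
  invisible(x)
}

# Backpropagate from a scalar (or any) root node.  Parameter leaves
# accumulate into their ev_par's `grad` field.
ag_backward <- function(root, seed = NULL) {
  stopifnot(is_ag(root))
  if (!root$rq) return(invisible(NULL))
  topo <- vector("list", 256L)
  nt <- 0L
  visit <- function(n) {
    if (isTRUE(n$.vis)) return(invisible(NULL))
    n$.vis <- TRUE
    if (!is.null(n$parents)) {
      for (p in n$parents) if (is_ag(p) && p$rq) visit(p)
    }
    nt <<- nt + 1L
    if (nt > length(topo)) topo[[2L * nt]] <<- NULL
    topo[[nt]] <<- n
    invisible(NULL)
  }
  visit(root)
  topo <- topo[seq_len(nt)]
  for (n in topo) n$grad <- NULL
  if (is.null(seed)) {
    seed <- ag_v(root)
    seed[] <- 1
  }
  root$grad <- seed
  for (n in rev(topo)) {
    n$.vis <- NULL
    g <- n$grad
    if (is.null(g)) next
    if (!is.null(n$bw)) {
      gs <- n$bw(g)
      ps <- n$parents
      for (j in seq_along(ps)) {
        p <- ps[[j]]
        if (is_ag(p) && p$rq && !is.null(gs[[j]])) {
          p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
        }
      }
    } else if (!is.null(n$par)) {
      n$par$grad <- if (is.null(n$par$grad)) g else n$par$grad + g
    }
  }
  invisible(NULL)
}
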