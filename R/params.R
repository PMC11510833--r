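# Parameter containers.
#
# Every learnable array lives in its own environment so that modules, the
# optimizer and checkpoints all see one shared copy.  `value` is a plain R
# array; `grad` is filled by the backward pass; `trainable = FALSE` marks
# buffers (batch-norm running statistics, the fixed DFL projection).

par_new <- function(dim, value = NULL, trainable = TRUE) {
  p <- new.env(parent = emptyenv())
  if (is.null(value)) value <- array(0, dim = dim)
  if (is.null(dim(value)) && length(dim) > 1L) dim(value) <- dim
  p$value <- value
  p$grad <- NULL
  p$trainable <- trainable
  class(p) <- "ev_par"
  p
}

par_kaiming <- function(dim, fan_in, gain = sqrt(2)) {
  par_new(dim, array(stats::rnorm(prod(dim), sd = gain / sqrt(fan_in)), dim = dim))
}

#' @export
print.ev_par <- function(x, ...) {
  cat("<ev_par ", paste(dim(x$value), collapse = "x"),
      if (!x$trainable) " (buffer)", ">\n", sep = "")
  invisible(x)
}

# Recursively collect parameter environments from a module tree.
collect_pars <- function(m) {
  out <- list()
  if (inherits(m, "ev_par")) return(list(m))
  if (is.list(m)) {
    for (el in m) {
      if (inherits(el, "ev_par")) out <- c(out, list(el))
      else if (is.list(el)) out <- c(out, collect_pars(el))
    }
  }
  out
}

n_trainable <- function(pars) {
  sum(vapply(pars, function(p) if (p$trainable) length(p$value) else 0L, numeric(1)))
}

zero_grads <- function(pars) {
  for (p in pars) p$grad <- NULL
  invisible(NULL)
}
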