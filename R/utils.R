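#' @keywords internal
"_PACKAGE"

# Numerically stable logistic.
sigmoid <- function(x) 1 / (1 + exp(-x))

# Exact (erf-based) GELU and its derivative.
gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Column-wise softmax of a matrix (each column a logit vector).
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

#' Derive a stage-specific seed from a master seed
#'
#' Fans a master seed out to independent sub-seeds by hashing the stage name,
#' so adding a pipeline stage never shifts the random stream of another stage.
#' The result is always a valid 32-bit integer seed.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or integer tokens naming the stage (and any indices).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  tokens <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.double(master_seed) %% 2147483647
  for (tok in tokens) {
    for (cc in utf8ToInt(tok)) {
      h <- (h * 31 + cc) %% 2147483647
    }
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- flat <-> nested parameter containers -----------------------------------

#' Flatten a nested parameter list into one numeric vector
#'
#' Depth-first, in list order; the inverse ([unflatten_params()]) requires
#' the original structure as a template. This is the vector the optimizer
#' and the meta-learning engine operate on.
#'
#' @param params Nested list of numeric arrays.
#' @return Numeric vector of all parameter values.
#' @export
flatten_params <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Rebuild a nested parameter list from a flat vector
#'
#' @param flat Numeric vector from [flatten_params()].
#' @param template Nested list fixing the structure and array dims.
#' @return Nested list shaped like \code{template}.
#' @export
unflatten_params <- function(flat, template) {
  pos <- 0L
  rebuild <- function(node) {
    if (is.list(node)) {
      lapply(node, rebuild)
    } else {
      n <- length(node)
      out <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (!is.null(dim(node))) dim(out) <- dim(node)
      out
    }
  }
  out <- rebuild(template)
  stopifnot(pos == length(flat))
  # carry over non-trainable metadata (class, normalization state)
  attributes(out) <- attributes(template)
  out
}

# Map a function over every leaf array of a nested parameter list.
map_params <- function(params, f) {
  if (is.list(params)) lapply(params, map_params, f = f) else f(params)
}

# Elementwise combination of two structurally identical nested lists.
zip_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- zip_params(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}
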