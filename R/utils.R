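#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif setNames
#' @importFrom utils head modifyList
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic entry points funnel through this so every output is a pure
# function of (inputs, seed).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, keeping the
# result inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + sum(utf8ToInt(as.character(stream)))) %% 2147483587
  as.integer(s) + 1L
}

abort_config <- function(msg) abort(msg, class = "cytodistill_config_error")
abort_data <- function(msg) abort(msg, class = "cytodistill_data_error")
abort_contract <- function(msg) abort(msg, class = "cytodistill_contract_error")

# Apply `f` elementwise over two parameter trees with identical structure.
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

# Flatten a parameter tree into a single numeric vector (deterministic order).
tree_unlist <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_unlist), use.names = FALSE)
  else as.numeric(a)
}

# Total number of scalar elements in a parameter tree.
tree_numel <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_numel, numeric(1)))
  else length(a)
}

# Content hash of any R object, via serialization + md5 (used for the
# frozen-teacher contract and run manifests).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
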