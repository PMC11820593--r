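#' @useDynLib ecgfusion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Deterministic sub-seed derivation: every stage that consumes randomness
# hashes (master seed, tag) so seeds never collide across stages and the
# whole pipeline is reproducible from one integer.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG state (does not disturb the caller's RNG).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# Map a function over every numeric leaf of a nested list, preserving shape.
tree_map <- function(f, tree) {
  if (is.list(tree)) return(lapply(tree, function(t) tree_map(f, t)))
  f(tree)
}

# Map over matched leaves of two identically-shaped trees.
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    stopifnot(is.list(b), length(a) == length(b))
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    return(out)
  }
  f(a, b)
}

# Sum of all leaves after applying f (used for loss penalties / diagnostics).
tree_reduce_sum <- function(f, tree) {
  if (is.list(tree)) return(sum(vapply(tree, function(t) tree_reduce_sum(f, t), 0)))
  f(tree)
}
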