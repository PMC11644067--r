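#' Independent reproducible random streams
#'
#' R has a single global RNG. Training needs several independent, individually
#' reproducible sources of randomness (weight init, data shuffling, the BSDA
#' sampling branch) so that disabling one consumer does not shift the draws of
#' the others. A stream captures its own `.Random.seed` and swaps it in and
#' out around each use.
#'
#' @param seed integer seed for the stream.
#' @return an environment holding the stream state.
#' @keywords internal
rng_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- get_global_seed()
  set.seed(as.integer(seed))
  s$state <- .Random.seed
  restore_global_seed(old)
  s
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression using a stream's RNG state
#' @param stream a [rng_stream()] object.
#' @param expr expression to evaluate.
#' @keywords internal
with_stream <- function(stream, expr) {
  old <- get_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    restore_global_seed(old)
  })
  expr
}

# Derive a bounded child seed from a parent seed and a tag; keeps everything
# below 2^31 even for large parent seeds.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 7919 + h * 104729 + 12345) %% 2147483647)
}
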