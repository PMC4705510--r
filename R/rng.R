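#' Named random-number streams from one master seed
#'
#' A simulation draws random numbers for several independent purposes
#' (agent placement, movement, per-cycle shuffling, stochastic rules).
#' Each purpose gets its own stream, seeded deterministically from the
#' master seed, so adding draws to one stream never perturbs another and
#' the whole run is reproducible from a single integer.
#'
#' @param seed single integer master seed.
#' @param names character vector of stream names to create.
#' @return an object of class `rng_streams`.
#' @export
rng_streams <- function(seed,
                        names = c("placement", "movement", "shuffle", "rules")) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  for (nm in names) {
    set.seed(derive_stream_seed(seed, nm))
    assign(nm, get(".Random.seed", envir = globalenv()), envir = env)
  }
  .restore_global_seed(old)
  structure(list(seed = seed, streams = env), class = "rng_streams")
}

#' Derive a child seed for a named stream
#'
#' Deterministic hash of (master seed, stream name) into the 32-bit
#' signed-integer range accepted by [set.seed()].
#'
#' @param seed master seed.
#' @param name stream name.
#' @return integer seed.
#' @export
derive_stream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 69621) %% 2147483629 + 1)
}

#' Evaluate a function under a named stream
#'
#' Swaps the stream's saved RNG state into `.Random.seed`, evaluates
#' `fun()`, then saves the advanced state back and restores whatever
#' global state existed before.
#'
#' @param rng an `rng_streams` object.
#' @param name stream name.
#' @param fun zero-argument function performing the draws.
#' @return the value of `fun()`.
#' @export
with_stream <- function(rng, name, fun) {
  stopifnot(inherits(rng, "rng_streams"))
  if (!exists(name, envir = rng$streams, inherits = FALSE)) {
    stop("unknown RNG stream: ", name)
  }
  old <- .save_global_seed()
  assign(".Random.seed", get(name, envir = rng$streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", envir = globalenv()), envir = rng$streams)
    .restore_global_seed(old)
  })
  fun()
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
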