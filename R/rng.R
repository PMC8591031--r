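#' @importFrom stats runif rnorm rlnorm rpois sd
#' @importFrom utils modifyList
NULL

# Independent, reproducible RNG streams ---------------------------------------
#
# Every network object (group, synapse group, behaviour) owns its own
# Mersenne-Twister stream, derived from the network's root seed and the
# object's stable path ("<group>/beh/<key>"). Drawing from one stream never
# advances another, so adding a recorder (or any passive module) leaves the
# dynamical trajectory bitwise unchanged.

derive_seed <- function(root_seed, path) {
  h <- digest::digest2int(paste(root_seed, path, sep = "/"))
  bitwAnd(h, 0x7FFFFFFFL)
}

new_rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  rng_reset(e)
  e
}

rng_reset <- function(stream) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(stream$seed, kind = "Mersenne-Twister")
  stream$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(stream)
}

# Evaluate fn() with the stream's state installed; the advanced state is saved
# back and the caller's global RNG state is restored exactly.
with_stream <- function(stream, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  fn()
}

# Diversification strings -----------------------------------------------------
#
# Grammar:  SPEC := NUMBER | NAME "(" ARGS ")" [";plot"]
#           NAME := uniform | normal | lognormal | poisson
# A bare "uniform" is shorthand for uniform(0,1). The optional ";plot" suffix
# is parsed and recorded but has no effect in the core (a histogram export
# hook exists in the storage layer). Custom sampler functions f(n) are also
# accepted wherever a spec string is.

.div_distributions <- c("uniform", "normal", "lognormal", "poisson")

#' Parse a diversification specification
#'
#' Turns a scalar, a distribution string such as `"normal(0.9,0.1)"`, or a
#' sampler function into a parsed specification that [sample_spec()] can draw
#' from. This is the mechanism that lets any behaviour parameter become a
#' per-neuron vector without changing model code.
#'
#' @param spec a single number, a string in the grammar
#'   `NUMBER | NAME "(" args ")" [";plot"]` with `NAME` one of
#'   `uniform`, `normal`, `lognormal`, `poisson`, or a function of `n`
#'   returning `n` samples.
#' @return an object of class `div_spec`.
#' @examples
#' parse_div_spec(0.5)
#' parse_div_spec("normal(0.9,0.1)")
#' parse_div_spec("uniform")
#' @export
parse_div_spec <- function(spec) {
  if (inherits(spec, "div_spec")) return(spec)
  if (is.function(spec)) {
    return(structure(list(kind = "function", fn = spec, plot = FALSE),
                     class = "div_spec"))
  }
  if (is.numeric(spec) && length(spec) == 1 && !is.na(spec)) {
    return(structure(list(kind = "constant", value = as.numeric(spec),
                          plot = FALSE), class = "div_spec"))
  }
  if (is.numeric(spec) && length(spec) > 1) {
    return(structure(list(kind = "vector", value = as.numeric(spec),
                          plot = FALSE), class = "div_spec"))
  }
  if (!is.character(spec) || length(spec) != 1) {
    stop("initialization spec must be a number, a string, or a function")
  }
  s <- trimws(spec)
  plot <- FALSE
  if (grepl(";\\s*plot\\s*$", s)) {
    plot <- TRUE
    s <- trimws(sub(";\\s*plot\\s*$", "", s))
  }
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) {
    return(structure(list(kind = "constant", value = num, plot = plot),
                     class = "div_spec"))
  }
  m <- regmatches(s, regexec("^([A-Za-z_]+)\\s*(\\(([^)]*)\\))?$", s))[[1]]
  if (length(m) == 0) {
    stop(sprintf("cannot parse initialization spec '%s'", spec))
  }
  name <- m[2]
  if (!name %in% .div_distributions) {
    stop(sprintf(
      "unknown distribution '%s' in spec '%s'; supported distributions: %s",
      name, spec, paste(.div_distributions, collapse = ", ")))
  }
  args <- numeric(0)
  if (nzchar(m[3])) {
    argstr <- trimws(m[4])
    if (nzchar(argstr)) {
      args <- suppressWarnings(as.numeric(strsplit(argstr, ",")[[1]]))
      if (anyNA(args)) {
        stop(sprintf("non-numeric argument in spec '%s'", spec))
      }
    }
  }
  defaults <- switch(name,
    uniform   = c(0, 1),
    normal    = c(0, 1),
    lognormal = c(0, 1),
    poisson   = c(1))
  if (length(args) > length(defaults)) {
    stop(sprintf("too many arguments for %s() in spec '%s'", name, spec))
  }
  full <- defaults
  if (length(args) > 0) full[seq_along(args)] <- args
  structure(list(kind = "distribution", name = name, args = full, plot = plot),
            class = "div_spec")
}

#' Draw from a parsed diversification specification
#'
#' @param spec a `div_spec` (or anything [parse_div_spec()] accepts).
#' @param n number of samples (one per neuron or synapse).
#' @return numeric vector of length `n`. Constant specs are recycled; the
#'   draw consumes the caller's current RNG state, so wrap in the owning
#'   object's stream for reproducibility.
#' @export
sample_spec <- function(spec, n) {
  spec <- parse_div_spec(spec)
  switch(spec$kind,
    constant = rep(spec$value, n),
    vector = {
      if (length(spec$value) != n) {
        stop(sprintf("explicit vector spec has length %d, expected %d",
                     length(spec$value), n))
      }
      spec$value
    },
    "function" = {
      out <- spec$fn(n)
      if (length(out) != n) stop("custom sampler returned wrong length")
      as.numeric(out)
    },
    distribution = switch(spec$name,
      uniform   = runif(n, spec$args[1], spec$args[2]),
      normal    = rnorm(n, spec$args[1], spec$args[2]),
      lognormal = rlnorm(n, spec$args[1], spec$args[2]),
      poisson   = as.numeric(rpois(n, spec$args[1]))))
}

# TRUE when the spec makes per-neuron values (anything but a scalar constant).
spec_is_heterogeneous <- function(spec) {
  p <- parse_div_spec(spec)
  !identical(p$kind, "constant")
}
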