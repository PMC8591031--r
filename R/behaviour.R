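# Behaviour modules: the unit of user-defined computation. A behaviour has a
# positive numeric key (its position in the global execution pipeline), raw
# constructor arguments (init_params, which may contain diversification
# strings), and two hooks: set_variables() once at network initialization and
# new_iteration() once per simulated step.

#' @import R6
NULL

#' Behaviour module base class
#'
#' All dynamics in a network live in behaviour modules attached to a
#' [NeuronGroup], [SynapseGroup] or [Network] under a positive numeric key.
#' During [Network]$initialize_network() the keys of every behaviour across
#' all objects are sorted into one global pipeline; each simulated step then
#' runs every module's `new_iteration()` once, in key order.
#'
#' Subclass this (or use [behaviour()] for ad-hoc modules) and override
#' `set_variables(parent)` and `new_iteration(parent)`. `get_init_attr()`
#' retrieves constructor arguments and applies diversification strings, so a
#' parameter written as `"normal(0.9,0.1)"` silently becomes a per-neuron
#' vector.
#'
#' @export
Behaviour <- R6::R6Class("Behaviour",
  public = list(
    #' @field key positive numeric execution-order key (set when attached).
    key = NULL,
    #' @field init_params raw constructor arguments.
    init_params = NULL,
    #' @field tags character vector of tags for the tagging system.
    tags = character(0),
    #' @field parent owning group or network; bound at initialization.
    parent = NULL,
    #' @field network the network the parent belongs to.
    network = NULL,
    #' @field rng this module's private RNG stream.
    rng = NULL,
    #' @field reg_index global registration index (tie-break bookkeeping).
    reg_index = NA_integer_,
    #' @field reads names of state variables this module reads (module graph).
    reads = character(0),
    #' @field writes names of state variables this module writes.
    writes = character(0),

    #' @description Create a behaviour module.
    #' @param ... named init parameters; the special names `tags`, `reads`
    #'   and `writes` are stored on the corresponding fields.
    initialize = function(...) {
      p <- list(...)
      if (!is.null(p$tags)) { self$tags <- as.character(p$tags); p$tags <- NULL }
      if (!is.null(p$reads)) { self$reads <- p$reads; p$reads <- NULL }
      if (!is.null(p$writes)) { self$writes <- p$writes; p$writes <- NULL }
      self$init_params <- p
    },

    #' @description Initialization hook; called once per network
    #'   initialization, in pipeline order, before any `new_iteration`.
    #' @param parent the owning group or network.
    set_variables = function(parent) invisible(NULL),

    #' @description Per-step hook; called once per simulated iteration in
    #'   pipeline order.
    #' @param parent the owning group or network.
    new_iteration = function(parent) invisible(NULL),

    #' @description Fetch a constructor argument, applying diversification.
    #' @param name parameter name.
    #' @param default value used when the parameter was not supplied.
    #' @param diversify if TRUE (default) distribution strings / sampler
    #'   functions are expanded to one draw per neuron (or per element of
    #'   `n`), using this module's private stream.
    #' @param n number of elements for a diversified draw; defaults to the
    #'   parent group's size.
    get_init_attr = function(name, default = NULL, diversify = TRUE, n = NULL) {
      val <- self$init_params[[name]]
      if (is.null(val)) val <- default
      if (is.null(val)) return(NULL)
      if (!diversify) return(val)
      spec <- parse_div_spec(val)
      if (identical(spec$kind, "constant")) return(spec$value)
      if (is.null(n)) n <- self$parent$size
      with_stream(self$rng, function() sample_spec(spec, n))
    },

    #' @description Short human-readable label (used in the module graph).
    label = function() {
      sprintf("%s(%s)", class(self)[1], format(self$key))
    }
  )
)

#' Create an ad-hoc behaviour module from functions
#'
#' Convenience wrapper around [Behaviour] for one-off modules: supply the two
#' hooks as closures instead of writing an R6 subclass.
#'
#' @param setup `function(self, parent)` run once at network initialization
#'   (may be `NULL`).
#' @param step `function(self, parent)` run once per iteration (may be
#'   `NULL`).
#' @param ... named init parameters, plus optional `tags`, `reads`, `writes`.
#' @return a [Behaviour] instance.
#' @examples
#' counter <- behaviour(
#'   setup = function(self, parent) self$count <- 0,
#'   step  = function(self, parent) self$count <- self$count + 1
#' )
#' @export
behaviour <- function(setup = NULL, step = NULL, ...) {
  AdHoc <- R6::R6Class("AdHocBehaviour", inherit = Behaviour,
    public = list(
      count = NULL,   # scratch slot commonly used by ad-hoc modules
      state = NULL,   # generic private state slot
      setup_fn = NULL,
      step_fn = NULL,
      set_variables = function(parent) {
        if (!is.null(self$setup_fn)) self$setup_fn(self, parent)
        invisible(NULL)
      },
      new_iteration = function(parent) {
        if (!is.null(self$step_fn)) self$step_fn(self, parent)
        invisible(NULL)
      }
    )
  )
  b <- AdHoc$new(...)
  b$setup_fn <- setup
  b$step_fn <- step
  b
}
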