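# Recorders: behaviour modules that evaluate compiled expression strings at a
# fixed interval and store the results as time series. The expression string
# is simultaneously the trace's tag, so recorded data is retrieved through
# the same tagging system as every other object.

# -- expression DSL ------------------------------------------------------------
#
# Surface syntax (kept numpy-flavoured for compatibility with model strings):
#   attribute access   n.<varname>        (s.<varname> / synapse.<varname>)
#   function calls     np.<fn>(expr)      fn in the whitelist below
#   arithmetic         + - * / ^  and comparisons > < >= <= == !=
#   special            n.iteration        current iteration number
# Nothing else resolves: the evaluation environment is built from scratch for
# each compiled program, so expressions cannot touch the calling session.

.np_whitelist <- list(
  "np.mean"   = function(x) mean(x),
  "np.sum"    = function(x) sum(x),
  "np.max"    = function(x) max(x),
  "np.min"    = function(x) min(x),
  "np.std"    = function(x) sqrt(mean((x - mean(x))^2)),
  "np.var"    = function(x) mean((x - mean(x))^2),
  "np.median" = function(x) stats::median(x),
  "np.abs"    = function(x) abs(x),
  "np.where"  = function(x) which(x),
  "np.any"    = function(x) any(x),
  "np.all"    = function(x) all(x),
  "np.length" = function(x) length(x)
)

.dsl_operators <- c("+", "-", "*", "/", "^", "(", ">", "<", ">=", "<=",
                    "==", "!=", "&", "|", "!")

#' Compile a recording expression
#'
#' Parses an expression string of the recorder DSL (e.g. `"n.voltage"` or
#' `"np.mean(n.voltage)"`) and validates every symbol against the DSL
#' surface: `n.<var>` (neuron state), `s.<var>` / `synapse.<var>` (synapse
#' matrices), `np.<fn>` calls from a fixed whitelist, arithmetic/comparison
#' operators and numeric literals. Unknown names are rejected at compile
#' time, all at once.
#'
#' @param source the expression string.
#' @return an `expression_program` object.
#' @export
compile_expression <- function(source) {
  stopifnot(is.character(source), length(source) == 1)
  expr <- tryCatch(str2lang(source), error = function(e) {
    stop(sprintf("cannot parse recording expression '%s': %s",
                 source, conditionMessage(e)))
  })
  syms <- all.names(expr)
  vars <- character(0)
  svars <- character(0)
  bad <- character(0)
  uses_iteration <- FALSE
  for (s in unique(syms)) {
    if (s %in% .dsl_operators) next
    if (s %in% names(.np_whitelist)) next
    if (identical(s, "n.iteration")) { uses_iteration <- TRUE; next }
    if (grepl("^n\\.[A-Za-z_][A-Za-z0-9_]*$", s)) {
      vars <- c(vars, sub("^n\\.", "", s)); next
    }
    if (grepl("^(s|synapse)\\.[A-Za-z_][A-Za-z0-9_]*$", s)) {
      svars <- c(svars, sub("^(s|synapse)\\.", "", s)); next
    }
    bad <- c(bad, s)
  }
  if (length(bad) > 0) {
    stop(sprintf(
      "recording expression '%s' uses unknown name(s): %s (allowed: n.<var>, s.<var>, np.{%s}, operators)",
      source, paste(bad, collapse = ", "),
      paste(sub("^np\\.", "", names(.np_whitelist)), collapse = ", ")))
  }
  structure(list(source = source, expr = expr, vars = unique(vars),
                 synapse_vars = unique(svars),
                 uses_iteration = uses_iteration,
                 symbols = unique(syms)),
            class = "expression_program")
}

#' Evaluate a compiled recording expression
#'
#' @param program an `expression_program` from [compile_expression()].
#' @param parent the group the expression is evaluated against.
#' @param iteration current iteration number (bound to `n.iteration`).
#' @return the expression value.
#' @export
eval_expression <- function(program, parent, iteration = NA_integer_) {
  env <- new.env(parent = emptyenv())
  for (op in .dsl_operators[.dsl_operators != "("]) {
    assign(op, get(op, envir = baseenv()), envir = env)
  }
  assign("(", get("(", envir = baseenv()), envir = env)
  for (nm in intersect(names(.np_whitelist), program$symbols)) {
    assign(nm, .np_whitelist[[nm]], envir = env)
  }
  is_synapse <- inherits(parent, "SynapseGroup")
  for (v in program$vars) {
    val <- if (is_synapse) parent$get_mat(v) else parent$get(v)
    assign(paste0("n.", v), val, envir = env)
  }
  for (v in program$synapse_vars) {
    if (!is_synapse) {
      stop(sprintf("expression '%s' uses synapse variables but its parent is not a synapse group",
                   program$source))
    }
    val <- parent$get_mat(v)
    for (alias in c("s.", "synapse.")) {
      nm <- paste0(alias, v)
      if (nm %in% program$symbols) assign(nm, val, envir = env)
    }
  }
  if (program$uses_iteration) assign("n.iteration", iteration, envir = env)
  eval(program$expr, envir = env)
}

# -- recorder ------------------------------------------------------------------

#' Recorder behaviour
#'
#' Records the values of one or more compiled expression strings every
#' `interval` iterations (at iterations where `iteration %% interval == 0`,
#' counting from 1). Stored values are snapshots: later mutation of the live
#' state never alters recorded history. Each expression string acts as a tag,
#' so `find_by_tag(net, expr)` returns the trace recorded under `expr`.
#'
#' Create with [recorder()]; give recorders keys larger than all dynamics
#' behaviours so they see the end-of-step state.
#'
#' @export
RecorderBehaviour <- R6::R6Class("RecorderBehaviour", inherit = Behaviour,
  public = list(
    #' @field expressions character vector of recorded expression sources.
    expressions = character(0),
    #' @field interval record every `interval`-th iteration.
    interval = 1L,
    #' @field traces named list: expression -> list of recorded values.
    traces = NULL,
    #' @field iteration_trace iteration numbers at record times.
    iteration_trace = integer(0),

    #' @description Create a recorder.
    #' @param expressions character vector of DSL expressions.
    #' @param interval positive integer.
    #' @param ... tags etc. passed to [Behaviour].
    initialize = function(expressions, interval = 1L, ...) {
      super$initialize(...)
      stopifnot(is.character(expressions), length(expressions) >= 1)
      interval <- as.integer(interval)
      if (interval < 1) stop("recorder interval must be a positive integer")
      self$expressions <- expressions
      self$interval <- interval
      self$traces <- stats::setNames(
        replicate(length(expressions), list(), simplify = FALSE), expressions)
      private$programs <- lapply(expressions, compile_expression)
      self$reads <- unique(unlist(lapply(private$programs, function(p) p$vars)))
    },

    #' @description Compile hook (expressions are compiled eagerly in the
    #'   constructor; nothing to do here).
    #' @param parent owning group.
    set_variables = function(parent) invisible(NULL),

    #' @description Evaluate and append all expressions if the current
    #'   iteration is a multiple of `interval`.
    #' @param parent owning group.
    new_iteration = function(parent) {
      it <- self$network$iteration
      if (it %% self$interval != 0L) return(invisible(NULL))
      for (i in seq_along(private$programs)) {
        p <- private$programs[[i]]
        val <- tryCatch(
          eval_expression(p, parent, it),
          error = function(e) {
            stop(sprintf("recorder expression '%s' failed at iteration %d: %s",
                         p$source, it, conditionMessage(e)))
          })
        tr <- self$traces[[p$source]]
        tr[[length(tr) + 1L]] <- val
        self$traces[[p$source]] <- tr
      }
      self$iteration_trace <- c(self$iteration_trace, it)
      invisible(NULL)
    },

    #' @description The trace recorded under an expression string.
    #' @param expression one of `$expressions`.
    #' @return a `recorder_trace` with fields `expression`, `values` (list)
    #'   and `iterations`.
    trace = function(expression) {
      if (!expression %in% self$expressions) {
        stop(sprintf("no trace recorded under '%s'", expression))
      }
      structure(list(expression = expression,
                     values = self$traces[[expression]],
                     iterations = self$iteration_trace,
                     recorder = self),
                class = "recorder_trace")
    },

    #' @description Adopt previously recorded history (used when merging).
    #' @param expression expression string.
    #' @param values list of recorded values.
    #' @param iterations matching iteration numbers.
    adopt_history = function(expression, values, iterations) {
      self$traces[[expression]] <- values
      if (length(iterations) > length(self$iteration_trace)) {
        self$iteration_trace <- iterations
      }
      invisible(self)
    }
  ),
  private = list(programs = NULL)
)

#' Create a recorder behaviour
#'
#' @param expressions character vector of recording expressions, e.g.
#'   `c("n.voltage", "np.mean(n.voltage)")`.
#' @param interval record every `interval`-th iteration (default 1).
#' @param tags optional extra tags.
#' @return a [RecorderBehaviour].
#' @export
recorder <- function(expressions, interval = 1L, tags = character(0)) {
  RecorderBehaviour$new(expressions = expressions, interval = interval,
                        tags = tags)
}

#' @export
print.recorder_trace <- function(x, ...) {
  cat(sprintf("<recorder_trace '%s': %d samples>\n",
              x$expression, length(x$values)))
  invisible(x)
}

#' Stack a vector-valued trace into a matrix
#'
#' @param x a `recorder_trace` whose values are equal-length vectors.
#' @param ... unused.
#' @return matrix with one row per recorded time point.
#' @export
as.matrix.recorder_trace <- function(x, ...) {
  do.call(rbind, lapply(x$values, as.numeric))
}

#' Flatten a scalar-valued trace
#'
#' @param x a `recorder_trace` whose values are scalars.
#' @param ... unused.
#' @return numeric vector.
#' @export
as.double.recorder_trace <- function(x, ...) {
  vapply(x$values, as.numeric, numeric(1))
}

#' Merge redundant recorders on one group
#'
#' Replaces several recorders attached to the same group by a single recorder
#' covering the union of their expressions, recording at the greatest common
#' divisor of their intervals. Previously recorded history is carried over
#' (for an expression recorded by several of the inputs, the first recorder's
#' history wins), so tag-based retrieval behaves exactly as before the merge.
#'
#' @param group a [NeuronGroup] or [SynapseGroup] whose recorders to merge,
#'   or a list of [RecorderBehaviour]s sharing one parent group.
#' @return the merged [RecorderBehaviour] (invisibly the group's only
#'   recorder afterwards). With fewer than two recorders this is a no-op.
#' @export
merge_recorders <- function(group) {
  if (is.list(group) && !inherits(group, "R6")) {
    recs <- group
    parents <- unique(lapply(recs, function(r) r$parent))
    if (length(parents) != 1) stop("recorders to merge must share one parent group")
    group <- parents[[1]]
  } else {
    recs <- Filter(function(b) inherits(b, "RecorderBehaviour"), group$behaviours)
  }
  if (length(recs) < 2) {
    return(invisible(if (length(recs) == 1) recs[[1]] else NULL))
  }
  exprs <- unique(unlist(lapply(recs, function(r) r$expressions)))
  ints <- vapply(recs, function(r) r$interval, integer(1))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  interval <- Reduce(gcd2, ints)
  keys <- vapply(recs, function(r) r$key, numeric(1))
  merged <- recorder(exprs, interval = interval,
                     tags = unique(unlist(lapply(recs, function(r) r$tags))))
  for (e in exprs) {
    donor <- recs[[which(vapply(recs, function(r) e %in% r$expressions,
                                logical(1)))[1]]]
    merged$adopt_history(e, donor$traces[[e]], donor$iteration_trace)
  }
  for (r in recs) group$remove_behaviour(r)
  group$add_behaviour(max(keys), merged)
  invisible(merged)
}
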