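# Differential-equation engine: a Clock tracking physical time, unit-carrying
# values, and a parser that turns strings like
#     dv/dt = -v/tau : volt
# into per-step forward-Euler updates. The grammar is one definition per
# line; "d<name>/dt = <expr> : <unit>" declares an integrated state,
# "<name> = <expr> : <unit>" a derived quantity recomputed (not integrated)
# each step. Unit tokens are second/volt/amp with power-of-ten prefixes,
# plus "1" for dimensionless. All magnitudes are stored in SI base units.

# dimension exponent vector over (second, kilogram, metre, ampere)
.dim_names <- c("s", "kg", "m", "A")
.dimensionless <- c(0, 0, 0, 0)
.base_unit_dims <- list(
  second = c(1, 0, 0, 0),
  volt   = c(-3, 1, 2, -1),
  amp    = c(0, 0, 0, 1)
)
.unit_prefixes <- c(G = 1e9, M = 1e6, k = 1e3, m = 1e-3, u = 1e-6,
                    n = 1e-9, p = 1e-12)

dim_label <- function(dim) {
  if (all(dim == 0)) return("1")
  parts <- sprintf("%s^%g", .dim_names, dim)[dim != 0]
  paste(parts, collapse = " ")
}

#' Parse a unit token
#'
#' Accepts `second`, `volt`, `amp`, their one-letter symbols `s`, `V`, `A`,
#' any of these with a power-of-ten prefix (`G M k m u n p`, e.g. `ms`,
#' `mV`, `pA`), and `1` for dimensionless.
#'
#' @param token unit string.
#' @return list with `scale` (factor to SI) and `dim` (exponent vector).
#' @export
parse_unit <- function(token) {
  token <- trimws(token)
  if (token == "1" || token == "") {
    return(list(scale = 1, dim = .dimensionless))
  }
  symbols <- c(s = "second", V = "volt", A = "amp")
  m <- regmatches(token, regexec("^([GMkmunp]?)(second|volt|amp|s|V|A)$", token))[[1]]
  if (length(m) == 0) {
    stop(sprintf("unknown unit '%s' (supported: second, volt, amp, s, V, A with prefixes G M k m u n p, or 1)",
                 token))
  }
  base <- m[3]
  if (base %in% names(symbols)) base <- symbols[[base]]
  scale <- if (nzchar(m[2])) .unit_prefixes[[m[2]]] else 1
  list(scale = scale, dim = .base_unit_dims[[base]])
}

#' A physical quantity: magnitude (in SI base units) plus dimension
#'
#' @param magnitude numeric value(s).
#' @param unit unit token (see [parse_unit()]); the magnitude is given in
#'   this unit and converted to SI.
#' @return a `unit_value`.
#' @examples
#' unit_value(10, "mV")   # 0.01 volt
#' @export
unit_value <- function(magnitude, unit = "1") {
  u <- parse_unit(unit)
  structure(list(magnitude = magnitude * u$scale, dim = u$dim),
            class = "unit_value")
}

#' Parse a quantity string like "10*mV"
#'
#' @param text `"<number>"` or `"<number>*<unit>"` (also accepts a plain
#'   number or an existing `unit_value`).
#' @return a `unit_value`.
#' @export
parse_quantity <- function(text) {
  if (inherits(text, "unit_value")) return(text)
  if (is.numeric(text)) return(unit_value(text, "1"))
  parts <- strsplit(text, "*", fixed = TRUE)[[1]]
  num <- suppressWarnings(as.numeric(trimws(parts[1])))
  if (is.na(num)) stop(sprintf("cannot parse quantity '%s'", text))
  unit <- if (length(parts) >= 2) trimws(parts[2]) else "1"
  unit_value(num, unit)
}

#' @export
print.unit_value <- function(x, ...) {
  cat(sprintf("<unit_value %s [%s]>\n",
              paste(format(x$magnitude), collapse = ", "), dim_label(x$dim)))
  invisible(x)
}

#' Simulation clock
#'
#' Tracks physical time: `t == iteration * dt`, advancing by exactly `dt`
#' per network iteration.
#'
#' @export
Clock <- R6::R6Class("Clock",
  public = list(
    #' @field dt step duration in seconds.
    dt = NULL,
    #' @field t current time in seconds.
    t = 0,
    #' @description Create a clock.
    #' @param dt positive step duration; a number (seconds), a quantity
    #'   string like `"0.1*ms"`, or a `unit_value` with time dimension.
    initialize = function(dt = 1) {
      q <- parse_quantity(dt)
      if (!all(q$dim == .dimensionless) &&
          !all(q$dim == .base_unit_dims$second)) {
        stop("clock dt must be a time")
      }
      if (q$magnitude <= 0) stop("clock dt must be positive")
      self$dt <- q$magnitude
    },
    #' @description Advance time by one step.
    advance = function() {
      self$t <- self$t + self$dt
      invisible(self)
    },
    #' @description Reset time to zero.
    reset = function() {
      self$t <- 0
      invisible(self)
    }
  )
)

# ---- equation parsing --------------------------------------------------------

.eq_functions <- c("exp", "log", "sin", "cos", "tanh", "sqrt")
.eq_operators <- c("+", "-", "*", "/", "^", "(")

#' Parse a set of model equations
#'
#' @param text equation text: one definition per line,
#'   `d<name>/dt = <expr> : <unit>` for ODEs and `<name> = <expr> : <unit>`
#'   for derived quantities. Blank lines and `#` comments are ignored.
#' @param parameters named list of parameters; each value a number, a
#'   quantity string (`"10*mV"`), or a [unit_value()].
#' @return an `equation_set` with elements `odes`, `derived`, `parameters`.
#'   Parsing performs a full dimensional check: every right-hand side must
#'   have dimension `declared_unit / time` (ODEs) or `declared_unit`
#'   (derived quantities); unresolved symbols across all equations are
#'   reported at once.
#' @examples
#' parse_equation_set("dv/dt = -v/tau : volt",
#'                    parameters = list(tau = "10*ms"))
#' @export
parse_equation_set <- function(text, parameters = list()) {
  params <- lapply(parameters, parse_quantity)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  odes <- list()
  derived <- list()
  for (ln_no in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[[ln_no]])
    line <- trimws(raw)
    if (!nzchar(line)) next
    m <- regmatches(line, regexec(
      "^(d([A-Za-z_][A-Za-z0-9_]*)/dt|([A-Za-z_][A-Za-z0-9_]*))\\s*=\\s*(.+?)\\s*:\\s*(\\S+)$",
      line))[[1]]
    if (length(m) == 0) {
      stop(sprintf("equation syntax error at line %d: '%s' (expected 'd<name>/dt = <expr> : <unit>' or '<name> = <expr> : <unit>')",
                   ln_no, line))
    }
    is_ode <- nzchar(m[3])
    name <- if (is_ode) m[3] else m[4]
    rhs_src <- m[5]
    unit <- parse_unit(m[6])
    rhs <- tryCatch(str2lang(rhs_src), error = function(e) {
      stop(sprintf("equation syntax error at line %d ('%s'): %s",
                   ln_no, rhs_src, conditionMessage(e)))
    })
    entry <- list(name = name, rhs = rhs, rhs_src = rhs_src,
                  unit_dim = unit$dim, unit_scale = unit$scale, line = ln_no)
    if (is_ode) odes[[name]] <- entry else derived[[name]] <- entry
  }
  eqs <- structure(list(odes = odes, derived = derived, parameters = params),
                   class = "equation_set")
  check_equation_dimensions(eqs)
  eqs
}

# dimension of every known symbol
equation_symbol_dims <- function(eqs) {
  dims <- list(t = .base_unit_dims$second)
  for (nm in names(eqs$parameters)) dims[[nm]] <- eqs$parameters[[nm]]$dim
  for (e in eqs$odes) dims[[e$name]] <- e$unit_dim
  for (e in eqs$derived) dims[[e$name]] <- e$unit_dim
  dims
}

check_equation_dimensions <- function(eqs) {
  dims <- equation_symbol_dims(eqs)
  # first pass: collect unresolved symbols across all equations
  unresolved <- character(0)
  for (e in c(eqs$derived, eqs$odes)) {
    for (s in all.vars(e$rhs)) {
      if (!s %in% names(dims) && s != "xi_uniform") {
        unresolved <- c(unresolved, s)
      }
    }
    for (s in setdiff(all.names(e$rhs), all.vars(e$rhs))) {
      if (!s %in% c(.eq_operators, .eq_functions, "xi_uniform")) {
        unresolved <- c(unresolved, s)
      }
    }
  }
  if (length(unresolved) > 0) {
    stop(sprintf("equation set uses unresolved symbol(s): %s",
                 paste(unique(unresolved), collapse = ", ")))
  }
  for (e in eqs$derived) {
    d <- expr_dim(e$rhs, dims, e$rhs_src)
    if (!all(d == e$unit_dim)) {
      stop(sprintf("dimension mismatch in '%s': right-hand side is [%s], declared [%s]",
                   e$rhs_src, dim_label(d), dim_label(e$unit_dim)))
    }
  }
  for (e in eqs$odes) {
    d <- expr_dim(e$rhs, dims, e$rhs_src)
    expected <- e$unit_dim - .base_unit_dims$second
    if (!all(d == expected)) {
      stop(sprintf("dimension mismatch in ODE 'd%s/dt = %s': right-hand side is [%s], expected [%s] (declared unit / time)",
                   e$name, e$rhs_src, dim_label(d), dim_label(expected)))
    }
  }
  invisible(TRUE)
}

# recursive dimensional evaluation of an expression tree
expr_dim <- function(expr, dims, src) {
  if (is.numeric(expr)) return(.dimensionless)
  if (is.name(expr)) {
    s <- as.character(expr)
    d <- dims[[s]]
    if (is.null(d)) stop(sprintf("unresolved symbol '%s' in '%s'", s, src))
    return(d)
  }
  if (is.call(expr)) {
    op <- as.character(expr[[1]])
    args <- as.list(expr)[-1]
    if (op == "(") return(expr_dim(args[[1]], dims, src))
    if (op == "xi_uniform") return(.dimensionless)
    if (op %in% c("+", "-")) {
      if (length(args) == 1) return(expr_dim(args[[1]], dims, src))
      d1 <- expr_dim(args[[1]], dims, src)
      d2 <- expr_dim(args[[2]], dims, src)
      if (!all(d1 == d2)) {
        stop(sprintf("dimension mismatch in '%s': cannot add [%s] and [%s]",
                     src, dim_label(d1), dim_label(d2)))
      }
      return(d1)
    }
    if (op == "*") {
      return(expr_dim(args[[1]], dims, src) + expr_dim(args[[2]], dims, src))
    }
    if (op == "/") {
      return(expr_dim(args[[1]], dims, src) - expr_dim(args[[2]], dims, src))
    }
    if (op == "^") {
      d1 <- expr_dim(args[[1]], dims, src)
      if (!is.numeric(args[[2]])) {
        stop(sprintf("exponent in '%s' must be a numeric literal", src))
      }
      p <- args[[2]]
      d <- d1 * p
      if (any(d != round(d))) {
        stop(sprintf("non-integer dimension exponents in '%s'", src))
      }
      return(d)
    }
    if (op %in% .eq_functions) {
      d1 <- expr_dim(args[[1]], dims, src)
      if (op == "sqrt") {
        d <- d1 / 2
        if (any(d != round(d))) {
          stop(sprintf("sqrt of odd dimension exponents in '%s'", src))
        }
        return(d)
      }
      if (!all(d1 == 0)) {
        stop(sprintf("%s() in '%s' requires a dimensionless argument, got [%s]",
                     op, src, dim_label(d1)))
      }
      return(.dimensionless)
    }
    stop(sprintf("unsupported operation '%s' in '%s'", op, src))
  }
  stop(sprintf("unsupported expression element in '%s'", src))
}

# evaluation environment for one step: states + parameter magnitudes + t +
# the reserved per-neuron noise source xi_uniform(a, b)
equation_env <- function(eqs, state, t, n) {
  env <- new.env(parent = baseenv())
  for (nm in names(eqs$parameters)) {
    assign(nm, eqs$parameters[[nm]]$magnitude, envir = env)
  }
  for (nm in names(state)) assign(nm, state[[nm]], envir = env)
  assign("t", t, envir = env)
  assign("xi_uniform", function(a, b) runif(n, a, b), envir = env)
  for (e in eqs$derived) {
    assign(e$name, eval(e$rhs, envir = env), envir = env)
  }
  env
}

#' One forward-Euler step of an equation set
#'
#' Updates every integrated state simultaneously:
#' `x <- x + dt * RHS(x, t)` with all right-hand sides evaluated on the
#' pre-step values. Derived quantities are recomputed first and visible to
#' the RHS.
#'
#' @param eqs an `equation_set` from [parse_equation_set()].
#' @param state named list of numeric vectors (SI magnitudes), one entry per
#'   ODE state.
#' @param clock a [Clock]; `clock$dt` is the step and `clock$t` the current
#'   time. The clock is *not* advanced here.
#' @param n number of elements per state vector (for `xi_uniform`); default
#'   taken from the first state.
#' @return the updated state list.
#' @export
euler_step <- function(eqs, state, clock, n = NULL) {
  if (length(eqs$odes) == 0) return(state)
  if (is.null(n)) n <- length(state[[1]])
  env <- equation_env(eqs, state, clock$t, n)
  rhs_vals <- list()
  for (e in eqs$odes) {
    val <- eval(e$rhs, envir = env)
    if (any(!is.finite(val))) {
      stop(sprintf("non-finite value integrating state '%s' at t = %g",
                   e$name, clock$t))
    }
    rhs_vals[[e$name]] <- val
  }
  for (nm in names(rhs_vals)) {
    state[[nm]] <- state[[nm]] + clock$dt * rhs_vals[[nm]]
  }
  state
}

# ---- equation-defined behaviour ---------------------------------------------

#' Turn an equation set into a behaviour module
#'
#' Wraps [euler_step()] into a [Behaviour]: each iteration integrates the
#' states (registered on the parent group, SI magnitudes), then evaluates an
#' optional boolean `threshold` expression into the group's `spike` vector
#' and applies the `reset` assignments to spiking neurons. Without a
#' threshold the behaviour is pure ODE integration and no spike vector is
#' registered.
#'
#' @param equations equation text (see [parse_equation_set()]) or an
#'   `equation_set`.
#' @param parameters named parameter list (ignored when `equations` is
#'   already parsed).
#' @param init named list of initial values per state (numbers, quantity
#'   strings, or `unit_value`s; default 0).
#' @param threshold boolean expression string over the states, e.g.
#'   `"v > 0.5"`, or `NULL`.
#' @param reset assignment statements applied where spiking, e.g.
#'   `"v = 0"`; several statements separated by `;`. Assigning to an unknown
#'   state is rejected at construction.
#' @param dt clock step (number in seconds or quantity string); defaults to
#'   the network's `dt` at initialization.
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
equation_behaviour <- function(equations, parameters = list(), init = list(),
                               threshold = NULL, reset = NULL, dt = NULL,
                               tags = character(0)) {
  eqs <- if (inherits(equations, "equation_set")) equations
         else parse_equation_set(equations, parameters)
  resets <- list()
  if (!is.null(reset)) {
    for (stmt in strsplit(reset, ";", fixed = TRUE)[[1]]) {
      stmt <- trimws(stmt)
      if (!nzchar(stmt)) next
      m <- regmatches(stmt, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", stmt))[[1]]
      if (length(m) == 0) stop(sprintf("cannot parse reset statement '%s'", stmt))
      if (!m[2] %in% names(eqs$odes)) {
        stop(sprintf("reset assigns to '%s', which is not an integrated state (states: %s)",
                     m[2], paste(names(eqs$odes), collapse = ", ")))
      }
      resets[[m[2]]] <- str2lang(m[3])
    }
  }
  thr <- if (!is.null(threshold)) str2lang(threshold) else NULL
  EquationBehaviour$new(eqs = eqs, init = init, threshold = thr,
                        resets = resets, dt = dt, tags = tags,
                        reads = names(eqs$odes),
                        writes = c(names(eqs$odes),
                                   if (!is.null(thr)) "spike"))
}

EquationBehaviour <- R6::R6Class("EquationBehaviour", inherit = Behaviour,
  public = list(
    eqs = NULL, clock = NULL, threshold = NULL, resets = NULL,
    set_variables = function(parent) {
      self$eqs <- self$init_params$eqs
      self$threshold <- self$init_params$threshold
      self$resets <- self$init_params$resets
      dt <- self$init_params$dt
      if (is.null(dt)) dt <- self$network$dt
      self$clock <- Clock$new(dt)
      init <- self$init_params$init
      for (nm in names(self$eqs$odes)) {
        v0 <- if (!is.null(init[[nm]])) parse_quantity(init[[nm]])$magnitude else 0
        parent$set(nm, rep(v0, length.out = parent$size))
      }
      if (!is.null(self$threshold)) parent$set("spike", rep(FALSE, parent$size))
      invisible(NULL)
    },
    new_iteration = function(parent) {
      state <- lapply(stats::setNames(names(self$eqs$odes), names(self$eqs$odes)),
                      function(nm) parent$get(nm))
      state <- euler_step(self$eqs, state, self$clock, n = parent$size)
      self$clock$advance()
      if (!is.null(self$threshold)) {
        env <- equation_env(self$eqs, state, self$clock$t, parent$size)
        spike <- eval(self$threshold, envir = env)
        for (nm in names(self$resets)) {
          val <- eval(self$resets[[nm]], envir = env)
          vec <- state[[nm]]
          vec[spike] <- if (length(val) > 1) val[spike] else val
          state[[nm]] <- vec
        }
        parent$set("spike", spike)
      }
      for (nm in names(state)) parent$set(nm, state[[nm]])
      invisible(NULL)
    }
  )
)
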