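# Neuron-model behaviours: leaky integrate-and-fire, recurrent synaptic
# input, refractory period, and the Izhikevich model.

# Afferent drive for one synapse group: the per-destination sum of weights of
# the currently spiking source neurons. Computed with rowSums over the
# spiking columns (ascending column order, long-double accumulation) rather
# than a BLAS matrix product: dropping all-zero columns from a left-to-right
# sum cannot change any partial sum, which makes partitioned and
# unpartitioned networks bitwise identical.
synaptic_sum <- function(W, spikes) {
  idx <- which(as.logical(spikes))
  if (length(idx) == 0) return(numeric(nrow(W)))
  rowSums(W[, idx, drop = FALSE])
}

#' Leaky integrate-and-fire behaviour
#'
#' Registers the state vectors `voltage` (init 0), `spike` (logical) and
#' `threshold` on its group. Each step performs, in order: leak, additive
#' uniform membrane noise, threshold test, reset:
#' \deqn{v \leftarrow v + ((\lambda - 1) v + \xi),\quad
#'       \xi \sim U(0, a),\quad
#'       s \leftarrow v > \theta,\quad v[s] \leftarrow 0}
#' where \eqn{\lambda} is `leak_factor` and \eqn{a} is `noise_amplitude`.
#' The update is written in explicit Euler form `v + ((leak-1)*v + noise)`
#' (algebraically `leak*v + noise`) so that an equation-engine definition of
#' the same model integrates with identical floating-point arithmetic.
#' Resting and reset voltages are zero.
#'
#' `leak_factor` and `threshold` accept diversification strings, e.g.
#' `leak_factor = "normal(0.9,0.1)"` gives every neuron its own leak.
#'
#' @param threshold spike threshold (default 0.5).
#' @param leak_factor multiplicative decay per step in (0, 1] (default 0.9);
#'   values outside (0, 1] are allowed but flagged with a warning.
#' @param noise_amplitude upper bound of the per-step uniform noise
#'   (default 0.1); 0 disables the draw entirely.
#' @param v_init initial voltage specification (default 0).
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
lif_behaviour <- function(threshold = 0.5, leak_factor = 0.9,
                          noise_amplitude = 0.1, v_init = 0,
                          tags = character(0)) {
  LIF$new(threshold = threshold, leak_factor = leak_factor,
          noise_amplitude = noise_amplitude, v_init = v_init, tags = tags,
          reads = c("voltage", "threshold"),
          writes = c("voltage", "spike"))
}

LIF <- R6::R6Class("LIF", inherit = Behaviour,
  public = list(
    leak = NULL,
    noise_amplitude = NULL,
    set_variables = function(parent) {
      parent$set("voltage", self$get_init_attr("v_init", 0))
      parent$set("spike", rep(FALSE, parent$size))
      parent$set("threshold", self$get_init_attr("threshold", 0.5))
      self$leak <- self$get_init_attr("leak_factor", 0.9)
      if (any(self$leak <= 0) || any(self$leak > 1)) {
        warning(sprintf("leak_factor outside (0, 1] on group '%s'", parent$name),
                call. = FALSE)
      }
      self$noise_amplitude <- self$get_init_attr("noise_amplitude", 0.1,
                                                 diversify = FALSE)
      invisible(NULL)
    },
    new_iteration = function(parent) {
      v <- parent$get("voltage")
      if (self$noise_amplitude > 0) {
        noise <- runif(parent$size, 0, self$noise_amplitude)
        v <- v + ((self$leak - 1) * v + noise)
      } else {
        v <- v + (self$leak - 1) * v
      }
      spike <- v > parent$get("threshold")
      v[spike] <- 0
      parent$set("voltage", v)
      parent$set("spike", spike)
      invisible(NULL)
    }
  )
)

#' Recurrent synaptic input behaviour
#'
#' Attach to a [NeuronGroup] (conventionally with a key just above the neuron
#' model's). For every afferent synapse group it adds
#' `strength * (W %*% spike_src)` to the destination voltages, where `W` is
#' the group's weight matrix and `spike_src` the source group's current spike
#' vector — i.e. spikes produced earlier in the same step if the source's
#' neuron model has a lower key. Afferent groups are processed in
#' registration order; with partitioned synapse groups this fixed order makes
#' the result bitwise reproducible.
#'
#' @param strength input scaling (default 0.1).
#' @param matrix_name name of the weight matrix (default "W").
#' @param create_matrix if not `NULL`, a `list(spec=, density=)` used to
#'   create the matrix in `set_variables()` when the synapse group does not
#'   already have one.
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
synaptic_input_behaviour <- function(strength = 0.1, matrix_name = "W",
                                     create_matrix = NULL,
                                     tags = character(0)) {
  SynapticInput$new(strength = strength, matrix_name = matrix_name,
                    create_matrix = create_matrix, tags = tags,
                    reads = c("spike"), writes = c("voltage"))
}

SynapticInput <- R6::R6Class("SynapticInput", inherit = Behaviour,
  public = list(
    strength = NULL,
    matrix_name = NULL,
    set_variables = function(parent) {
      self$strength <- self$get_init_attr("strength", 0.1, diversify = FALSE)
      self$matrix_name <- self$get_init_attr("matrix_name", "W", diversify = FALSE)
      cm <- self$get_init_attr("create_matrix", NULL, diversify = FALSE)
      for (sg in parent$afferent) {
        if (!sg$has_mat(self$matrix_name)) {
          if (is.null(cm)) {
            stop(sprintf("synapse group '%s' has no matrix '%s' for synaptic input",
                         sg$name, self$matrix_name))
          }
          sg$new_mat(self$matrix_name, spec = cm$spec,
                     density = if (is.null(cm$density)) 1 else cm$density,
                     eager = FALSE)
        }
      }
      invisible(NULL)
    },
    new_iteration = function(parent) {
      for (sg in parent$afferent) {
        W <- sg$get_mat(self$matrix_name)
        s <- sg$src$get("spike")
        contrib <- self$strength * synaptic_sum(W, s)
        idx <- sg$dst_indices()
        v <- parent$get("voltage")
        v[idx] <- v[idx] + contrib
        parent$set("voltage", v)
      }
      invisible(NULL)
    }
  )
)

#' Refractory-period behaviour
#'
#' Attach after the neuron model (higher key). Neurons whose refractory
#' counter is positive have their spike forced off and voltage reset to 0,
#' and the counter is decremented; a spike that is allowed through restarts
#' the counter at `refractory_steps`. With `refractory_steps = 0` the
#' dynamics are untouched.
#'
#' @param refractory_steps non-negative integer number of silent steps
#'   enforced after each spike.
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
refractory_behaviour <- function(refractory_steps = 2, tags = character(0)) {
  if (refractory_steps < 0) stop("refractory_steps must be >= 0")
  Refractory$new(refractory_steps = refractory_steps, tags = tags,
                 reads = c("spike"), writes = c("spike", "voltage"))
}

Refractory <- R6::R6Class("Refractory", inherit = Behaviour,
  public = list(
    steps = NULL,
    counter = NULL,
    set_variables = function(parent) {
      self$steps <- self$get_init_attr("refractory_steps", 2, diversify = FALSE)
      if (self$steps < 0) stop("refractory_steps must be >= 0")
      self$counter <- rep(0L, parent$size)
      invisible(NULL)
    },
    new_iteration = function(parent) {
      if (self$steps == 0) return(invisible(NULL))
      spike <- parent$get("spike")
      blocked <- self$counter > 0L
      if (any(blocked & spike)) {
        v <- parent$get("voltage")
        v[blocked & spike] <- 0
        parent$set("voltage", v)
      }
      spike[blocked] <- FALSE
      self$counter[blocked] <- self$counter[blocked] - 1L
      self$counter[spike] <- as.integer(self$steps)
      parent$set("spike", spike)
      invisible(NULL)
    }
  )
)

#' Izhikevich neuron behaviour
#'
#' Two-variable quadratic integrate-and-fire model, integrated with forward
#' Euler at dt = 1 ms:
#' \deqn{v \mathrel{+}= 0.04 v^2 + 5 v + 140 - u + I}
#' \deqn{u \mathrel{+}= a (b v - u)}
#' with spike when `v >= 30` mV, after which `v <- c` and `u <- u + d`.
#' The recovery update uses the freshly updated `v`; the spike test runs
#' before the reset. Defaults are the regular-spiking parameter set.
#'
#' Registers `v` (init `c`), `u` (init `b * v`), and `spike` on the group.
#'
#' @param a,b,c,d model parameters (diversifiable).
#' @param I per-step input current; a scalar, diversification string, or
#'   `function(parent, iteration)` returning a vector.
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
izhikevich_behaviour <- function(a = 0.02, b = 0.2, c = -65, d = 8, I = 0,
                                 tags = character(0)) {
  # NB: `c` is a model parameter here, shadowing base::c in this scope
  Izhikevich$new(a = a, b = b, c = c, d = d, I = I, tags = tags,
                 reads = base::c("v", "u"), writes = base::c("v", "u", "spike"))
}

Izhikevich <- R6::R6Class("Izhikevich", inherit = Behaviour,
  public = list(
    a = NULL, b = NULL, cc = NULL, d = NULL, input = NULL,
    set_variables = function(parent) {
      self$a <- self$get_init_attr("a", 0.02)
      self$b <- self$get_init_attr("b", 0.2)
      self$cc <- self$get_init_attr("c", -65)
      self$d <- self$get_init_attr("d", 8)
      self$input <- self$init_params$I
      if (is.null(self$input)) self$input <- 0
      v0 <- rep(0, parent$size) + self$cc
      parent$set("v", v0)
      parent$set("u", self$b * v0)
      parent$set("spike", rep(FALSE, parent$size))
      invisible(NULL)
    },
    new_iteration = function(parent) {
      v <- parent$get("v")
      u <- parent$get("u")
      I <- if (is.function(self$input)) {
        self$input(parent, self$network$iteration)
      } else if (is.character(self$input)) {
        with_stream(self$rng, function() sample_spec(self$input, parent$size))
      } else {
        self$input
      }
      v <- v + (0.04 * v^2 + 5 * v + 140 - u + I)
      u <- u + self$a * (self$b * v - u)
      spike <- v >= 30
      if (any(spike)) {
        v[spike] <- if (length(self$cc) > 1) self$cc[spike] else self$cc
        u[spike] <- u[spike] + (if (length(self$d) > 1) self$d[spike] else self$d)
      }
      parent$set("v", v)
      parent$set("u", u)
      parent$set("spike", spike)
      invisible(NULL)
    }
  )
)
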