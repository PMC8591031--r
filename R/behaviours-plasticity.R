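# Plasticity and homeostasis behaviours: SORN-style STDP, joint afferent
# weight normalization, intrinsic plasticity, and a diffusing-messenger
# (nitric-oxide-like) homeostasis rule.

#' Spike-timing-dependent plasticity (SORN-style)
#'
#' Attach to a [SynapseGroup] with a key above both neuron models. Uses the
#' binary-neuron STDP rule of self-organizing recurrent networks:
#' \deqn{\Delta W_{ij} = \eta \left[ s^{dst}_i(t)\, s^{src}_j(t-1)
#'        - s^{dst}_i(t-1)\, s^{src}_j(t) \right]}
#' i.e. potentiation when the presynaptic neuron fired one step before the
#' postsynaptic one, depression for the reverse order. Weights are clipped to
#' `[w_min, w_max]` and structurally absent synapses (zeros of the density
#' mask) stay zero. Previous-step spike vectors are buffered privately by
#' this behaviour; the neuron model stays ignorant of plasticity.
#'
#' @param eta_stdp learning rate (>= 0, default 0.001).
#' @param w_min,w_max clip bounds (defaults 0 and Inf).
#' @param matrix_name weight matrix to adapt (default "W").
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
stdp_behaviour <- function(eta_stdp = 0.001, w_min = 0, w_max = Inf,
                           matrix_name = "W", tags = character(0)) {
  if (eta_stdp < 0) stop("eta_stdp must be >= 0")
  if (w_min > w_max) stop("w_min must be <= w_max")
  STDP$new(eta_stdp = eta_stdp, w_min = w_min, w_max = w_max,
           matrix_name = matrix_name, tags = tags,
           reads = c("spike"), writes = character(0))
}

STDP <- R6::R6Class("STDP", inherit = Behaviour,
  public = list(
    eta = NULL, w_min = NULL, w_max = NULL, matrix_name = NULL,
    prev_src = NULL, prev_dst = NULL,
    set_variables = function(parent) {
      self$eta <- self$get_init_attr("eta_stdp", 0.001, diversify = FALSE)
      self$w_min <- self$get_init_attr("w_min", 0, diversify = FALSE)
      self$w_max <- self$get_init_attr("w_max", Inf, diversify = FALSE)
      self$matrix_name <- self$get_init_attr("matrix_name", "W", diversify = FALSE)
      self$prev_src <- rep(0, parent$src$size)
      self$prev_dst <- rep(0, parent$dst$size)
      invisible(NULL)
    },
    new_iteration = function(parent) {
      s_src <- as.numeric(parent$src$get("spike"))
      s_dst <- as.numeric(parent$dst$get("spike"))
      W <- parent$get_mat(self$matrix_name)
      dW <- self$eta * (tcrossprod(s_dst, self$prev_src) -
                        tcrossprod(self$prev_dst, s_src))
      W <- W + dW
      W[W < self$w_min] <- self$w_min
      W[W > self$w_max] <- self$w_max
      if (!is.null(parent$enabled)) W[!parent$enabled] <- 0
      parent$set_mat(self$matrix_name, W)
      self$prev_src <- s_src
      self$prev_dst <- s_dst
      invisible(NULL)
    }
  )
)

#' Joint afferent synaptic weight normalization
#'
#' Attach to a [NeuronGroup]. Rescales each neuron's incoming weights so that
#' the sum over *all* afferent synapse groups equals `norm_target`: for
#' neuron i with joint afferent sum \eqn{\Sigma_i}, every incoming weight is
#' multiplied by \eqn{norm\_target / \Sigma_i}. Neurons whose joint sum is 0
#' are left untouched. When negative weights are present the sum of values
#' (not magnitudes) is normalized and a warning is emitted.
#'
#' Operating on the neuron group rather than a single synapse group is what
#' makes the rule correct across multiple afferent inputs — and across the
#' parts of a partitioned synapse group.
#'
#' @param norm_target per-neuron target for the joint afferent sum
#'   (default 1).
#' @param matrix_name weight matrix name (default "W").
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
normalization_behaviour <- function(norm_target = 1, matrix_name = "W",
                                    tags = character(0)) {
  Normalization$new(norm_target = norm_target, matrix_name = matrix_name,
                    tags = tags, reads = character(0), writes = character(0))
}

Normalization <- R6::R6Class("Normalization", inherit = Behaviour,
  public = list(
    target = NULL, matrix_name = NULL,
    set_variables = function(parent) {
      self$target <- self$get_init_attr("norm_target", 1)
      self$matrix_name <- self$get_init_attr("matrix_name", "W", diversify = FALSE)
      invisible(NULL)
    },
    new_iteration = function(parent) {
      normalize_afferent(parent, self$target, self$matrix_name)
      invisible(NULL)
    }
  )
)

#' Normalize afferent weights once (functional form)
#'
#' @param neurons a [NeuronGroup].
#' @param norm_target per-neuron joint afferent sum target.
#' @param matrix_name weight matrix name.
#' @return invisibly, the vector of per-neuron joint sums before scaling.
#' @export
normalize_afferent <- function(neurons, norm_target = 1, matrix_name = "W") {
  sgs <- Filter(function(sg) sg$has_mat(matrix_name), neurons$afferent)
  if (length(sgs) == 0) return(invisible(numeric(0)))
  sums <- rep(0, neurons$size)
  negative <- FALSE
  for (sg in sgs) {
    W <- sg$get_mat(matrix_name)
    if (any(W < 0)) negative <- TRUE
    sums[sg$dst_indices()] <- sums[sg$dst_indices()] + rowSums(W)
  }
  if (negative) {
    warning("negative weights present; normalizing by the sum of values",
            call. = FALSE)
  }
  scale <- ifelse(sums != 0, norm_target / sums, 1)
  for (sg in sgs) {
    W <- sg$get_mat(matrix_name)
    sg$set_mat(matrix_name, W * scale[sg$dst_indices()])
  }
  invisible(sums)
}

#' Intrinsic plasticity behaviour
#'
#' Attach to a [NeuronGroup] after the neuron model. Adapts each neuron's
#' firing threshold toward a target firing rate:
#' \deqn{\theta_i \leftarrow \theta_i + \eta_{ip} (s_i - r_{target})}
#' so frequently firing neurons become less excitable and silent ones more.
#'
#' @param eta_ip adaptation rate (default 0.01).
#' @param target_rate desired per-step spike probability (default 0.05).
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
ip_behaviour <- function(eta_ip = 0.01, target_rate = 0.05,
                         tags = character(0)) {
  IP$new(eta_ip = eta_ip, target_rate = target_rate, tags = tags,
         reads = c("spike", "threshold"), writes = c("threshold"))
}

IP <- R6::R6Class("IP", inherit = Behaviour,
  public = list(
    eta = NULL, target = NULL,
    set_variables = function(parent) {
      self$eta <- self$get_init_attr("eta_ip", 0.01)
      self$target <- self$get_init_attr("target_rate", 0.05)
      invisible(NULL)
    },
    new_iteration = function(parent) {
      th <- parent$get("threshold")
      s <- as.numeric(parent$get("spike"))
      parent$set("threshold", th + self$eta * (s - self$target))
      invisible(NULL)
    }
  )
)

#' Diffusing-messenger homeostasis behaviour
#'
#' A minimal rendition of nitric-oxide-like diffusive homeostasis on the
#' group's spatial grid. Each neuron holds a messenger concentration
#' \eqn{n_i} updated as
#' \deqn{n_i \leftarrow (1-\lambda) n_i + \alpha s_i + D\, \nabla^2 n}
#' with a zero-flux (reflecting) discrete Laplacian on the layout grid, and
#' the firing threshold is modulated by the local concentration:
#' \deqn{\theta_i \leftarrow \theta_i + \eta_{nox} (n_i - n_{target}).}
#' With `decay = 0` and no spikes the total messenger mass is conserved
#' (the zero-flux Laplacian sums to zero).
#'
#' Requires a [attach_spatial_layout()] on the group. Registers the state
#' vector `nox`.
#'
#' @param production per-spike messenger production \eqn{\alpha}
#'   (default 0.1).
#' @param diffusion diffusion coefficient \eqn{D} (default 0.1; keep
#'   `D < 1/(2 * n_axes)` for stability).
#' @param decay per-step decay \eqn{\lambda} in `[0, 1]` (default 0.01).
#' @param eta_nox threshold modulation rate (default 0; purely diagnostic
#'   when 0).
#' @param nox_target concentration setpoint (default 0.1).
#' @param tags optional tags.
#' @return a [Behaviour].
#' @export
nox_behaviour <- function(production = 0.1, diffusion = 0.1, decay = 0.01,
                          eta_nox = 0, nox_target = 0.1,
                          tags = character(0)) {
  NOX$new(production = production, diffusion = diffusion, decay = decay,
          eta_nox = eta_nox, nox_target = nox_target, tags = tags,
          reads = c("spike"), writes = c("nox", "threshold"))
}

NOX <- R6::R6Class("NOX", inherit = Behaviour,
  public = list(
    alpha = NULL, D = NULL, lambda = NULL, eta = NULL, target = NULL,
    set_variables = function(parent) {
      if (is.null(parent$layout)) {
        stop(sprintf("nox_behaviour on group '%s' requires a spatial layout (attach_spatial_layout)",
                     parent$name))
      }
      self$alpha <- self$get_init_attr("production", 0.1, diversify = FALSE)
      self$D <- self$get_init_attr("diffusion", 0.1, diversify = FALSE)
      self$lambda <- self$get_init_attr("decay", 0.01, diversify = FALSE)
      self$eta <- self$get_init_attr("eta_nox", 0, diversify = FALSE)
      self$target <- self$get_init_attr("nox_target", 0.1, diversify = FALSE)
      parent$set("nox", rep(0, parent$size))
      invisible(NULL)
    },
    new_iteration = function(parent) {
      lay <- parent$layout
      n <- parent$get("nox")
      s <- as.numeric(parent$get("spike"))
      lap <- grid_laplacian(n, lay$width, lay$height, lay$depth)
      n <- (1 - self$lambda) * n + self$alpha * s + self$D * lap
      parent$set("nox", n)
      if (self$eta != 0) {
        th <- parent$get("threshold")
        parent$set("threshold", th + self$eta * (n - self$target))
      }
      invisible(NULL)
    }
  )
)

# Discrete Laplacian on the x-fastest grid with zero-flux (reflecting)
# boundaries: for each axis, sum of (neighbour - centre) over the existing
# neighbours. Missing neighbours contribute nothing, so the total over the
# grid is a sum of antisymmetric pairs and vanishes.
grid_laplacian <- function(v, width, height, depth) {
  a <- array(v, dim = c(width, height, depth))
  lap <- array(0, dim = dim(a))
  shift_diff <- function(axis) {
    d <- dim(a)[axis]
    if (d == 1) return(NULL)
    idx_lo <- lapply(dim(a), seq_len)
    idx_hi <- idx_lo
    idx_lo[[axis]] <- seq_len(d - 1)   # cells with an upper neighbour
    idx_hi[[axis]] <- seq_len(d - 1) + 1L
    lo <- do.call(`[`, c(list(a), idx_lo, list(drop = FALSE)))
    hi <- do.call(`[`, c(list(a), idx_hi, list(drop = FALSE)))
    diff <- hi - lo
    add <- array(0, dim = dim(a))
    add <- do.call(`[<-`, c(list(add), idx_lo,
                            list(value = do.call(`[`, c(list(add), idx_lo, list(drop = FALSE))) + diff)))
    add <- do.call(`[<-`, c(list(add), idx_hi,
                            list(value = do.call(`[`, c(list(add), idx_hi, list(drop = FALSE))) - diff)))
    add
  }
  for (axis in 1:3) {
    d <- shift_diff(axis)
    if (!is.null(d)) lap <- lap + d
  }
  as.numeric(lap)
}
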