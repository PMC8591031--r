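# Neuron groups, synapse groups, subgroups and spatial layouts.
#
# Groups are deliberately dumb containers: a NeuronGroup is a registry of
# per-neuron state vectors, a SynapseGroup a registry of D x S weight
# matrices (D = destination size, S = source size). All dynamics live in the
# attached behaviour modules.

.uid_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

#' Population of neurons
#'
#' A `NeuronGroup` holds `size` neurons and a registry of state vectors, each
#' of length `size`. It carries no dynamics: behaviour modules attached under
#' numeric keys define what the neurons do. Groups also track their afferent
#' (incoming) and efferent (outgoing) [SynapseGroup]s.
#'
#' @export
NeuronGroup <- R6::R6Class("NeuronGroup",
  public = list(
    #' @field size number of neurons.
    size = NULL,
    #' @field name unique name within the network.
    name = NULL,
    #' @field tags character tags for the tagging system.
    tags = character(0),
    #' @field behaviours list of attached [Behaviour] modules (keys set).
    behaviours = list(),
    #' @field state environment mapping variable name -> vector of length size.
    state = NULL,
    #' @field afferent list of synapse groups terminating on this group.
    afferent = list(),
    #' @field efferent list of synapse groups originating here.
    efferent = list(),
    #' @field network owning [Network].
    network = NULL,
    #' @field rng private RNG stream.
    rng = NULL,
    #' @field layout [SpatialLayout] or NULL.
    layout = NULL,
    #' @field uid internal unique id.
    uid = NULL,

    #' @description Create a neuron group (normally via
    #'   `Network$add_neuron_group()`).
    #' @param size positive integer neuron count.
    #' @param name group name.
    #' @param tags character tags.
    initialize = function(size, name = "neurons", tags = character(0)) {
      stopifnot(length(size) == 1, size >= 1, size == as.integer(size))
      self$size <- as.integer(size)
      self$name <- name
      self$tags <- unique(c(as.character(tags), name))
      self$state <- new.env(parent = emptyenv())
      self$uid <- .uid_counter()
      private$eager <- list()
    },

    #' @description Attach a behaviour under a numeric key.
    #' @param key positive number giving the global execution order.
    #' @param beh a [Behaviour].
    add_behaviour = function(key, beh) {
      stopifnot(inherits(beh, "Behaviour"))
      key <- as.numeric(key)
      if (!is.finite(key) || key <= 0) {
        stop(sprintf("behaviour '%s' on group '%s' has non-positive key %s; keys must be > 0",
                     class(beh)[1], self$name, format(key)))
      }
      beh$key <- key
      self$behaviours[[length(self$behaviours) + 1L]] <- beh
      if (!is.null(self$network)) self$network$register_late_behaviour(beh, self)
      invisible(beh)
    },

    #' @description Remove a behaviour object from this group.
    #' @param beh the behaviour instance to remove.
    remove_behaviour = function(beh) {
      keep <- !vapply(self$behaviours, identical, logical(1), beh)
      self$behaviours <- self$behaviours[keep]
      if (!is.null(self$network)) self$network$touch_structure()
      invisible(self)
    },

    #' @description Draw an unregistered vector of length `size` from this
    #'   group's stream (the `get_neuron_vec` idiom).
    #' @param spec scalar, diversification string, or sampler function;
    #'   default 0 gives an all-zero vector.
    vec = function(spec = 0) {
      sp <- parse_div_spec(spec)
      if (identical(sp$kind, "constant")) return(rep(sp$value, self$size))
      with_stream(self$rng, function() sample_spec(sp, self$size))
    },

    #' @description Create *and register* a state vector under `name`.
    #'   Vectors registered before network initialization are snapshotted and
    #'   restored on re-initialization.
    #' @param name variable name.
    #' @param spec initial value specification (see [parse_div_spec()]).
    #' @param eager snapshot for re-initialization (default TRUE when called
    #'   outside behaviours, i.e. before the network is initialized).
    new_vec = function(name, spec = 0, eager = !isTRUE(self$network$initialized)) {
      v <- self$vec(spec)
      self$set(name, v)
      if (isTRUE(eager)) private$eager[[name]] <- v
      invisible(v)
    },

    #' @description Read a registered state vector.
    #' @param name variable name.
    get = function(name) {
      if (!exists(name, envir = self$state, inherits = FALSE)) {
        stop(sprintf("group '%s' has no state variable '%s' (available: %s)",
                     self$name, name,
                     paste(ls(self$state), collapse = ", ")))
      }
      get(name, envir = self$state, inherits = FALSE)
    },

    #' @description TRUE if the named state vector exists.
    #' @param name variable name.
    has = function(name) exists(name, envir = self$state, inherits = FALSE),

    #' @description Register / overwrite a state vector. Scalars are
    #'   broadcast; anything else must have length `size`.
    #' @param name variable name.
    #' @param value numeric or logical vector.
    set = function(name, value) {
      if (length(value) == 1) value <- rep(value, self$size)
      if (length(value) != self$size) {
        stop(sprintf("state vector '%s' has length %d, expected group size %d",
                     name, length(value), self$size))
      }
      assign(name, value, envir = self$state)
      invisible(value)
    },

    #' @description Names of all registered state vectors.
    state_names = function() ls(self$state),

    #' @description Restore eager vectors and drop everything else (used by
    #'   network re-initialization).
    reset_state = function() {
      rm(list = ls(self$state), envir = self$state)
      for (nm in names(private$eager)) assign(nm, private$eager[[nm]], envir = self$state)
      invisible(self)
    },

    #' @description Indices (1-based) of this group within itself; subgroup
    #'   counterpart returns masked indices.
    indices = function() seq_len(self$size),

    #' @description The underlying full group (identity here; parent for
    #'   subgroups).
    base_group = function() self,

    #' @description Create a [SubNeuronGroup] view.
    #' @param mask logical vector of length `size`.
    subgroup = function(mask) SubNeuronGroup$new(self, mask)
  ),
  private = list(eager = NULL)
)

#' Masked view onto a NeuronGroup
#'
#' A `SubNeuronGroup` gives partial access to the state of its parent group:
#' reads return the masked entries, writes are visible in the parent
#' (shared-view contract). Used heavily by [partition_synapse_group()].
#'
#' @export
SubNeuronGroup <- R6::R6Class("SubNeuronGroup",
  public = list(
    #' @field parent the full [NeuronGroup].
    parent = NULL,
    #' @field mask logical vector over the parent.
    mask = NULL,
    #' @field size number of TRUE mask entries.
    size = NULL,
    #' @field name derived name.
    name = NULL,
    #' @field tags tags of the view.
    tags = character(0),

    #' @description Create a masked view.
    #' @param parent a [NeuronGroup].
    #' @param mask logical vector of length `parent$size`.
    initialize = function(parent, mask) {
      if (length(mask) != parent$size) {
        stop(sprintf("mask length %d does not match group size %d",
                     length(mask), parent$size))
      }
      self$parent <- parent
      self$mask <- as.logical(mask)
      self$size <- sum(self$mask)
      self$name <- sprintf("%s[sub:%d]", parent$name, self$size)
    },

    #' @description Read the masked entries of a parent state vector.
    #' @param name variable name.
    get = function(name) self$parent$get(name)[self$mask],

    #' @description TRUE if the parent has the variable.
    #' @param name variable name.
    has = function(name) self$parent$has(name),

    #' @description Write through the view into the parent vector.
    #' @param name variable name.
    #' @param value scalar or vector of length `size`.
    set = function(name, value) {
      full <- self$parent$get(name)
      full[self$mask] <- value
      self$parent$set(name, full)
      invisible(value)
    },

    #' @description 1-based parent indices selected by the mask.
    indices = function() which(self$mask),

    #' @description The underlying full group.
    base_group = function() self$parent
  )
)

#' Bundle of synapses between two neuron groups
#'
#' Connects a source group to a destination group and holds a registry of
#' weight matrices with `dst$size` rows and `src$size` columns (the D x S
#' convention: row i collects neuron i's afferent weights). Either side may
#' be a [SubNeuronGroup], which is how partitioned synapse groups address
#' blocks of a larger population.
#'
#' @export
SynapseGroup <- R6::R6Class("SynapseGroup",
  public = list(
    #' @field src source group (spikes come from here).
    src = NULL,
    #' @field dst destination group (input arrives here).
    dst = NULL,
    #' @field name unique name within the network.
    name = NULL,
    #' @field tags character tags.
    tags = character(0),
    #' @field behaviours attached [Behaviour] modules.
    behaviours = list(),
    #' @field mats environment mapping matrix name -> D x S matrix.
    mats = NULL,
    #' @field enabled logical D x S structural mask (which synapses exist);
    #'   NULL means all.
    enabled = NULL,
    #' @field network owning [Network].
    network = NULL,
    #' @field rng private RNG stream.
    rng = NULL,
    #' @field uid internal unique id.
    uid = NULL,

    #' @description Create a synapse group (normally via
    #'   `Network$add_synapse_group()`).
    #' @param src source [NeuronGroup] or [SubNeuronGroup].
    #' @param dst destination [NeuronGroup] or [SubNeuronGroup].
    #' @param name group name.
    #' @param tags character tags.
    initialize = function(src, dst, name = "synapses", tags = character(0)) {
      self$src <- src
      self$dst <- dst
      self$name <- name
      self$tags <- unique(c(as.character(tags), name))
      self$mats <- new.env(parent = emptyenv())
      self$uid <- .uid_counter()
      private$eager <- list()
    },

    #' @description Attach a behaviour under a numeric key.
    #' @param key positive number.
    #' @param beh a [Behaviour].
    add_behaviour = function(key, beh) {
      stopifnot(inherits(beh, "Behaviour"))
      key <- as.numeric(key)
      if (!is.finite(key) || key <= 0) {
        stop(sprintf("behaviour '%s' on synapse group '%s' has non-positive key %s; keys must be > 0",
                     class(beh)[1], self$name, format(key)))
      }
      beh$key <- key
      self$behaviours[[length(self$behaviours) + 1L]] <- beh
      if (!is.null(self$network)) self$network$register_late_behaviour(beh, self)
      invisible(beh)
    },

    #' @description Number of destination rows / source columns.
    dims = function() c(self$dst$size, self$src$size),

    #' @description Draw an unregistered D x S matrix (the `get_synapse_mat`
    #'   idiom). With `density < 1`, exactly `round(density * D * S)` entries
    #'   (chosen without replacement from this group's stream) are nonzero.
    #' @param spec value specification for the (nonzero) entries.
    #' @param density fraction of structurally present synapses in (0, 1].
    mat = function(spec = 1, density = 1) {
      d <- self$dims()
      if (!is.numeric(density) || length(density) != 1 ||
          density <= 0 || density > 1) {
        stop(sprintf("density must be in (0, 1], got %s", format(density)))
      }
      n <- d[1] * d[2]
      k <- round(density * n)
      with_stream(self$rng, function() {
        vals <- sample_spec(parse_div_spec(spec), k)
        if (k == n) {
          m <- matrix(vals, nrow = d[1], ncol = d[2])
          mask <- matrix(TRUE, d[1], d[2])
        } else {
          pos <- sample.int(n, k)
          m <- matrix(0, nrow = d[1], ncol = d[2])
          m[pos] <- vals
          mask <- matrix(FALSE, d[1], d[2])
          mask[pos] <- TRUE
        }
        attr(m, "structure_mask") <- mask
        m
      })
    },

    #' @description Create *and register* a weight matrix under `name`; also
    #'   records the structural mask in `$enabled`.
    #' @param name matrix name (conventionally "W").
    #' @param spec value specification.
    #' @param density fraction in (0, 1].
    #' @param eager snapshot for re-initialization (default TRUE before the
    #'   network is initialized).
    new_mat = function(name, spec = 1, density = 1,
                       eager = !isTRUE(self$network$initialized)) {
      m <- self$mat(spec, density)
      self$enabled <- attr(m, "structure_mask")
      attr(m, "structure_mask") <- NULL
      self$set_mat(name, m)
      if (isTRUE(eager)) {
        private$eager[[name]] <- m
        private$eager_enabled <- self$enabled
      }
      invisible(m)
    },

    #' @description Read a registered matrix.
    #' @param name matrix name.
    get_mat = function(name) {
      if (!exists(name, envir = self$mats, inherits = FALSE)) {
        stop(sprintf("synapse group '%s' has no matrix '%s' (available: %s)",
                     self$name, name, paste(ls(self$mats), collapse = ", ")))
      }
      get(name, envir = self$mats, inherits = FALSE)
    },

    #' @description TRUE if the named matrix exists.
    #' @param name matrix name.
    has_mat = function(name) exists(name, envir = self$mats, inherits = FALSE),

    #' @description Register / overwrite a matrix (must be D x S).
    #' @param name matrix name.
    #' @param m numeric matrix.
    set_mat = function(name, m) {
      d <- self$dims()
      if (!is.matrix(m) || nrow(m) != d[1] || ncol(m) != d[2]) {
        stop(sprintf("matrix '%s' must be %d x %d (dst x src), got %s",
                     name, d[1], d[2],
                     paste(dim(m), collapse = " x ")))
      }
      assign(name, m, envir = self$mats)
      invisible(m)
    },

    #' @description Names of registered matrices.
    mat_names = function() ls(self$mats),

    #' @description Register a matrix *and* snapshot it for
    #'   re-initialization (used when slicing partitioned weights).
    #' @param name matrix name.
    #' @param m numeric matrix.
    #' @param enabled optional structural mask to adopt alongside.
    adopt_mat = function(name, m, enabled = NULL) {
      self$set_mat(name, m)
      private$eager[[name]] <- m
      if (!is.null(enabled)) {
        self$enabled <- enabled
        private$eager_enabled <- enabled
      }
      invisible(m)
    },

    #' @description Restore eager matrices, drop the rest (re-initialization).
    reset_state = function() {
      rm(list = ls(self$mats), envir = self$mats)
      for (nm in names(private$eager)) assign(nm, private$eager[[nm]], envir = self$mats)
      if (!is.null(private$eager_enabled)) self$enabled <- private$eager_enabled
      invisible(self)
    },

    #' @description 1-based indices of the destination neurons within the
    #'   destination *base* group.
    dst_indices = function() {
      if (inherits(self$dst, "SubNeuronGroup")) self$dst$indices() else seq_len(self$dst$size)
    },

    #' @description 1-based indices of the source neurons within the source
    #'   base group.
    src_indices = function() {
      if (inherits(self$src, "SubNeuronGroup")) self$src$indices() else seq_len(self$src$size)
    }
  ),
  private = list(eager = NULL, eager_enabled = NULL)
)

# Spatial layout ---------------------------------------------------------------

#' Attach a 3D grid layout to a neuron group
#'
#' Assigns integer grid coordinates to every neuron and registers them as the
#' state vectors `x`, `y`, `z`. The linearization is x-fastest row-major:
#' neuron `i` (0-based) sits at `x = i %% width`,
#' `y = (i %/% width) %% height`, `z = i %/% (width * height)`.
#'
#' @param group a [NeuronGroup].
#' @param width,height,depth positive integers with
#'   `width * height * depth == group$size`.
#' @return a `SpatialLayout` object (also stored on `group$layout`).
#' @export
attach_spatial_layout <- function(group, width, height, depth = 1) {
  width <- as.integer(width); height <- as.integer(height); depth <- as.integer(depth)
  stopifnot(width >= 1, height >= 1, depth >= 1)
  if (width * height * depth != group$size) {
    stop(sprintf("grid %d x %d x %d has %d cells but the group has %d neurons",
                 width, height, depth, width * height * depth, group$size))
  }
  i <- seq_len(group$size) - 1L
  x <- i %% width
  y <- (i %/% width) %% height
  z <- i %/% (width * height)
  group$new_vec("x", x, eager = TRUE)
  group$new_vec("y", y, eager = TRUE)
  group$new_vec("z", z, eager = TRUE)
  layout <- structure(
    list(width = width, height = height, depth = depth, x = x, y = y, z = z),
    class = "SpatialLayout")
  group$layout <- layout
  invisible(layout)
}

#' @export
print.SpatialLayout <- function(x, ...) {
  cat(sprintf("<SpatialLayout %d x %d x %d>\n", x$width, x$height, x$depth))
  invisible(x)
}
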