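# The Network: container of all groups plus the global, key-sorted execution
# pipeline. Initialization sorts every behaviour attached anywhere in the
# network by its numeric key and calls set_variables() once per module; each
# simulated step then runs every module's new_iteration() once, in order.

#' Neural network container
#'
#' Holds the [NeuronGroup]s and [SynapseGroup]s of a simulation together with
#' optional network-level behaviours, owns the iteration counter and the root
#' random seed, and manages the global execution pipeline.
#'
#' Typical use:
#' ```r
#' net <- Network$new(seed = 42)
#' ng  <- net$add_neuron_group(size = 100, name = "exc",
#'                             behaviours = list(`1` = lif_behaviour(),
#'                                               `9` = recorder("n.voltage")))
#' sg  <- net$add_synapse_group(ng, ng, name = "rec", tags = "GLU")
#' net$initialize_network()
#' net$simulate_iterations(1000)
#' ```
#'
#' @export
Network <- R6::R6Class("Network",
  public = list(
    #' @field neuron_groups ordered list of [NeuronGroup].
    neuron_groups = list(),
    #' @field synapse_groups ordered list of [SynapseGroup].
    synapse_groups = list(),
    #' @field behaviours network-level [Behaviour] modules.
    behaviours = list(),
    #' @field iteration current iteration (0 before any step).
    iteration = 0L,
    #' @field pipeline list of list(key, behaviour, parent), sorted by key.
    pipeline = list(),
    #' @field seed root random seed; all object streams derive from it.
    seed = NULL,
    #' @field dt clock step in seconds (used by the equation engine).
    dt = 1,
    #' @field initialized TRUE after `initialize_network()`.
    initialized = FALSE,
    #' @field shuffle_ties if TRUE, equal-key behaviours are shuffled with a
    #'   seed-derived stream instead of keeping registration order.
    shuffle_ties = FALSE,
    #' @field structure_version bumped on every structural change
    #'   (tag-cache invalidation).
    structure_version = 0L,
    #' @field uid internal unique id.
    uid = NULL,
    #' @field tags character tags.
    tags = character(0),
    #' @field tag_cache environment for cached tag queries.
    tag_cache = NULL,

    #' @description Create a network.
    #' @param seed integer root seed (default 42).
    #' @param dt clock step in seconds (default 1).
    #' @param shuffle_ties shuffle equal-key behaviours using the network
    #'   seed instead of deterministic registration order.
    #' @param tags character tags.
    initialize = function(seed = 42L, dt = 1, shuffle_ties = FALSE,
                          tags = character(0)) {
      self$seed <- as.integer(seed)
      self$dt <- dt
      self$shuffle_ties <- isTRUE(shuffle_ties)
      self$tags <- unique(c(as.character(tags), "network"))
      self$uid <- .uid_counter()
      self$tag_cache <- new.env(parent = emptyenv())
      private$reg_counter <- 0L
    },

    #' @description Create and register a neuron group.
    #' @param size neuron count.
    #' @param name unique group name.
    #' @param tags character tags.
    #' @param behaviours named list; names are numeric keys, e.g.
    #'   `list(`1` = lif_behaviour(), `9` = recorder("n.voltage"))`.
    #' @return the new [NeuronGroup].
    add_neuron_group = function(size, name = NULL, tags = character(0),
                                behaviours = list()) {
      if (is.null(name)) name <- sprintf("neurons_%d", length(self$neuron_groups) + 1L)
      ng <- NeuronGroup$new(size, name = name, tags = tags)
      ng$network <- self
      ng$rng <- new_rng_stream(derive_seed(self$seed, paste0("ng/", name)))
      self$neuron_groups[[length(self$neuron_groups) + 1L]] <- ng
      private$attach_behaviour_list(ng, behaviours)
      self$touch_structure()
      ng
    },

    #' @description Create and register a synapse group. Either endpoint may
    #'   be a [SubNeuronGroup]; afferent/efferent bookkeeping is kept on the
    #'   underlying base groups.
    #' @param src source group.
    #' @param dst destination group.
    #' @param name unique group name.
    #' @param tags character tags.
    #' @param behaviours named list keyed like `add_neuron_group`'s.
    #' @return the new [SynapseGroup].
    add_synapse_group = function(src, dst, name = NULL, tags = character(0),
                                 behaviours = list()) {
      if (is.null(name)) name <- sprintf("synapses_%d", length(self$synapse_groups) + 1L)
      sg <- SynapseGroup$new(src, dst, name = name, tags = tags)
      sg$network <- self
      sg$rng <- new_rng_stream(derive_seed(self$seed, paste0("sg/", name)))
      self$synapse_groups[[length(self$synapse_groups) + 1L]] <- sg
      dst_base <- dst$base_group(); src_base <- src$base_group()
      dst_base$afferent[[length(dst_base$afferent) + 1L]] <- sg
      src_base$efferent[[length(src_base$efferent) + 1L]] <- sg
      private$attach_behaviour_list(sg, behaviours)
      self$touch_structure()
      sg
    },

    #' @description Attach a network-level behaviour.
    #' @param key positive numeric key.
    #' @param beh a [Behaviour].
    add_behaviour = function(key, beh) {
      stopifnot(inherits(beh, "Behaviour"))
      key <- as.numeric(key)
      if (!is.finite(key) || key <= 0) {
        stop(sprintf("network-level behaviour '%s' has non-positive key %s; keys must be > 0",
                     class(beh)[1], format(key)))
      }
      beh$key <- key
      self$behaviours[[length(self$behaviours) + 1L]] <- beh
      self$register_late_behaviour(beh, self)
      invisible(beh)
    },

    #' @description Remove a network-level behaviour instance.
    #' @param beh the behaviour to remove.
    remove_behaviour = function(beh) {
      keep <- !vapply(self$behaviours, identical, logical(1), beh)
      self$behaviours <- self$behaviours[keep]
      self$touch_structure()
      invisible(self)
    },

    #' @description Mark the structure changed (invalidates tag caches and,
    #'   if initialized, re-sorts the pipeline on next use).
    touch_structure = function() {
      self$structure_version <- self$structure_version + 1L
      if (self$initialized) private$pipeline_stale <- TRUE
      invisible(self)
    },

    #' @description Used internally when a behaviour is attached after the
    #'   network was initialized: binds parent and stream, runs its
    #'   `set_variables()` immediately, and re-sorts the pipeline without
    #'   touching any state.
    #' @param beh the behaviour.
    #' @param parent its owner.
    register_late_behaviour = function(beh, parent) {
      self$touch_structure()
      if (self$initialized) {
        private$bind_behaviour(beh, parent)
        with_stream(beh$rng, function() beh$set_variables(parent))
      }
      invisible(self)
    },

    #' @description Build (or rebuild) the global execution pipeline and call
    #'   every behaviour's `set_variables()` in pipeline order.
    #'   Re-initialization resets the iteration counter, every RNG stream and
    #'   all registered state, so a re-initialized network replays exactly.
    initialize_network = function() {
      private$check_groups()
      self$iteration <- 0L
      # reset streams and state
      for (ng in self$neuron_groups) {
        ng$rng <- new_rng_stream(derive_seed(self$seed, paste0("ng/", ng$name)))
        ng$reset_state()
      }
      for (sg in self$synapse_groups) {
        sg$rng <- new_rng_stream(derive_seed(self$seed, paste0("sg/", sg$name)))
        sg$reset_state()
      }
      entries <- private$collect_entries()
      for (e in entries) private$bind_behaviour(e$behaviour, e$parent)
      self$pipeline <- private$sort_entries(entries)
      private$pipeline_stale <- FALSE
      self$initialized <- TRUE
      self$touch_structure()
      private$pipeline_stale <- FALSE
      for (e in self$pipeline) {
        b <- e$behaviour
        with_stream(b$rng, function() b$set_variables(e$parent))
      }
      invisible(self)
    },

    #' @description Run `n` simulation steps. Each step increments the
    #'   iteration counter, then executes every pipeline entry once in key
    #'   order.
    #' @param n non-negative integer number of steps.
    simulate_iterations = function(n) {
      if (!self$initialized) {
        stop("network must be initialized with initialize_network() before simulating")
      }
      n <- as.integer(n)
      stopifnot(n >= 0)
      if (n == 0) return(invisible(self))
      for (step in seq_len(n)) {
        if (private$pipeline_stale) private$resort_pipeline()
        self$iteration <- self$iteration + 1L
        for (e in self$pipeline) {
          b <- e$behaviour
          with_stream(b$rng, function() b$new_iteration(e$parent))
        }
      }
      invisible(self)
    },

    #' @description All behaviours in current pipeline order (initializes
    #'   lazily sorted view for inspection/module graph).
    pipeline_entries = function() {
      if (private$pipeline_stale) private$resort_pipeline()
      self$pipeline
    },

    #' @description Replace a synapse group in the registry by a list of
    #'   parts (used by [partition_synapse_group()]); afferent/efferent lists
    #'   of the base groups are rewritten accordingly.
    #' @param sg the synapse group to remove.
    #' @param parts list of replacement [SynapseGroup]s (already registered).
    replace_synapse_group = function(sg, parts) {
      drop1 <- function(lst) lst[!vapply(lst, identical, logical(1), sg)]
      self$synapse_groups <- drop1(self$synapse_groups)
      sgd <- sg$dst$base_group(); sgs <- sg$src$base_group()
      sgd$afferent <- drop1(sgd$afferent)
      sgs$efferent <- drop1(sgs$efferent)
      self$touch_structure()
      invisible(self)
    }
  ),
  private = list(
    reg_counter = 0L,
    pipeline_stale = FALSE,

    attach_behaviour_list = function(obj, behaviours) {
      if (length(behaviours) == 0) return(invisible(NULL))
      keys <- names(behaviours)
      if (is.null(keys) || any(!nzchar(keys))) {
        stop("behaviours must be a named list; names are the numeric execution keys")
      }
      for (i in seq_along(behaviours)) {
        k <- suppressWarnings(as.numeric(keys[[i]]))
        if (is.na(k)) stop(sprintf("behaviour key '%s' is not numeric", keys[[i]]))
        obj$add_behaviour(k, behaviours[[i]])
      }
      invisible(NULL)
    },

    check_groups = function() {
      nms <- vapply(self$neuron_groups, function(g) g$name, character(1))
      if (anyDuplicated(nms)) stop("neuron group names must be unique")
      for (sg in self$synapse_groups) {
        for (side in list(sg$src$base_group(), sg$dst$base_group())) {
          ok <- any(vapply(self$neuron_groups, identical, logical(1), side))
          if (!ok) {
            stop(sprintf("synapse group '%s' references neuron group '%s' which is not registered in this network",
                         sg$name, side$name))
          }
        }
      }
      invisible(NULL)
    },

    bind_behaviour = function(beh, parent) {
      beh$parent <- parent
      beh$network <- self
      if (is.na(beh$reg_index)) {
        private$reg_counter <- private$reg_counter + 1L
        beh$reg_index <- private$reg_counter
      }
      pname <- if (inherits(parent, "Network")) "net" else parent$name
      beh$rng <- new_rng_stream(
        derive_seed(self$seed, sprintf("beh/%s/%s", pname, format(beh$key))))
      invisible(NULL)
    },

    collect_entries = function() {
      entries <- list()
      idx <- 0L
      add <- function(beh, parent) {
        idx <<- idx + 1L
        entries[[idx]] <<- list(key = beh$key, behaviour = beh, parent = parent)
      }
      for (ng in self$neuron_groups) for (b in ng$behaviours) add(b, ng)
      for (sg in self$synapse_groups) for (b in sg$behaviours) add(b, sg)
      for (b in self$behaviours) add(b, self)
      for (e in entries) {
        if (!is.finite(e$key) || e$key <= 0) {
          stop(sprintf("behaviour '%s' has non-positive key %s",
                       class(e$behaviour)[1], format(e$key)))
        }
      }
      entries
    },

    sort_entries = function(entries) {
      if (length(entries) == 0) return(list())
      keys <- vapply(entries, function(e) e$key, numeric(1))
      if (anyDuplicated(keys)) {
        dup <- unique(keys[duplicated(keys)])
        if (self$shuffle_ties) {
          shuffle_stream <- new_rng_stream(derive_seed(self$seed, "tie-shuffle"))
          ord <- order(keys)  # stable
          for (k in dup) {
            pos <- which(keys[ord] == k)
            perm <- with_stream(shuffle_stream, function() sample(length(pos)))
            ord[pos] <- ord[pos][perm]
          }
          return(entries[ord])
        }
        warning(sprintf(
          "behaviours share execution key(s) %s; running them in registration order (set shuffle_ties = TRUE on the Network for seeded shuffling)",
          paste(format(dup), collapse = ", ")), call. = FALSE)
      }
      entries[order(keys)]  # stable sort: registration order within ties
    },

    resort_pipeline = function() {
      entries <- private$collect_entries()
      for (e in entries) {
        if (is.null(e$behaviour$rng)) private$bind_behaviour(e$behaviour, e$parent)
      }
      self$pipeline <- private$sort_entries(entries)
      private$pipeline_stale <- FALSE
      invisible(NULL)
    }
  )
)

#' Initialize a network (functional form)
#'
#' Equivalent to `network$initialize_network()`; sorts all behaviour keys
#' across the whole network into the global execution pipeline and calls each
#' module's `set_variables()` once, in order.
#'
#' @param network a [Network].
#' @return the network, invisibly.
#' @export
initialize_network <- function(network) network$initialize_network()

#' Run simulation steps (functional form)
#'
#' @param network an initialized [Network].
#' @param n number of steps (non-negative).
#' @return the network, invisibly.
#' @export
simulate_iterations <- function(network, n) network$simulate_iterations(n)
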