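# Tag-based object retrieval. Every network object (network, groups,
# behaviours, recorder traces) carries a set of string tags; find_by_tag()
# walks the tree depth-first in registration/key order and returns all
# matches. Results are cached per (root, tag) and invalidated whenever the
# network structure changes. A recorder's expression strings double as tags
# of the traces recorded under them.

#' Find all objects carrying a tag
#'
#' Searches `root` and its descendants (groups, behaviours, recorder traces)
#' depth-first in registration order and returns every object tagged with
#' `tag`. The search result is cached on the network and reused until the
#' structure changes (groups/behaviours added or removed). For a recorder,
#' each recorded expression string acts as a tag of that expression's trace,
#' so `find_by_tag(net, "np.mean(n.voltage)")` returns the recorded mean
#' trace(s).
#'
#' An unknown tag returns an empty list rather than an error.
#'
#' The idiomatic shorthand `net["my_tag"]` / `group["my_tag"]` is also
#' provided.
#'
#' @param root a [Network], [NeuronGroup], [SynapseGroup] or [Behaviour].
#' @param tag a single string.
#' @return list of matching objects (possibly empty), in depth-first
#'   pre-order.
#' @export
find_by_tag <- function(root, tag) {
  stopifnot(is.character(tag), length(tag) == 1)
  net <- tag_network_of(root)
  if (is.null(net)) return(tag_search(root, tag))
  key <- sprintf("%d\r%s", tag_uid(root), tag)
  hit <- get0(key, envir = net$tag_cache, inherits = FALSE)
  if (!is.null(hit) && hit$version == net$structure_version) {
    return(hit$result)
  }
  res <- tag_search(root, tag)
  assign(key, list(version = net$structure_version, result = res),
         envir = net$tag_cache)
  res
}

tag_uid <- function(obj) {
  if (!is.null(obj$uid)) obj$uid else 0L
}

tag_network_of <- function(obj) {
  if (inherits(obj, "Network")) return(obj)
  if (inherits(obj, c("NeuronGroup", "SynapseGroup"))) return(obj$network)
  if (inherits(obj, "SubNeuronGroup")) return(obj$parent$network)
  if (inherits(obj, "Behaviour")) return(obj$network)
  NULL
}

# uncached recursive search, depth-first pre-order
tag_search <- function(obj, tag) {
  out <- list()
  push <- function(x) out[[length(out) + 1L]] <<- x
  visit_behaviour <- function(b) {
    if (tag %in% b$tags) push(b)
    if (inherits(b, "RecorderBehaviour")) {
      if (tag %in% b$expressions) push(b$trace(tag))
    }
  }
  visit_group <- function(g) {
    if (tag %in% g$tags) push(g)
    behs <- g$behaviours
    if (length(behs) > 1) {
      keys <- vapply(behs, function(b) b$key, numeric(1))
      behs <- behs[order(keys)]
    }
    for (b in behs) visit_behaviour(b)
  }
  if (inherits(obj, "Network")) {
    if (tag %in% obj$tags) push(obj)
    for (g in obj$neuron_groups) visit_group(g)
    for (g in obj$synapse_groups) visit_group(g)
    for (b in obj$behaviours) visit_behaviour(b)
  } else if (inherits(obj, c("NeuronGroup", "SynapseGroup"))) {
    visit_group(obj)
  } else if (inherits(obj, "Behaviour")) {
    visit_behaviour(obj)
  } else {
    stop("find_by_tag: unsupported root object")
  }
  out
}

#' @export
`[.Network` <- function(x, tag) find_by_tag(x, tag)

#' @export
`[.NeuronGroup` <- function(x, tag) find_by_tag(x, tag)

#' @export
`[.SynapseGroup` <- function(x, tag) find_by_tag(x, tag)

#' @export
`[.Behaviour` <- function(x, tag) find_by_tag(x, tag)
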