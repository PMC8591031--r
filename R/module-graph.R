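# Module graph export: a flow chart of the behaviour pipeline in DOT format.
# Nodes are behaviours in execution order; a directed edge A -> B (labelled
# with the variable) is drawn when A declares a write to a state variable
# that B declares it reads. Behaviours that declare nothing get a node
# without edges — no edges is better than wrong edges.

#' Export the behaviour pipeline as a DOT flow chart
#'
#' @param obj an initialized [Network] (full pipeline) or a single
#'   [NeuronGroup]/[SynapseGroup] (its own behaviours, in key order).
#' @param file output path for the DOT text; `NULL` returns the DOT string.
#' @return the DOT source, invisibly when written to a file.
#' @export
export_module_graph <- function(obj, file = NULL) {
  if (inherits(obj, "Network")) {
    if (!obj$initialized) {
      stop("export_module_graph: initialize the network first")
    }
    entries <- obj$pipeline_entries()
  } else {
    behs <- obj$behaviours
    keys <- vapply(behs, function(b) b$key, numeric(1))
    behs <- behs[order(keys)]
    entries <- lapply(behs, function(b) list(key = b$key, behaviour = b, parent = obj))
  }
  n <- length(entries)
  lines <- c("digraph modules {", "  rankdir=LR;",
             "  node [shape=box, fontsize=10];")
  ids <- sprintf("b%d", seq_len(n))
  for (i in seq_len(n)) {
    e <- entries[[i]]
    parent_name <- if (inherits(e$parent, "Network")) "network" else e$parent$name
    label <- sprintf("%s\\nkey %s\\n%s", class(e$behaviour)[1],
                     format(e$key), parent_name)
    lines <- c(lines, sprintf('  %s [label="%s", order=%d];', ids[i], label, i))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      shared <- intersect(entries[[i]]$behaviour$writes,
                          entries[[j]]$behaviour$reads)
      for (v in shared) {
        lines <- c(lines, sprintf('  %s -> %s [label="%s"];', ids[i], ids[j], v))
      }
    }
  }
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (is.null(file)) return(dot)
  writeLines(dot, file)
  invisible(dot)
}
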