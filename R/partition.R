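# Partitioning: replace one large, sparse, locally-connected synapse group by
# many small dense ones over SubNeuronGroups, without changing simulation
# results. The destination grid is cut into axis-aligned blocks; each block
# is paired with the minimal source block dilated by the connection reach.

#' Maximal connection reach of a synapse group
#'
#' Scans the nonzero entries of the weight matrix and returns the largest
#' Chebyshev (box) distance between the grid coordinates of any connected
#' source/destination pair. Both endpoint groups need a
#' [attach_spatial_layout()].
#'
#' @param sg a [SynapseGroup] with a registered weight matrix.
#' @param matrix_name weight matrix name (default "W").
#' @return integer grid distance (0 for pure self-connections).
#' @export
infer_max_distance <- function(sg, matrix_name = "W") {
  src <- sg$src$base_group()
  dst <- sg$dst$base_group()
  if (is.null(src$layout) || is.null(dst$layout)) {
    stop(sprintf("infer_max_distance: both groups of '%s' need a spatial layout",
                 sg$name))
  }
  W <- sg$get_mat(matrix_name)
  nz <- which(W != 0, arr.ind = TRUE)
  if (nrow(nz) == 0) return(0L)
  di <- sg$dst_indices()[nz[, 1]]
  sj <- sg$src_indices()[nz[, 2]]
  dl <- dst$layout; sl <- src$layout
  cheb <- pmax(abs(dl$x[di] - sl$x[sj]),
               abs(dl$y[di] - sl$y[sj]),
               abs(dl$z[di] - sl$z[sj]))
  as.integer(max(cheb))
}

#' Partition a synapse group into dense local blocks
#'
#' Cuts the destination grid into `blocks_per_axis` axis-aligned blocks per
#' axis, pairs each destination block with the minimal source block dilated
#' by the connection reach (`max_distance`, inferred from the weight matrix
#' when not given), and replaces `sg` in its network by one [SynapseGroup]
#' per block whose endpoints are [SubNeuronGroup] views. Weight values are
#' sliced, never recomputed, so the union of the part matrices reconstructs
#' the original bitwise; behaviours attached to `sg` are cloned onto every
#' part. Parts are registered in ascending block index (x fastest), which
#' fixes the floating-point summation order of downstream input behaviours.
#'
#' Destination blocks tile the group exactly, so every destination neuron
#' receives its afferent input from exactly one part and partitioned and
#' unpartitioned simulations agree bitwise.
#'
#' Call before `initialize_network()`, with the weight matrix already
#' created.
#'
#' @param sg the [SynapseGroup] to replace.
#' @param blocks_per_axis integer, or vector of 3 integers (x, y, z blocks).
#'   Blocks exceeding the grid collapse to a single block per axis.
#' @param max_distance connection reach override; default
#'   [infer_max_distance()].
#' @param matrix_name weight matrix name (default "W").
#' @return invisible list of the new [SynapseGroup] parts.
#' @export
partition_synapse_group <- function(sg, blocks_per_axis = 2,
                                    max_distance = NULL,
                                    matrix_name = "W") {
  net <- sg$network
  src <- sg$src$base_group()
  dst <- sg$dst$base_group()
  if (!inherits(sg$src, "NeuronGroup") || !inherits(sg$dst, "NeuronGroup")) {
    stop("partition_synapse_group expects a synapse group over full neuron groups")
  }
  if (is.null(src$layout) || is.null(dst$layout)) {
    stop(sprintf("partition_synapse_group: both groups of '%s' need a spatial layout",
                 sg$name))
  }
  if (is.null(max_distance)) max_distance <- infer_max_distance(sg, matrix_name)
  md <- as.integer(max_distance)
  b <- rep(as.integer(blocks_per_axis), length.out = 3)
  if (any(b < 1)) stop("blocks_per_axis must be >= 1")
  dl <- dst$layout; sl <- src$layout
  dims <- c(dl$width, dl$height, dl$depth)
  b <- pmin(b, dims)  # degenerate request: single block per short axis

  # block k (0-based) of n over extent w covers [floor(k*w/n), floor((k+1)*w/n) - 1]
  axis_range <- function(k, n, w) {
    lo <- floor(k * w / n)
    hi <- floor((k + 1) * w / n) - 1
    c(lo, hi)
  }

  W <- sg$get_mat(matrix_name)
  other_mats <- setdiff(sg$mat_names(), matrix_name)
  parts <- list()
  for (kz in seq_len(b[3]) - 1L) {
    rz <- axis_range(kz, b[3], dims[3])
    for (ky in seq_len(b[2]) - 1L) {
      ry <- axis_range(ky, b[2], dims[2])
      for (kx in seq_len(b[1]) - 1L) {
        rx <- axis_range(kx, b[1], dims[1])
        dmask <- dl$x >= rx[1] & dl$x <= rx[2] &
                 dl$y >= ry[1] & dl$y <= ry[2] &
                 dl$z >= rz[1] & dl$z <= rz[2]
        if (!any(dmask)) next
        smask <- sl$x >= rx[1] - md & sl$x <= rx[2] + md &
                 sl$y >= ry[1] - md & sl$y <= ry[2] + md &
                 sl$z >= rz[1] - md & sl$z <= rz[2] + md
        if (!any(smask)) next
        dsub <- dst$subgroup(dmask)
        ssub <- src$subgroup(smask)
        part <- net$add_synapse_group(
          ssub, dsub,
          name = sprintf("%s_part_%d_%d_%d", sg$name, kx, ky, kz),
          tags = unique(c(sg$tags, "partition")))
        part$adopt_mat(matrix_name, W[dmask, smask, drop = FALSE],
                       enabled = if (!is.null(sg$enabled))
                         sg$enabled[dmask, smask, drop = FALSE])
        for (nm in other_mats) {
          part$adopt_mat(nm, sg$get_mat(nm)[dmask, smask, drop = FALSE])
        }
        for (beh in sg$behaviours) {
          part$add_behaviour(beh$key, beh$clone(deep = TRUE))
        }
        parts[[length(parts) + 1L]] <- part
      }
    }
  }
  net$replace_synapse_group(sg, parts)
  invisible(parts)
}
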