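#' Hierarchical family clustering of hidden neurons by lateral-weight pruning
#'
#' Treats the hidden layer as a weighted graph on its (symmetrized) lateral
#' inhibitory weights and prunes edges from the most inhibitory upward: at
#' each cutoff `c` only edges with weight strictly greater than `c` are
#' kept, and the connected components of the remaining graph are that
#' level's families. Raising the cutoff toward 0 can only split components,
#' never merge them, which yields a nested tree of neuron families —
#' cooperating subgroups (weights near 0) stay joined, competing ones
#' (weights near -1) separate early.
#'
#' Directionality is collapsed by the element-wise minimum of `w[j, j']` and
#' `w[j', j]` (the strongest inhibition of the pair wins).
#'
#' @param lateral_W square hidden lateral weight matrix, entries in
#'   `[-1, 0]`, zero diagonal.
#' @param cutoffs increasing vector of pruning levels in `[-1, 0]`
#'   (default: -1 to 0 in steps of 0.05).
#' @return an object of class `family_tree`: a list with `cutoffs`,
#'   `partitions` (one integer membership vector per cutoff, components
#'   numbered from 1) and `n_components` per cutoff.
#' @export
cluster_families <- function(lateral_W, cutoffs = seq(-1, 0, by = 0.05)) {
  if (!is.matrix(lateral_W) || nrow(lateral_W) != ncol(lateral_W)) {
    stop("lateral_W must be square")
  }
  if (any(diag(lateral_W) != 0)) stop("lateral_W must have a zero diagonal")
  if (any(lateral_W < -1 | lateral_W > 0)) stop("lateral weights must lie in [-1, 0]")
  cutoffs <- sort(cutoffs)
  sym <- pmin(lateral_W, t(lateral_W))
  n <- nrow(sym)
  partitions <- vector("list", length(cutoffs))
  n_comp <- integer(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    keep <- sym > cutoffs[i]
    diag(keep) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(keep, mode = "undirected")
    comp <- igraph::components(g)
    partitions[[i]] <- as.integer(comp$membership)
    n_comp[i] <- comp$no
  }
  structure(
    list(cutoffs = cutoffs, partitions = partitions, n_components = n_comp,
         n_neurons = n),
    class = "family_tree"
  )
}

#' @export
print.family_tree <- function(x, ...) {
  cat(sprintf("<family_tree over %d neurons, %d cutoff levels>\n",
              x$n_neurons, length(x$cutoffs)))
  print(data.frame(cutoff = x$cutoffs, components = x$n_components),
        row.names = FALSE)
  invisible(x)
}

#' Pick the family-tree level with a target number of components
#'
#' Returns the index of the lowest cutoff whose partition has exactly `K`
#' components, or `NA` if no level does.
#'
#' @param tree a [cluster_families()] tree.
#' @param K target component count.
#' @return integer level index, or `NA_integer_`.
#' @export
level_with_k_components <- function(tree, K) {
  i <- which(tree$n_components == K)
  if (length(i) == 0L) NA_integer_ else i[1]
}

#' Map hidden-neuron families to output classes
#'
#' Tags each hidden neuron with the class of its strongest outgoing
#' feed-forward weight, labels each family with the majority tag, and
#' reports the majority fraction (purity). When true per-neuron class tags
#' coincide with the output classes (as after supervised training), the
#' adjusted Rand index between the family partition and the tags measures
#' how well lateral-weight pruning recovers the class structure.
#'
#' @param partition integer membership vector over hidden neurons (one
#'   family-tree level).
#' @param fwd_hidden_to_output_W hidden x output feed-forward weight matrix.
#' @return a list with per-family `label` (0-based class) and `purity`,
#'   per-neuron `neuron_class`, and `ari` — the adjusted Rand index between
#'   the partition and the per-neuron class tags.
#' @export
map_families_to_classes <- function(partition, fwd_hidden_to_output_W) {
  if (length(partition) != nrow(fwd_hidden_to_output_W)) {
    stop("partition must cover all hidden neurons")
  }
  neuron_class <- apply(fwd_hidden_to_output_W, 1, which.max) - 1L
  fams <- sort(unique(partition))
  label <- integer(length(fams))
  purity <- numeric(length(fams))
  for (i in seq_along(fams)) {
    members <- which(partition == fams[i])
    if (length(members) == 0L) stop("empty family")
    tab <- table(neuron_class[members])
    label[i] <- as.integer(names(tab)[which.max(tab)])
    purity[i] <- max(tab) / length(members)
  }
  list(label = label, purity = purity, neuron_class = neuron_class,
       ari = mclust::adjustedRandIndex(partition, neuron_class))
}

#' Per-class receptive-field maps from the product of forward weights
#'
#' The product of the input->hidden and hidden->output weight matrices gives,
#' for every output class, an input-space map of which pixels excite it —
#' a cheap visualization of what each class neuron has learned.
#'
#' @param W_in_hid input x hidden weights.
#' @param W_hid_out hidden x output weights.
#' @param normalize min-max normalize each class column for rendering.
#' @return an `n_input` x `n_output` matrix.
#' @export
receptive_field_product <- function(W_in_hid, W_hid_out, normalize = TRUE) {
  if (ncol(W_in_hid) != nrow(W_hid_out)) stop("weight matrix shapes do not compose")
  M <- W_in_hid %*% W_hid_out
  if (normalize) {
    M <- apply(M, 2, function(col) {
      rng <- range(col)
      if (diff(rng) == 0) rep(0, length(col)) else (col - rng[1]) / diff(rng)
    })
  }
  M
}

#' Correlation between forward and reciprocal hidden/output weights
#'
#' Pearson correlation between the hidden->output forward weights and the
#' aligned (transposed) output->hidden reciprocal weights. A positive
#' correlation after training indicates that output neurons feed back onto
#' the same hidden neurons that drive them.
#'
#' @param W_hid_out hidden x output forward weights.
#' @param W_out_hid output x hidden reciprocal weights.
#' @return Pearson r, or `NA_real_` when either matrix has zero variance
#'   (the correlation is then undefined).
#' @export
forward_reciprocal_correlation <- function(W_hid_out, W_out_hid) {
  aligned <- t(W_out_hid)
  if (!identical(dim(aligned), dim(W_hid_out))) stop("weight shapes do not align")
  x <- as.vector(W_hid_out)
  y <- as.vector(aligned)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Lesion the reciprocal connections of a trained network
#'
#' Sets all output->hidden reciprocal weights to 0 and freezes their
#' plasticity, leaving everything else untouched — the classic post-training
#' lesion probing how much recognition relies on the learned feedback.
#'
#' @param net an `snn_network` with the reciprocal group enabled.
#' @return the modified network, invisibly.
#' @export
lesion_reciprocal <- function(net) {
  if (!net$cfg$enabled[["reciprocal"]]) stop("reciprocal connections are not enabled")
  g <- net$groups$reciprocal
  g$W[] <- 0
  g$plastic <- FALSE
  net$groups$reciprocal <- g
  invisible(net)
}
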