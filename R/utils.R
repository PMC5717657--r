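#' Derive a reproducible substream seed
#'
#' Derives an integer seed for a named pipeline stage and replicate index from
#' a root seed, so that each replicate of each stage draws from its own
#' reproducible stream and changing the number of replicates never reshuffles
#' earlier ones.
#'
#' @param seed integer root seed.
#' @param stage character stage name (e.g. \code{"treeset"}).
#' @param replicate integer replicate index (0 for unreplicated stages).
#' @return A single integer in \code{[0, 2^31 - 2]}.
#' @export
derive_seed <- function(seed, stage, replicate = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  code <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  val <- (abs(as.numeric(seed)) + 10007 * as.numeric(replicate) + 999983 * code) %% 2147483646
  as.integer(val)
}

## internal: stop with a consistent "input error" style
.input_error <- function(...) stop(..., call. = FALSE)

## internal: children lookup table for a phylo object
.children_list <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2L])
  }
  kids
}

## internal: parent lookup (0 for root)
.parent_vec <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  par <- integer(n)
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  par
}

## internal: topological depth (edges from root) of every node
.topo_depths <- function(phy) {
  n <- ape::Ntip(phy) + phy$Nnode
  d <- integer(n)
  pre <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in rev(seq_len(nrow(pre)))) d[pre[i, 2L]] <- d[pre[i, 1L]] + 1L
  d
}

## internal: ensure a phylo has unique node labels (assigned as nd1, nd2, ...)
.ensure_node_labels <- function(phy) {
  nn <- phy$Nnode
  if (is.null(phy$node.label) || anyNA(phy$node.label) ||
      any(!nzchar(phy$node.label)) || anyDuplicated(phy$node.label)) {
    phy$node.label <- paste0("nd", seq_len(nn))
  }
  phy
}
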