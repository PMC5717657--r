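#' Ancestral shape variables under Brownian motion
#'
#' Maximum-likelihood point estimates of trait values at every internal node
#' under Brownian motion with a constant diffusion rate — equivalently, the
#' unique minimizer of the squared-change objective
#' \eqn{\sum_{branches} (x_{child} - x_{parent})^2 / v} per dimension
#' (squared-change parsimony weighted by branch duration v). Computed by a
#' two-pass pruning algorithm (tip-to-root contraction, root-to-tip
#' finalization) in O(n p) time; dimensions are independent. The diffusion
#' rate cancels and is not estimated.
#'
#' @param tree a [chrono_tree()] (polytomies allowed).
#' @param tip_traits numeric matrix of observed trait values with one row per
#'   tip (row names = tip labels), or a named vector for a single dimension.
#' @param eps branch durations below `eps` Myr are floored at `eps` with a
#'   warning (degenerate inputs only; never needed after 'equal' scaling).
#' @return An object of class `trait_tree`: list with `tree` (the
#'   `chrono_tree`) and `traits`, an (Ntip + Nnode) x p matrix holding the
#'   observed tip values followed by the node estimates (row names are tip
#'   then node labels).
#' @export
ancestral_states <- function(tree, tip_traits, eps = 1e-8) {
  stopifnot(inherits(tree, "chrono_tree"))
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  if (is.null(dim(tip_traits)))
    tip_traits <- matrix(tip_traits, ncol = 1L, dimnames = list(names(tip_traits), "trait"))
  miss <- setdiff(phy$tip.label, rownames(tip_traits))
  if (length(miss)) .input_error("missing trait values for tip(s): ", paste(miss, collapse = ", "))
  x <- tip_traits[phy$tip.label, , drop = FALSE]
  if (!is.numeric(x) || any(!is.finite(x)))
    .input_error("non-finite trait values among the tips")
  p <- ncol(x)

  po <- ape::reorder.phylo(phy, "postorder")
  v <- po$edge.length
  if (any(v < eps)) {
    warning(sum(v < eps), " branch duration(s) below ", eps, " Myr floored")
    v <- pmax(v, eps)
  }

  S1 <- numeric(n)                 # sum of 1/v' over children
  S2 <- matrix(0, n, p)            # sum of value/v' over children
  vedge <- numeric(n)              # (floored) duration of the branch above each node
  ## tip-to-root contraction
  for (i in seq_len(nrow(po$edge))) {
    par <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    vedge[ch] <- v[i]
    if (ch <= ntip) {
      val <- x[ch, ]
      vp <- v[i]
    } else {
      val <- S2[ch, ] / S1[ch]
      vp <- v[i] + 1 / S1[ch]
    }
    S1[par] <- S1[par] + 1 / vp
    S2[par, ] <- S2[par, ] + val / vp
  }

  xhat <- matrix(NA_real_, n, p)
  xhat[seq_len(ntip), ] <- x
  root <- ntip + 1L
  xhat[root, ] <- S2[root, ] / S1[root]
  ## root-to-tip finalization (reverse postorder = preorder)
  for (i in rev(seq_len(nrow(po$edge)))) {
    ch <- po$edge[i, 2L]
    if (ch <= ntip) next
    par <- po$edge[i, 1L]
    w <- 1 / vedge[ch]
    xhat[ch, ] <- (S2[ch, ] + xhat[par, ] * w) / (S1[ch] + w)
  }
  rownames(xhat) <- c(phy$tip.label, phy$node.label)
  colnames(xhat) <- colnames(x)
  structure(list(tree = tree, traits = xhat), class = "trait_tree")
}

#' @export
print.trait_tree <- function(x, ...) {
  cat("Trait-mapped tree:", ape::Ntip(x$tree$phy), "tips,",
      x$tree$phy$Nnode, "internal nodes,", ncol(x$traits), "trait dimension(s)\n")
  invisible(x)
}

#' Export node trait estimates as CSV
#'
#' Writes one row per node (tips included) with its label, age, and trait
#' values.
#'
#' @param x a `trait_tree`.
#' @param file CSV path.
#' @export
write_node_states <- function(x, file) {
  stopifnot(inherits(x, "trait_tree"))
  d <- data.frame(node = rownames(x$traits),
                  age = node_ages(x$tree),
                  x$traits, check.names = FALSE, row.names = NULL)
  utils::write.csv(d, file, row.names = FALSE)
  invisible(file)
}
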