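#' Time-scaled phylogeny with node ages
#'
#' A `chrono_tree` couples an [ape::phylo] topology with absolute node ages in
#' Ma before present (larger = older). Branch lengths are durations in Myr and
#' always equal `age(parent) - age(child)`.
#'
#' @param phy a rooted `phylo` object.
#' @param ages numeric vector of node ages (Ma), in ape node order
#'   (tips `1..Ntip`, then internal nodes `Ntip+1..Ntip+Nnode`).
#' @return An object of class `c("chrono_tree")` with elements `phy` (the
#'   topology, `edge.length` set to branch durations) and `ages`.
#' @export
chrono_tree <- function(phy, ages) {
  if (!inherits(phy, "phylo")) .input_error("'phy' must be a phylo object")
  n <- ape::Ntip(phy) + phy$Nnode
  if (length(ages) != n || !all(is.finite(ages)))
    .input_error("'ages' must be a finite numeric vector with one age per node")
  if (any(ages < -1e-9)) .input_error("node ages must be non-negative (Ma before present)")
  phy <- .ensure_node_labels(phy)
  dur <- ages[phy$edge[, 1L]] - ages[phy$edge[, 2L]]
  if (any(dur <= 0))
    .input_error("every parent must be older than its children (positive branch durations)")
  phy$edge.length <- dur
  structure(list(phy = phy, ages = as.numeric(ages)), class = "chrono_tree")
}

#' @export
print.chrono_tree <- function(x, ...) {
  cat("Time-scaled tree:", ape::Ntip(x$phy), "tips,", x$phy$Nnode,
      "internal nodes\n")
  cat("Root age:", format(root_age(x)), "Ma;",
      sum(tip_ages(x) < 1e-9), "extant tip(s)\n")
  invisible(x)
}

#' Node ages of a chrono_tree
#'
#' @param x a `chrono_tree`.
#' @return Named numeric vector of ages (Ma) for all nodes; names are tip
#'   labels followed by node labels.
#' @export
node_ages <- function(x) {
  stopifnot(inherits(x, "chrono_tree"))
  stats::setNames(x$ages, c(x$phy$tip.label, x$phy$node.label))
}

#' @rdname node_ages
#' @export
tip_ages <- function(x) {
  stopifnot(inherits(x, "chrono_tree"))
  stats::setNames(x$ages[seq_len(ape::Ntip(x$phy))], x$phy$tip.label)
}

#' @rdname node_ages
#' @export
root_age <- function(x) {
  stopifnot(inherits(x, "chrono_tree"))
  x$ages[ape::Ntip(x$phy) + 1L]
}

#' Read and write time-scaled trees
#'
#' Trees are stored as plain Newick with branch lengths equal to durations in
#' Myr. Absolute ages are recovered on reading from the tip ages, which the
#' caller supplies (typically from the stratigraphic range table); internal
#' consistency is checked to `tol`.
#'
#' @param x a `chrono_tree`.
#' @param file path to a Newick file.
#' @param tip_ages named numeric vector of tip ages (Ma), names = tip labels.
#' @param tol consistency tolerance on recovered ages (Ma).
#' @return `read_chrono_tree` returns a `chrono_tree`; `write_chrono_tree`
#'   returns `file` invisibly.
#' @export
write_chrono_tree <- function(x, file) {
  stopifnot(inherits(x, "chrono_tree"))
  ape::write.tree(x$phy, file = file, digits = 15)
  invisible(file)
}

#' @rdname write_chrono_tree
#' @export
read_chrono_tree <- function(file, tip_ages, tol = 1e-6) {
  phy <- ape::read.tree(file)
  if (is.null(phy$edge.length)) .input_error("tree file has no branch lengths")
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  depth <- numeric(n)
  pre <- ape::reorder.phylo(phy, "postorder")
  for (i in rev(seq_len(nrow(pre$edge))))
    depth[pre$edge[i, 2L]] <- depth[pre$edge[i, 1L]] + pre$edge.length[i]
  miss <- setdiff(phy$tip.label, names(tip_ages))
  if (length(miss)) .input_error("missing tip ages for: ", paste(miss, collapse = ", "))
  ra <- depth[seq_len(ntip)] + as.numeric(tip_ages[phy$tip.label])
  if (diff(range(ra)) > tol)
    .input_error("tip ages inconsistent with branch lengths (root age spread ",
                 format(diff(range(ra))), " Ma)")
  ages <- mean(ra) - depth
  ages[seq_len(ntip)] <- as.numeric(tip_ages[phy$tip.label])  # exact tip ages
  ages[ages < 0 & ages > -tol] <- 0
  chrono_tree(phy, ages)
}
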