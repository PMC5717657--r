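#' Stratigraphic age-range table
#'
#' Validates (or reads) a table of per-tip stratigraphic ranges: columns
#' `tip_id`, `older_bound`, `younger_bound` in Ma (larger = older). Extant
#' tips have both bounds equal to zero.
#'
#' @param x data frame with columns `tip_id`, `older_bound`, `younger_bound`.
#' @param file CSV path.
#' @return Validated data frame of class `strat_ranges`.
#' @export
strat_ranges <- function(x) {
  need <- c("tip_id", "older_bound", "younger_bound")
  if (!all(need %in% names(x))) .input_error("range table needs columns: ", paste(need, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$tip_id <- as.character(x$tip_id)
  if (anyDuplicated(x$tip_id)) .input_error("duplicated tip_id in range table")
  if (any(!is.finite(x$older_bound)) || any(!is.finite(x$younger_bound)))
    .input_error("non-finite bounds in range table")
  if (any(x$older_bound < 0) || any(x$younger_bound < 0))
    .input_error("stratigraphic bounds must be >= 0 Ma")
  if (any(x$older_bound < x$younger_bound))
    .input_error("older_bound must be >= younger_bound")
  class(x) <- c("strat_ranges", "data.frame")
  x
}

#' @rdname strat_ranges
#' @export
read_strat_ranges <- function(file) {
  strat_ranges(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' @rdname strat_ranges
#' @export
write_strat_ranges <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Which tips of a range table are extant?
#'
#' @param ranges a `strat_ranges` table.
#' @return Logical vector (TRUE where both bounds are zero).
#' @export
is_extant <- function(ranges) {
  ranges$older_bound == 0 & ranges$younger_bound == 0
}

#' Randomly resolve polytomies to a binary topology
#'
#' Every multifurcation is resolved by recursive random pairing: while a node
#' has more than two children, a uniformly chosen pair of its child subtrees
#' is joined under a new node. For a three-child polytomy this is uniform
#' over the three rooted resolutions. Every clade of the input is a clade of
#' the output.
#'
#' @param topology a rooted `phylo` (branch lengths, if any, are dropped).
#' @return A strictly binary rooted `phylo` with the same tip set.
#' @export
resolve_polytomies_random <- function(topology) {
  phy <- topology
  if (!inherits(phy, "phylo")) .input_error("'topology' must be a phylo object")
  ntip <- ape::Ntip(phy)
  kids <- .children_list(phy)
  build <- function(node) {
    if (node <= ntip) return(paste0("t", node))
    parts <- vapply(kids[[node]], build, character(1))
    while (length(parts) > 2L) {
      pick <- sample.int(length(parts), 2L)
      parts <- c(parts[-pick], paste0("(", parts[pick[1L]], ",", parts[pick[2L]], ")"))
    }
    if (length(parts) == 1L) parts else paste0("(", parts[1L], ",", parts[2L], ")")
  }
  txt <- paste0(build(ntip + 1L), ";")
  out <- ape::read.tree(text = txt)
  out$tip.label <- phy$tip.label[as.integer(sub("^t", "", out$tip.label))]
  out
}

#' Sample fossil tip ages from stratigraphic ranges
#'
#' In mode `"older_bound"` every fossil tip is assigned exactly the older
#' (lower) boundary of its stratigraphic unit; in mode `"uniform"` an age is
#' drawn uniformly over the unit's duration. Extant tips always get age 0.
#'
#' @param ranges a `strat_ranges` table.
#' @param mode `"older_bound"` or `"uniform"`.
#' @return Named numeric vector of tip ages (Ma).
#' @export
sample_fossil_ages <- function(ranges, mode = c("older_bound", "uniform")) {
  mode <- match.arg(mode)
  ranges <- strat_ranges(ranges)
  ages <- switch(mode,
    older_bound = ranges$older_bound,
    uniform = stats::runif(nrow(ranges), ranges$younger_bound, ranges$older_bound))
  ages[is_extant(ranges)] <- 0
  stats::setNames(ages, ranges$tip_id)
}

#' Node-age minimum constraints
#'
#' A constraint set is a list of entries, each `list(tips = <character>,
#' min_age = <Ma>)`, pinning the MRCA of `tips` to be at least `min_age` old.
#' One constraint set is typically drawn per replicate, emulating node ages
#' from a sample of posterior clock trees.
#'
#' `read_node_constraints` reads a long-format CSV with columns `sample_id`,
#' `clade_id`, `tip_id`, `min_age` and returns a list of constraint sets (one
#' per `sample_id`, in order of first appearance).
#'
#' @param file CSV path.
#' @return List of constraint sets.
#' @export
read_node_constraints <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "clade_id", "tip_id", "min_age")
  if (!all(need %in% names(d))) .input_error("constraint table needs columns: ", paste(need, collapse = ", "))
  lapply(split(d, factor(d$sample_id, levels = unique(d$sample_id))), function(s) {
    lapply(split(s, factor(s$clade_id, levels = unique(s$clade_id))), function(cl) {
      list(tips = as.character(cl$tip_id), min_age = cl$min_age[1L])
    })
  })
}

#' @rdname read_node_constraints
#' @param constraint_sets list of constraint sets to write.
#' @export
write_node_constraints <- function(constraint_sets, file) {
  rows <- do.call(rbind, lapply(seq_along(constraint_sets), function(s) {
    set <- constraint_sets[[s]]
    do.call(rbind, lapply(seq_along(set), function(j) {
      data.frame(sample_id = s, clade_id = j, tip_id = set[[j]]$tips,
                 min_age = set[[j]]$min_age)
    }))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Time-scale a topology with the 'equal' method
#'
#' Three-stage procedure producing strictly positive branch durations:
#' \enumerate{
#'   \item \emph{basic} node ages: each internal node is as old as its oldest
#'     descendant tip, raised further where a minimum-age constraint applies
#'     (minima propagate upward, so parents stay at least as old as children);
#'   \item the root age is increased by `vartime`;
#'   \item zero-duration branches are removed by sharing time: for each
#'     maximal root-ward chain of zero-duration branches, the duration of the
#'     nearest ancestral positive branch is redistributed evenly across
#'     itself and the chain (node ages are spaced evenly along the path;
#'     endpoint ages are untouched).
#' }
#' Tip ages are preserved exactly and root-to-tip spans are unchanged by
#' stage 3. Polytomies are allowed.
#'
#' @param topology rooted `phylo` (binary or polytomous).
#' @param tip_ages named numeric vector of tip ages (Ma), one per tip.
#' @param constraints a constraint set (see [read_node_constraints()]); may be
#'   empty.
#' @param vartime positive root extension (Myr).
#' @return A [chrono_tree()].
#' @export
time_scale_equal <- function(topology, tip_ages, constraints = list(), vartime = 1) {
  phy <- topology
  if (!inherits(phy, "phylo")) .input_error("'topology' must be a phylo object")
  if (!is.numeric(vartime) || vartime <= 0) .input_error("vartime must be > 0")
  ntip <- ape::Ntip(phy)
  if (ntip < 2L) .input_error("need at least 2 tips")
  n <- ntip + phy$Nnode
  root <- ntip + 1L
  miss <- setdiff(phy$tip.label, names(tip_ages))
  if (length(miss)) .input_error("missing tip ages for: ", paste(miss, collapse = ", "))
  ta <- as.numeric(tip_ages[phy$tip.label])
  if (any(!is.finite(ta)) || any(ta < 0)) .input_error("tip ages must be finite and >= 0")

  minage <- numeric(n)
  for (con in constraints) {
    bad <- setdiff(con$tips, phy$tip.label)
    if (length(bad)) .input_error("constraint names unknown tips: ", paste(bad, collapse = ", "))
    if (length(unique(con$tips)) < 2L)
      .input_error("constraint tip-sets must contain at least 2 tips")
    node <- ape::getMRCA(phy, con$tips)
    minage[node] <- max(minage[node], con$min_age)
  }

  ## stage 1: oldest-descendant ages with upward-propagating minima
  ages <- c(ta, rep(-Inf, phy$Nnode))
  po <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in seq_len(nrow(po))) {
    ch <- po[i, 2L]
    if (ch > ntip) ages[ch] <- max(ages[ch], minage[ch])
    ages[po[i, 1L]] <- max(ages[po[i, 1L]], ages[ch])
  }
  ages[root] <- max(ages[root], minage[root])

  ## stage 2: extend the root
  ages[root] <- ages[root] + vartime

  ## stage 3: even redistribution across zero-duration chains
  kids <- .children_list(phy)
  parent <- .parent_vec(phy)
  depth <- .topo_depths(phy)
  edge <- phy$edge
  tol0 <- 1e-12
  repeat {
    dur <- ages[edge[, 1L]] - ages[edge[, 2L]]
    zero <- which(dur < tol0)
    if (!length(zero)) break
    ## take the zero branch whose parent is closest to the root
    z <- zero[order(depth[edge[zero, 1L]], edge[zero, 1L], edge[zero, 2L])][1L]
    p <- edge[z, 1L]
    path <- edge[z, 2L]
    repeat {
      end <- path[length(path)]
      zk <- kids[[end]]
      if (is.null(zk)) break
      zk <- zk[ages[zk] > ages[end] - tol0]
      if (!length(zk)) break
      path <- c(path, min(zk))
    }
    q <- parent[p]
    if (q == 0L)
      stop("internal error: zero-duration branch at the root after stage 2")
    top <- ages[q]
    bottom <- ages[path[length(path)]]
    seg <- length(path) + 1L     # branches from q down to the chain end
    nodes <- c(p, path[-length(path)])
    ages[nodes] <- top - seq_along(nodes) * (top - bottom) / seg
  }

  dur <- ages[edge[, 1L]] - ages[edge[, 2L]]
  if (any(dur <= 0)) stop("internal error: non-positive duration after 'equal' scaling")
  for (con in constraints) {
    node <- ape::getMRCA(phy, con$tips)
    if (ages[node] < con$min_age - 1e-9)
      stop("internal error: constraint violated after scaling")
  }
  chrono_tree(phy, ages)
}

#' Specification for a stochastic time-scaling ensemble
#'
#' @param fossil_age_mode `"older_bound"` or `"uniform"` (see
#'   [sample_fossil_ages()]).
#' @param resolve_polytomies logical; randomly resolve before scaling?
#' @param n_replicates number of replicate trees.
#' @param vartime root extension (Myr).
#' @param seed root seed for the ensemble.
#' @return List of class `timescale_spec`.
#' @export
timescale_spec <- function(fossil_age_mode = c("uniform", "older_bound"),
                           resolve_polytomies = TRUE, n_replicates = 1000L,
                           vartime = 1, seed = 1L) {
  fossil_age_mode <- match.arg(fossil_age_mode)
  if (n_replicates < 1L) .input_error("n_replicates must be >= 1")
  structure(list(method = "equal", fossil_age_mode = fossil_age_mode,
                 resolve_polytomies = isTRUE(resolve_polytomies),
                 n_replicates = as.integer(n_replicates),
                 vartime = vartime, seed = as.integer(seed)),
            class = "timescale_spec")
}

#' Build a stochastic ensemble of time-scaled trees
#'
#' Per replicate: (a) resolve polytomies at random if requested, (b) sample
#' fossil tip ages per the chosen mode, (c) draw one node-constraint set
#' uniformly from the supplied collection, and (d) time-scale with the
#' 'equal' method. Each replicate runs under its own derived seed, so
#' individual replicates are independently reproducible.
#'
#' Three ensemble styles are in common use and map onto the options as:
#' set #1 = resolved polytomies + `older_bound` ages; set #2 = unresolved +
#' `uniform`; set #3 = resolved + `uniform`.
#'
#' @param topology rooted supertree (`phylo`), polytomies allowed.
#' @param ranges a `strat_ranges` table covering every tip.
#' @param constraint_sets list of constraint sets (may be empty = no
#'   constraints).
#' @param spec a [timescale_spec()].
#' @return List of `chrono_tree` of length `n_replicates`, class
#'   `chrono_tree_set`; each element carries attributes `replicate` and
#'   `constraint_set` (index drawn, or NA).
#' @export
build_tree_set <- function(topology, ranges, constraint_sets = list(), spec = timescale_spec()) {
  ranges <- strat_ranges(ranges)
  miss <- setdiff(topology$tip.label, ranges$tip_id)
  if (length(miss)) .input_error("tips without stratigraphic ranges: ", paste(miss, collapse = ", "))
  out <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    set.seed(derive_seed(spec$seed, "treeset", r))
    topo <- if (spec$resolve_polytomies) resolve_polytomies_random(topology) else topology
    tip_ages <- sample_fossil_ages(ranges, spec$fossil_age_mode)
    ci <- NA_integer_
    cons <- list()
    if (length(constraint_sets)) {
      ci <- sample.int(length(constraint_sets), 1L)
      cons <- constraint_sets[[ci]]
    }
    ct <- time_scale_equal(topo, tip_ages, cons, spec$vartime)
    attr(ct, "replicate") <- r
    attr(ct, "constraint_set") <- ci
    out[[r]] <- ct
  }
  structure(out, class = "chrono_tree_set", spec = spec)
}

#' @export
print.chrono_tree_set <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("Ensemble of", length(x), "time-scaled trees ('equal' method,",
      "fossil ages:", spec$fossil_age_mode,
      if (spec$resolve_polytomies) "; polytomies resolved)\n" else "; polytomies kept)\n")
  invisible(x)
}
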