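#' Simulate a birth-death tree with extinct tips
#'
#' Exact event-driven (Gillespie) simulation of a crown birth-death process:
#' two lineages start at the crown divergence, each lineage speciates at rate
#' `lambda` and goes extinct at rate `mu`. Extinct tips keep their extinction
#' ages; extant tips are at age 0. Two stop rules are supported: run to a
#' fixed crown `depth` (lineages alive then become extant), or stop when the
#' number of living lineages first reaches `extant_tips` (the present is then
#' placed just before the next event, so terminal durations stay positive).
#' Replicates that go completely extinct (or end with fewer than two tips)
#' are rejected and redrawn; the retry count is recorded.
#'
#' @param lambda speciation rate (events/Myr), > 0.
#' @param mu extinction rate (events/Myr), >= 0.
#' @param stop stop rule, `"depth"` or `"extant"`.
#' @param depth crown depth in Myr (for `stop = "depth"`).
#' @param extant_tips target number of living lineages (for
#'   `stop = "extant"`).
#' @param max_retries rejection limit before giving up.
#' @return A [chrono_tree()] with attribute `retries`.
#' @export
simulate_birth_death_tree <- function(lambda, mu = 0, stop = c("depth", "extant"),
                                      depth = NULL, extant_tips = NULL,
                                      max_retries = 1000L) {
  stop <- match.arg(stop)
  if (lambda <= 0 || mu < 0) .input_error("need lambda > 0 and mu >= 0")
  if (stop == "depth" && (is.null(depth) || depth <= 0))
    .input_error("stop = 'depth' needs a positive 'depth'")
  if (stop == "extant" && (is.null(extant_tips) || extant_tips < 2L))
    .input_error("stop = 'extant' needs extant_tips >= 2")
  for (try in seq_len(max_retries)) {
    res <- .sim_bd_once(lambda, mu, stop, depth, extant_tips)
    if (!is.null(res)) {
      attr(res, "retries") <- try - 1L
      return(res)
    }
  }
  stop("birth-death simulation failed ", max_retries,
       " times (total extinction); increase lambda/mu ratio or retries",
       call. = FALSE)
}

.sim_bd_once <- function(lambda, mu, stop, depth, extant_tips) {
  ## lineage records
  parent_event <- c(1L, 1L)      # event index of each lineage's birth
  t_birth <- c(0, 0)
  t_end <- c(NA_real_, NA_real_)
  fate <- c(NA_character_, NA_character_)  # "split", "extinct", "extant"
  split_event <- c(NA_integer_, NA_integer_)
  event_count <- 1L              # event 1 = crown divergence at t = 0
  active <- c(1L, 2L)
  t <- 0
  present <- NA_real_
  repeat {
    na <- length(active)
    if (na == 0L) return(NULL)
    if (stop == "extant" && na == extant_tips) {
      present <- t + stats::rexp(1L, na * (lambda + mu))
      break
    }
    if (length(fate) > 100000L) return(NULL)
    dt <- stats::rexp(1L, na * (lambda + mu))
    if (stop == "depth" && t + dt > depth) {
      present <- depth
      break
    }
    t <- t + dt
    i <- active[sample.int(na, 1L)]
    if (stats::runif(1L) < lambda / (lambda + mu)) {
      event_count <- event_count + 1L
      t_end[i] <- t
      fate[i] <- "split"
      split_event[i] <- event_count
      parent_event <- c(parent_event, event_count, event_count)
      t_birth <- c(t_birth, t, t)
      t_end <- c(t_end, NA_real_, NA_real_)
      fate <- c(fate, NA_character_, NA_character_)
      split_event <- c(split_event, NA_integer_, NA_integer_)
      active <- c(active[active != i], length(fate) - 1L, length(fate))
    } else {
      t_end[i] <- t
      fate[i] <- "extinct"
      active <- active[active != i]
    }
  }
  t_end[active] <- present
  fate[active] <- "extant"
  is_tip <- fate != "split"
  ntip <- sum(is_tip)
  if (ntip < 2L) return(NULL)

  tip_no <- integer(length(fate))
  tip_no[is_tip] <- seq_len(ntip)
  node_of_event <- ntip + seq_len(event_count)  # event j -> node ntip + j
  from <- node_of_event[parent_event]
  to <- ifelse(is_tip, tip_no, node_of_event[split_event])
  phy <- list(edge = cbind(from, to), tip.label = paste0("t", seq_len(ntip)),
              Nnode = event_count, edge.length = t_end - t_birth,
              node.label = paste0("nd", seq_len(event_count)))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  storage.mode(phy$edge) <- "integer"
  phy <- ape::reorder.phylo(phy, "cladewise")
  event_times <- numeric(event_count)
  event_times[parent_event] <- t_birth
  ages <- present - c(t_end[is_tip][order(tip_no[is_tip])], event_times)
  ages[abs(ages) < 1e-12] <- 0
  chrono_tree(phy, ages)
}

#' Simulate Brownian-motion trait evolution on a time-scaled tree
#'
#' Forward simulation from a fixed root value: along each branch of duration
#' v, each of the p dimensions receives an independent Normal(0, sigma2 * v)
#' increment. True internal values are retained so recovery can be tested.
#'
#' @param tree a [chrono_tree()].
#' @param sigma2 diffusion rate (variance per Myr per dimension), >= 0.
#' @param root_value numeric p-vector at the root (default 0).
#' @param p number of dimensions (ignored when `root_value` is given).
#' @return List with `tips` (Ntip x p matrix, row names = tip labels),
#'   `nodes` (Nnode x p, true internal values), and `all`.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_value = NULL, p = 1L) {
  stopifnot(inherits(tree, "chrono_tree"))
  if (sigma2 < 0) .input_error("sigma2 must be >= 0")
  if (is.null(root_value)) root_value <- rep(0, p)
  p <- length(root_value)
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  x <- matrix(NA_real_, n, p)
  x[ntip + 1L, ] <- root_value
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[i, 1L]
    ch <- po$edge[i, 2L]
    x[ch, ] <- x[par, ] + stats::rnorm(p, 0, sqrt(sigma2 * po$edge.length[i]))
  }
  rownames(x) <- c(phy$tip.label, phy$node.label)
  colnames(x) <- paste0("PC", seq_len(p))
  list(tips = x[seq_len(ntip), , drop = FALSE],
       nodes = x[(ntip + 1L):n, , drop = FALSE],
       all = x)
}

#' Simulate landmark configurations evolving on a tree
#'
#' Flattened mean-shape coordinates evolve by Brownian motion down the tree;
#' each tip configuration is then disguised by a random similarity transform
#' (rotation uniform on the circle, log-scale Normal(0, 0.1), translation
#' Normal(0, 10 x mean-shape centroid size) per axis), which generalized
#' Procrustes alignment must remove.
#'
#' @param mean_shape k x 2 matrix, non-degenerate.
#' @param tree a [chrono_tree()].
#' @param sigma2 diffusion rate per coordinate per Myr.
#' @return Named list of k x 2 landmark configurations (one per tip), with
#'   attribute `deviations`, the true tip-level flattened BM deviations.
#' @export
simulate_landmark_shapes <- function(mean_shape, tree, sigma2 = 1e-4) {
  mean_shape <- as.matrix(mean_shape)
  if (centroid_size(mean_shape) < 1e-8) .input_error("degenerate mean shape")
  k <- nrow(mean_shape)
  bm <- simulate_bm_traits(tree, sigma2, root_value = as.numeric(t(mean_shape)))
  scale0 <- centroid_size(mean_shape)
  configs <- lapply(seq_len(nrow(bm$tips)), function(i) {
    m <- matrix(bm$tips[i, ], ncol = 2L, byrow = TRUE)
    th <- stats::runif(1L, 0, 2 * pi)
    r <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L)
    s <- exp(stats::rnorm(1L, 0, 0.1))
    tr <- stats::rnorm(2L, 0, 10 * scale0)
    sweep(s * (m %*% r), 2L, -tr)
  })
  names(configs) <- rownames(bm$tips)
  attr(configs, "deviations") <- sweep(bm$tips, 2L, as.numeric(t(mean_shape)))
  configs
}

#' Assign stratigraphic units to the tips of a true chronogram
#'
#' Each fossil (non-extant) tip receives the stratigraphic unit containing
#' its true age (`younger < age <= older`); extant tips get the (0, 0)
#' range. By construction every true age lies inside its assigned range.
#'
#' @param tree a [chrono_tree()].
#' @param units data frame with columns `older`, `younger` (Ma) tiling the
#'   tree's age span.
#' @param extant_tol tips no older than this are treated as extant.
#' @return A [strat_ranges()] table.
#' @export
assign_strat_ranges <- function(tree, units, extant_tol = 1e-9) {
  stopifnot(inherits(tree, "chrono_tree"))
  ta <- tip_ages(tree)
  rows <- lapply(names(ta), function(tp) {
    a <- ta[[tp]]
    if (a <= extant_tol) return(data.frame(tip_id = tp, older_bound = 0, younger_bound = 0))
    hit <- which(units$younger < a & a <= units$older)
    if (!length(hit)) .input_error("tip '", tp, "' age ", format(a), " Ma outside all units")
    data.frame(tip_id = tp, older_bound = units$older[hit[1L]],
               younger_bound = units$younger[hit[1L]])
  })
  strat_ranges(do.call(rbind, rows))
}

#' Collapse a fraction of internal edges into polytomies
#'
#' A uniformly chosen fraction of the internal edges is collapsed (children
#' reattached to the grandparent), yielding an undated topology with
#' polytomies as in a typical supertree.
#'
#' @param tree a [chrono_tree()] or rooted `phylo`.
#' @param fraction fraction of internal edges to collapse, in \[0, 1).
#' @return A rooted `phylo` topology without branch lengths.
#' @export
inject_polytomies <- function(tree, fraction = 0.25) {
  phy <- if (inherits(tree, "chrono_tree")) tree$phy else tree
  if (fraction < 0 || fraction >= 1) .input_error("fraction must be in [0, 1)")
  ntip <- ape::Ntip(phy)
  internal <- which(phy$edge[, 2L] > ntip)
  ncol_ <- round(fraction * length(internal))
  el <- rep(1, nrow(phy$edge))
  if (ncol_ > 0L) el[sample(internal, ncol_)] <- 0
  phy$edge.length <- el
  out <- ape::di2multi(phy, tol = 0.5)
  out$edge.length <- NULL
  out$node.label <- NULL
  out
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Builds the default end-to-end fixture: a crown birth-death tree with
#' extinct and extant tips (lambda = 0.1, mu = 0.05 per Myr, stopped at 20
#' living lineages, so roughly 40 tips overall and a crown depth usually
#' between 40 and 100 Myr), Brownian shape scores in p = 7 dimensions at
#' rate 1 per Myr, stage-like 5-Myr stratigraphic units covering the tree
#' span (fossil dating is typically finer than the analysis bins), 10-Myr
#' time bins plus a Recent bin pinned at midpoint 0, a supertree topology
#' with a quarter of the internal edges collapsed into polytomies, and
#' optional minimum-age constraint sets emulating posterior clock-tree
#' samples: each set is one coherent chronogram (common rescaling uniform on
#' 90-110% of the truth plus 3% per-node log-normal jitter, nestedness
#' restored) read off at every node with at least two extant descendants.
#'
#' @param seed root seed.
#' @param lambda,mu birth and death rates (events/Myr).
#' @param extant_tips stop rule: number of living lineages.
#' @param p trait dimensions.
#' @param sigma2 BM rate per dimension (variance/Myr).
#' @param unit_width stratigraphic unit width for fossil dating (Myr).
#' @param bin_width time-bin width for the disparity analysis (Myr).
#' @param polytomy_fraction fraction of internal edges collapsed in the
#'   supertree topology.
#' @param n_constraint_sets number of constraint sets to draw (0 = none).
#' @param landmarks if > 0, also simulate this many landmarks per
#'   configuration (returned as `configs`).
#' @return List with `true_tree` (chrono_tree), `traits` (true BM values),
#'   `topology` (polytomous supertree), `ranges`, `bins`, `constraint_sets`,
#'   `scores` (tip score matrix), and optionally `configs`.
#' @export
simulate_study <- function(seed = 1L, lambda = 0.1, mu = 0.05, extant_tips = 20L,
                           p = 7L, sigma2 = 1, unit_width = 5, bin_width = 10,
                           polytomy_fraction = 0.25, n_constraint_sets = 10L,
                           landmarks = 0L) {
  set.seed(derive_seed(seed, "study"))
  true_tree <- simulate_birth_death_tree(lambda, mu, stop = "extant",
                                         extant_tips = extant_tips)
  traits <- simulate_bm_traits(true_tree, sigma2, p = p)
  ra <- root_age(true_tree)
  ue <- seq(0, ceiling(ra / unit_width) * unit_width, by = unit_width)
  units <- data.frame(older = ue[-1L], younger = ue[-length(ue)])
  ranges <- assign_strat_ranges(true_tree, units)
  be <- seq(0, ceiling(ra / bin_width) * bin_width, by = bin_width)
  b_old <- rev(be[-1L])
  b_yng <- rev(be[-length(be)])
  b_yng[length(b_yng)] <- 0.0117      # make room for the Recent bin
  bins <- time_bins(older = c(b_old, 0.0117), younger = c(b_yng, 0),
                    midpoint = c(rep(NA_real_, length(b_old)), 0))
  bins$name[nrow(bins)] <- "Recent"
  topology <- inject_polytomies(true_tree, polytomy_fraction)
  constraint_sets <- list()
  if (n_constraint_sets > 0L) {
    ## emulate posterior clock-tree samples: every node with at least two
    ## extant descendants gets a dated minimum scattered around its true age
    phy <- true_tree$phy
    ntip <- ape::Ntip(phy)
    extant <- which(tip_ages(true_tree) <= 1e-9)
    datable <- Filter(function(nd) {
      sum(.descendant_tips(phy, nd) %in% extant) >= 2L
    }, (ntip + 1L):(ntip + phy$Nnode))
    constraint_sets <- lapply(seq_len(n_constraint_sets), function(s) {
      ## one coherent chronogram per set: a common rescaling plus small
      ## per-node jitter, with nestedness (parent >= child) restored, the way
      ## ages inside a single posterior tree are mutually consistent
      f <- stats::runif(1L, 0.9, 1.1)
      a <- true_tree$ages * f * exp(stats::rnorm(length(true_tree$ages), 0, 0.03))
      po <- ape::reorder.phylo(phy, "postorder")$edge
      for (i in seq_len(nrow(po)))
        if (po[i, 2L] > ntip) a[po[i, 1L]] <- max(a[po[i, 1L]], a[po[i, 2L]])
      lapply(datable, function(nd) {
        tips <- phy$tip.label[intersect(.descendant_tips(phy, nd), extant)]
        list(tips = tips, min_age = a[nd])
      })
    })
  }
  out <- list(true_tree = true_tree, traits = traits, topology = topology,
              ranges = ranges, bins = bins, constraint_sets = constraint_sets,
              scores = traits$tips)
  if (landmarks > 0L) {
    th <- seq(0, 2 * pi, length.out = landmarks + 1L)[-1L]
    mean_shape <- cbind(cos(th), sin(th) * 0.6)
    out$mean_shape <- mean_shape
    out$configs <- simulate_landmark_shapes(mean_shape, true_tree, sigma2 = 1e-4)
  }
  out
}

## internal: tip descendants of a node (node itself if a tip)
.descendant_tips <- function(phy, node) {
  ntip <- ape::Ntip(phy)
  if (node <= ntip) return(node)
  kids <- .children_list(phy)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[[1L]]
    stack <- stack[-1L]
    ch <- kids[[nd]]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}
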