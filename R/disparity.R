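#' Time-bin series
#'
#' A series of named, non-overlapping stratigraphic bins ordered from oldest
#' to youngest. Lineages are sampled at each bin's temporal midpoint,
#' `(older + younger) / 2` by default. A `midpoint` column may override the
#' default — the conventional use is a Recent bin pinned at midpoint 0 Ma so
#' that extant tip values enter the youngest bin directly.
#'
#' @param older,younger bin boundaries in Ma (older > younger >= 0).
#' @param name optional bin names.
#' @param midpoint optional midpoint overrides (NA = arithmetic midpoint).
#' @param x data frame with columns `name`, `older`, `younger` and optional
#'   `midpoint`.
#' @param file CSV path.
#' @return Data frame of class `time_bins` with columns `name`, `older`,
#'   `younger`, `midpoint`.
#' @export
time_bins <- function(older, younger, name = NULL, midpoint = NULL) {
  if (length(older) != length(younger)) .input_error("older/younger length mismatch")
  if (any(!is.finite(older)) || any(!is.finite(younger)))
    .input_error("bin boundaries must be finite")
  if (any(younger < 0) || any(older <= younger))
    .input_error("bins need older > younger >= 0")
  if (is.null(name))
    name <- paste0(vapply(older, format, character(1), trim = TRUE), "-",
                   vapply(younger, format, character(1), trim = TRUE))
  mid <- (older + younger) / 2
  if (!is.null(midpoint)) {
    ok <- !is.na(midpoint)
    if (any(midpoint[ok] > older[ok] | midpoint[ok] < younger[ok]))
      .input_error("midpoint overrides must lie within their bins")
    mid[ok] <- midpoint[ok]
  }
  o <- order(older, decreasing = TRUE)
  d <- data.frame(name = as.character(name), older = older, younger = younger,
                  midpoint = mid)[o, , drop = FALSE]
  if (any(d$older[-1L] > d$younger[-nrow(d)] + 1e-12))
    .input_error("bins overlap")
  rownames(d) <- NULL
  class(d) <- c("time_bins", "data.frame")
  d
}

#' @rdname time_bins
#' @export
read_time_bins <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("name", "older", "younger")
  if (!all(need %in% names(d))) .input_error("bin table needs columns: ", paste(need, collapse = ", "))
  time_bins(d$older, d$younger, d$name, if ("midpoint" %in% names(d)) d$midpoint)
}

#' @rdname time_bins
#' @export
write_time_bins <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}

#' Interpolate lineages at a time slice (gradual model)
#'
#' Linear interpolation of trait values along each branch whose age interval
#' contains `t`: a branch from parent (age \eqn{a_p}, value \eqn{x_p}) to
#' child (age \eqn{a_c}, value \eqn{x_c}) contributes
#' \eqn{x_p + (x_c - x_p) (a_p - t) / (a_p - a_c)}. Branch membership uses
#' the closed interval with deduplication: a node whose age equals `t`
#' contributes exactly once, through its parent branch; the root at `t`
#' contributes its own value. A slice older than the root is empty.
#'
#' @param tm_tree a `trait_tree` from [ancestral_states()].
#' @param t slice age (Ma, >= 0).
#' @return Object of class `lineage_slice`: list with `t`, `branch`
#'   (labels of the child node of each sampled branch), and `values`
#'   (n_lineages x p matrix).
#' @export
interpolate_at_time <- function(tm_tree, t) {
  stopifnot(inherits(tm_tree, "trait_tree"))
  if (!is.finite(t) || t < 0) .input_error("slice age must be finite and >= 0")
  ct <- tm_tree$tree
  phy <- ct$phy
  ages <- ct$ages
  xh <- tm_tree$traits
  root <- ape::Ntip(phy) + 1L
  labs <- c(phy$tip.label, phy$node.label)
  if (t > ages[root]) {
    vals <- xh[0L, , drop = FALSE]
  } else if (t == ages[root]) {
    vals <- xh[root, , drop = FALSE]
    rownames(vals) <- labs[root]
  } else {
    ap <- ages[phy$edge[, 1L]]
    ac <- ages[phy$edge[, 2L]]
    sel <- which(ac <= t & t < ap)
    w <- (ap[sel] - t) / (ap[sel] - ac[sel])
    vals <- xh[phy$edge[sel, 1L], , drop = FALSE] * (1 - w) +
      xh[phy$edge[sel, 2L], , drop = FALSE] * w
    rownames(vals) <- labs[phy$edge[sel, 2L]]
  }
  structure(list(t = t, branch = rownames(vals), values = vals),
            class = "lineage_slice")
}

#' @export
print.lineage_slice <- function(x, ...) {
  cat("Lineage slice at", format(x$t), "Ma:", nrow(x$values), "branch(es),",
      ncol(x$values), "dimension(s)\n")
  invisible(x)
}

#' Sum of variances of a lineage slice
#'
#' Disparity of one time slice: the sum over trait dimensions of the sample
#' variance (n - 1 denominator) of the interpolated branch values. Only the
#' interpolated branch samples enter — no separate terminal or node values
#' are appended. Undefined (NA) with fewer than two lineages.
#'
#' @param slice a `lineage_slice`, or a numeric matrix of samples x
#'   dimensions.
#' @return Non-negative scalar, or `NA_real_` when fewer than 2 samples.
#' @export
sum_of_variances <- function(slice) {
  m <- if (inherits(slice, "lineage_slice")) slice$values else as.matrix(slice)
  if (nrow(m) < 2L) return(NA_real_)
  sum(apply(m, 2L, stats::var))
}

#' Disparity-through-time curve for one tree
#'
#' For each time bin, interpolates all lineages at the bin midpoint and
#' computes the sum of variances. Bins crossed by fewer than two lineages get
#' a missing (NA) disparity, not zero.
#'
#' @param tm_tree a `trait_tree`.
#' @param bins a [time_bins()] series.
#' @return Data frame of class `disparity_curve` with columns `bin`,
#'   `older`, `younger`, `midpoint`, `n_lineages`, `sov`.
#' @export
disparity_curve <- function(tm_tree, bins) {
  stopifnot(inherits(tm_tree, "trait_tree"), inherits(bins, "time_bins"))
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    sl <- interpolate_at_time(tm_tree, bins$midpoint[i])
    data.frame(bin = bins$name[i], older = bins$older[i], younger = bins$younger[i],
               midpoint = bins$midpoint[i], n_lineages = nrow(sl$values),
               sov = sum_of_variances(sl))
  })
  d <- do.call(rbind, rows)
  class(d) <- c("disparity_curve", "data.frame")
  d
}

#' Ensemble summary of disparity curves across replicate trees
#'
#' Per bin, summarises the sum of variances over all replicate curves in
#' which it is defined: median, 2.5% and 97.5% quantiles, minimum and
#' maximum. Bins undefined in every replicate stay missing.
#'
#' @param curves list of `disparity_curve` sharing one bin series.
#' @return Data frame of class `disparity_ensemble` with columns `bin`,
#'   `midpoint`, `n_defined`, `median`, `q025`, `q975`, `min`, `max`, plus
#'   `n_lineages_median`.
#' @export
ensemble_summary <- function(curves) {
  if (!length(curves)) .input_error("need at least one curve")
  if (inherits(curves, "disparity_curve")) curves <- list(curves)
  ref <- curves[[1L]]
  for (cu in curves)
    if (!identical(cu$bin, ref$bin) || max(abs(cu$midpoint - ref$midpoint)) > 1e-9)
      .input_error("curves do not share the same bin series")
  sov <- vapply(curves, `[[`, numeric(nrow(ref)), "sov")
  nl <- vapply(curves, `[[`, numeric(nrow(ref)), "n_lineages")
  sov <- matrix(sov, nrow = nrow(ref))
  nl <- matrix(nl, nrow = nrow(ref))
  summ <- t(vapply(seq_len(nrow(ref)), function(i) {
    v <- sov[i, ]
    v <- v[!is.na(v)]
    if (!length(v)) return(c(0, NA, NA, NA, NA, NA))
    c(length(v), stats::median(v), stats::quantile(v, c(0.025, 0.975), names = FALSE),
      min(v), max(v))
  }, numeric(6)))
  d <- data.frame(bin = ref$bin, midpoint = ref$midpoint,
                  n_defined = as.integer(summ[, 1L]), median = summ[, 2L],
                  q025 = summ[, 3L], q975 = summ[, 4L],
                  min = summ[, 5L], max = summ[, 6L],
                  n_lineages_median = apply(nl, 1L, stats::median))
  class(d) <- c("disparity_ensemble", "data.frame")
  d
}

#' Restrict a trait-mapped tree to a clade
#'
#' Extracts the subtree rooted at the most recent common ancestor of
#' `tip_set`, carrying node ages and reconstructed values over unchanged (no
#' re-estimation). A slice of the subset therefore equals the corresponding
#' whole-tree slice restricted to the clade's branches.
#'
#' @param tm_tree a `trait_tree`.
#' @param tip_set character vector (>= 2) of tip labels.
#' @return A `trait_tree` for the clade.
#' @export
clade_subset <- function(tm_tree, tip_set) {
  stopifnot(inherits(tm_tree, "trait_tree"))
  phy <- tm_tree$tree$phy
  bad <- setdiff(tip_set, phy$tip.label)
  if (length(bad)) .input_error("unknown tips: ", paste(bad, collapse = ", "))
  if (length(unique(tip_set)) < 2L) .input_error("tip_set must contain at least 2 tips")
  mrca <- ape::getMRCA(phy, tip_set)
  labs <- c(phy$tip.label, phy$node.label)
  if (mrca == ape::Ntip(phy) + 1L) {
    sub <- phy
  } else {
    sub <- ape::extract.clade(phy, mrca)
  }
  sublabs <- c(sub$tip.label, sub$node.label)
  idx <- match(sublabs, labs)
  ct <- chrono_tree(sub, tm_tree$tree$ages[idx])
  structure(list(tree = ct, traits = tm_tree$traits[idx, , drop = FALSE]),
            class = "trait_tree")
}

#' Drop fossil tips from a topology and its range table
#'
#' Retains only extant tips (both stratigraphic bounds zero); internal
#' degree-2 nodes left behind are suppressed, with branch durations summed,
#' so root-to-tip path lengths among the remaining tips are unchanged.
#'
#' @param topology rooted `phylo`.
#' @param ranges `strat_ranges` covering every tip.
#' @return List with elements `topology` and `ranges` restricted to extant
#'   tips.
#' @export
drop_fossils <- function(topology, ranges) {
  ranges <- strat_ranges(ranges)
  keep <- ranges$tip_id[is_extant(ranges)]
  keep <- intersect(topology$tip.label, keep)
  if (length(keep) < 2L) .input_error("fewer than 2 extant tips")
  list(topology = ape::keep.tip(topology, keep),
       ranges = strat_ranges(ranges[ranges$tip_id %in% keep, , drop = FALSE]))
}

#' Plot a disparity ensemble
#'
#' Curve of the per-bin median sum of variances against bin midpoint age
#' (time running left-to-right from oldest to youngest), with a band for the
#' full replicate range and a narrower band for the 2.5–97.5% quantile
#' envelope.
#'
#' @param x a `disparity_ensemble`.
#' @param main,ylab plot annotation.
#' @param col_median,col_quant,col_range colours for the median line and the
#'   two bands.
#' @param ... passed to [graphics::plot()].
#' @export
plot.disparity_ensemble <- function(x, main = "Disparity through time",
                                    ylab = "Sum of variances",
                                    col_median = "blue4",
                                    col_quant = grDevices::adjustcolor("cyan3", 0.5),
                                    col_range = grDevices::adjustcolor("goldenrod1", 0.5),
                                    ...) {
  ok <- !is.na(x$median)
  graphics::plot(x$midpoint[ok], x$median[ok], type = "n",
                 xlim = rev(range(x$midpoint[ok])),
                 ylim = range(c(x$min[ok], x$max[ok])),
                 xlab = "Age (Ma)", ylab = ylab, main = main, ...)
  graphics::polygon(c(x$midpoint[ok], rev(x$midpoint[ok])),
                    c(x$min[ok], rev(x$max[ok])), col = col_range, border = NA)
  graphics::polygon(c(x$midpoint[ok], rev(x$midpoint[ok])),
                    c(x$q025[ok], rev(x$q975[ok])), col = col_quant, border = NA)
  graphics::lines(x$midpoint[ok], x$median[ok], col = col_median, lwd = 2)
  invisible(x)
}

#' @export
plot.disparity_curve <- function(x, ylab = "Sum of variances", ...) {
  ok <- !is.na(x$sov)
  graphics::plot(x$midpoint[ok], x$sov[ok], type = "b",
                 xlim = rev(range(x$midpoint[ok])),
                 xlab = "Age (Ma)", ylab = ylab, ...)
  invisible(x)
}

#' Write a disparity curve or ensemble as CSV
#'
#' @param x a `disparity_curve` or `disparity_ensemble`.
#' @param file CSV path.
#' @export
write_disparity_csv <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE)
  invisible(file)
}
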