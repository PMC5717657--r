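#' Centroid size of a landmark configuration
#'
#' @param x a k x 2 numeric matrix of landmark coordinates.
#' @return Square root of the summed squared deviations from the centroid.
#' @export
centroid_size <- function(x) {
  x <- as.matrix(x)
  sqrt(sum(scale(x, scale = FALSE)^2))
}

## internal: center to origin and scale to unit centroid size
.standardize_config <- function(x, id = "<config>") {
  x <- as.matrix(x)
  if (!all(is.finite(x))) .input_error("non-finite coordinates in configuration '", id, "'")
  x <- scale(x, scale = FALSE)
  cs <- sqrt(sum(x^2))
  if (cs < 1e-12)
    .input_error("degenerate configuration '", id, "': all landmarks identical")
  attr(x, "scaled:center") <- NULL
  x / cs
}

## internal: optimal rotation of X onto M (both centered), reflection disallowed.
## Returns list(R = 2x2 rotation, reflected = TRUE if the unconstrained optimum
## was a reflection).
.optimal_rotation <- function(x, m) {
  sv <- svd(crossprod(x, m))
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  r <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  list(R = r, reflected = d < 0)
}

#' Procrustes distance between two configurations
#'
#' Both configurations are centered and scaled to unit centroid size, then one
#' is rotated (no reflection) onto the other; the residual Frobenius norm is
#' returned.
#'
#' @param a,b k x 2 landmark matrices with corresponding landmarks.
#' @return Non-negative scalar distance.
#' @export
procrustes_distance <- function(a, b) {
  a <- .standardize_config(a, "a")
  b <- .standardize_config(b, "b")
  r <- .optimal_rotation(a, b)$R
  sqrt(sum((a %*% r - b)^2))
}

#' Generalized Procrustes alignment of 2-D landmark configurations
#'
#' Iteratively superimposes a set of landmark configurations: each is centered
#' at the origin, scaled to unit centroid size, and rotated onto the current
#' mean shape; the mean is then re-estimated until it stabilises. Reflections
#' are never applied; configurations whose unconstrained optimum would require
#' one are flagged.
#'
#' @param configs named list of k x 2 numeric matrices (same k, same landmark
#'   order). Names are specimen ids.
#' @param tol convergence tolerance on the change in the mean shape
#'   (Frobenius norm).
#' @param max_iter maximum number of mean-update iterations.
#' @return An object of class `gpa_alignment`: a list with `shapes` (named
#'   list of aligned k x 2 matrices), `mean_shape`, `iterations`, `converged`,
#'   and `reflected` (character vector of flagged specimen ids).
#' @export
generalized_procrustes <- function(configs, tol = 1e-10, max_iter = 100L) {
  if (!is.list(configs) || length(configs) < 2L)
    .input_error("need at least 2 landmark configurations")
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    names(configs) <- paste0("spec", seq_along(configs))
  k <- nrow(as.matrix(configs[[1L]]))
  if (k < 3L) .input_error("need at least 3 landmarks")
  dims <- vapply(configs, function(m) dim(as.matrix(m)), integer(2))
  if (any(dims[1L, ] != k) || any(dims[2L, ] != 2L))
    .input_error("all configurations must share the same landmark count (k x 2)")
  shapes <- mapply(.standardize_config, configs, names(configs), SIMPLIFY = FALSE)

  ## initial mean: plain average if non-degenerate, else the first shape
  m <- Reduce(`+`, shapes) / length(shapes)
  if (sqrt(sum(m^2)) < 1e-6) m <- shapes[[1L]]
  m <- .standardize_config(m, "<mean>")

  converged <- FALSE
  iterations <- 0L
  reflected <- character(0)
  for (it in seq_len(max_iter)) {
    iterations <- it
    rots <- lapply(shapes, .optimal_rotation, m = m)
    aligned <- mapply(function(s, r) s %*% r$R, shapes, rots, SIMPLIFY = FALSE)
    m_new <- .standardize_config(Reduce(`+`, aligned) / length(aligned), "<mean>")
    delta <- sqrt(sum((m_new - m)^2))
    m <- m_new
    if (delta < tol) {
      converged <- TRUE
      reflected <- names(shapes)[vapply(rots, `[[`, logical(1), "reflected")]
      break
    }
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter, " iterations")
  rots <- lapply(shapes, .optimal_rotation, m = m)
  reflected <- names(shapes)[vapply(rots, `[[`, logical(1), "reflected")]
  if (length(reflected))
    warning("configurations would require reflection (not applied): ",
            paste(reflected, collapse = ", "))
  aligned <- mapply(function(s, r) s %*% r$R, shapes, rots, SIMPLIFY = FALSE)
  structure(list(shapes = aligned, mean_shape = m, iterations = iterations,
                 converged = converged, reflected = reflected),
            class = "gpa_alignment")
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat("GPA alignment:", length(x$shapes), "configurations,",
      nrow(x$mean_shape), "landmarks;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iteration(s)\n")
  invisible(x)
}

#' Principal components of aligned shapes
#'
#' Eigendecomposition of the sample covariance (n - 1 denominator) of the
#' flattened aligned coordinates (x1, y1, ..., xk, yk), centered on the mean.
#' The number of retained axes defaults to the broken-stick criterion.
#'
#' @param shapes a `gpa_alignment` or a named list of aligned k x 2 matrices.
#' @param n_retained optional integer override for the number of retained
#'   axes (the retained count is otherwise chosen by [broken_stick_select()]).
#' @return An object of class `shape_space`: list with `scores` (n x p),
#'   `eigenvalues`, `loadings` (orthonormal columns), `mean_shape` (k x 2),
#'   `n_retained`, and `k`.
#' @export
principal_components <- function(shapes, n_retained = NULL) {
  if (inherits(shapes, "gpa_alignment")) shapes <- shapes$shapes
  n <- length(shapes)
  if (n < 3L) .input_error("need at least 3 shapes for a shape space")
  flat <- t(vapply(shapes, function(m) as.numeric(t(m)), numeric(2L * nrow(shapes[[1L]]))))
  rownames(flat) <- names(shapes)
  pca <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  k <- nrow(shapes[[1L]])
  auto <- if (sum(ev) > 0) broken_stick_select(ev) else 1L
  if (is.null(n_retained)) {
    n_retained <- auto
  } else {
    n_retained <- as.integer(n_retained)
    if (n_retained < 1L || n_retained > length(ev))
      .input_error("n_retained must be between 1 and ", length(ev))
  }
  structure(list(scores = pca$x, eigenvalues = ev, loadings = pca$rotation,
                 mean_shape = matrix(pca$center, ncol = 2L, byrow = TRUE),
                 n_retained = n_retained, k = k),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  cat("Shape space:", nrow(x$scores), "specimens,", length(x$eigenvalues),
      "axes;", x$n_retained, "retained\n")
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat("Variance explained by retained axes:",
      format(round(sum(pct[seq_len(x$n_retained)]), 1)), "%\n")
  invisible(x)
}

#' Retained scores of a shape space
#'
#' @param x a `shape_space`.
#' @return Matrix of scores restricted to the retained axes.
#' @export
retained_scores <- function(x) {
  stopifnot(inherits(x, "shape_space"))
  x$scores[, seq_len(x$n_retained), drop = FALSE]
}

#' Broken-stick selection of principal component axes
#'
#' Under a random partition of total variance among p axes, the expected
#' proportion of axis j is \eqn{b_j = (1/p) \sum_{i=j}^{p} 1/i}. The leading
#' contiguous run of axes whose observed proportion strictly exceeds its
#' broken-stick expectation is retained; at least one axis is always kept.
#'
#' @param eigenvalues non-negative eigenvalues in descending order.
#' @return Integer count of retained axes.
#' @export
broken_stick_select <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 1L || any(!is.finite(ev)) || any(ev < -1e-12))
    .input_error("eigenvalues must be finite and non-negative")
  if (is.unsorted(rev(ev) - 1e-12 * max(abs(ev))))
    .input_error("eigenvalues must be in descending order")
  if (sum(ev) <= 0) .input_error("all eigenvalues are zero")
  p <- length(ev)
  expected <- rev(cumsum(rev(1 / seq_len(p)))) / p
  observed <- ev / sum(ev)
  exceeds <- observed > expected     # strict: ties do not count
  run <- if (all(exceeds)) p else which(!exceeds)[1L] - 1L
  max(run, 1L)
}

#' Broken-stick expected proportions
#'
#' @param p number of axes.
#' @return Numeric vector of expected proportions \eqn{b_1, ..., b_p}.
#' @export
broken_stick_expectation <- function(p) {
  p <- as.integer(p)
  stopifnot(p >= 1L)
  rev(cumsum(rev(1 / seq_len(p)))) / p
}
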