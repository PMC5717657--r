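## Independent reference implementations used only to verify the package.

## Closed-form ordinary Procrustes superimposition of exactly two
## configurations: center, scale to unit centroid size, rotate b onto a by
## the SVD of the 2x2 cross-product. Returns the aligned pair and residual.
oracle_opa2 <- function(a, b) {
  std <- function(m) {
    m <- sweep(as.matrix(m), 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  a <- std(a)
  b <- std(b)
  sv <- svd(t(b) %*% a)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  b_rot <- b %*% rot
  list(a = a, b = b_rot, residual = sqrt(sum((a - b_rot)^2)))
}

## Brute-force BM/squared-change ancestral states: build the full
## inverse-duration-weighted graph Laplacian and solve the stationarity
## system for the internal values (a global linear solve, no pruning).
oracle_ancestral <- function(ct, tip_traits) {
  phy <- ct$phy
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  w <- 1 / pmax(phy$edge.length, 1e-8)
  L <- matrix(0, n, n)
  for (i in seq_len(nrow(phy$edge))) {
    a <- phy$edge[i, 1]
    b <- phy$edge[i, 2]
    L[a, b] <- L[a, b] - w[i]
    L[b, a] <- L[b, a] - w[i]
    L[a, a] <- L[a, a] + w[i]
    L[b, b] <- L[b, b] + w[i]
  }
  tips <- seq_len(ntip)
  internal <- (ntip + 1):n
  if (is.null(dim(tip_traits)))
    tip_traits <- matrix(tip_traits, ncol = 1, dimnames = list(names(tip_traits), NULL))
  xb <- tip_traits[phy$tip.label, , drop = FALSE]
  xi <- solve(L[internal, internal, drop = FALSE],
              -L[internal, tips, drop = FALSE] %*% xb)
  rownames(xi) <- phy$node.label
  rbind(xb, xi)
}

## Naive reference for the three-stage 'equal' time-scaling, coded over
## label-keyed recursive helpers rather than edge-matrix arithmetic.
oracle_equal <- function(phy, tip_ages, constraints = list(), vartime = 1) {
  ntip <- ape::Ntip(phy)
  n <- ntip + phy$Nnode
  root <- ntip + 1
  kids_of <- function(nd) phy$edge[phy$edge[, 1] == nd, 2]
  parent_of <- function(nd) phy$edge[phy$edge[, 2] == nd, 1]
  minage <- rep(0, n)
  for (con in constraints) {
    nd <- ape::getMRCA(phy, con$tips)
    minage[nd] <- max(minage[nd], con$min_age)
  }
  age <- rep(NA_real_, n)
  age[seq_len(ntip)] <- tip_ages[phy$tip.label]
  basic <- function(nd) {
    if (nd <= ntip) return(age[nd])
    a <- max(c(vapply(kids_of(nd), basic, numeric(1)), minage[nd]))
    age[nd] <<- a
    a
  }
  basic(root)
  age[root] <- age[root] + vartime
  depth_of <- function(nd) {
    d <- 0
    while (nd != root) {
      nd <- parent_of(nd)
      d <- d + 1
    }
    d
  }
  repeat {
    zz <- which(age[phy$edge[, 1]] - age[phy$edge[, 2]] < 1e-12)
    if (!length(zz)) break
    zz <- zz[order(vapply(phy$edge[zz, 1], depth_of, numeric(1)),
                   phy$edge[zz, 1], phy$edge[zz, 2])]
    p <- phy$edge[zz[1], 1]
    chain <- phy$edge[zz[1], 2]
    repeat {
      last <- chain[length(chain)]
      zk <- kids_of(last)
      zk <- zk[age[zk] > age[last] - 1e-12]
      if (!length(zk)) break
      chain <- c(chain, min(zk))
    }
    top <- age[parent_of(p)]
    bottom <- age[chain[length(chain)]]
    nodes <- c(p, chain[-length(chain)])
    step <- (top - bottom) / (length(chain) + 1)
    for (j in seq_along(nodes)) age[nodes[j]] <- top - j * step
  }
  age
}

## Brute-force time slice: closed-interval scan over every branch, with the
## explicit deduplication rule (a node at exactly t contributes once, via its
## parent branch; the root contributes its own value).
oracle_slice <- function(tt, t) {
  phy <- tt$tree$phy
  ages <- tt$tree$ages
  X <- tt$traits
  root <- ape::Ntip(phy) + 1
  if (t > ages[root]) return(X[0, , drop = FALSE])
  contributors <- list()
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    ch <- phy$edge[i, 2]
    if (!(ages[ch] <= t && t <= ages[p])) next
    if (t == ages[p]) {
      ## value sits exactly on the parent node: belongs to p's own parent
      ## branch (or to the root itself)
      if (p == root) contributors[[paste0("n", p)]] <- X[p, ]
      next
    }
    w <- (ages[p] - t) / (ages[p] - ages[ch])
    contributors[[paste0("n", ch)]] <- X[p, ] * (1 - w) + X[ch, ] * w
  }
  do.call(rbind, contributors)
}

## Random time-scaled tree with positive durations and fossil/extant mix.
rand_chrono <- function(ntip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rtree(ntip)
  n <- ntip + phy$Nnode
  depth <- numeric(n)
  po <- ape::reorder.phylo(phy, "postorder")
  for (i in rev(seq_len(nrow(po$edge))))
    depth[po$edge[i, 2]] <- depth[po$edge[i, 1]] + po$edge.length[i]
  chrono_tree(phy, max(depth) - depth)
}

## Tip-label set of every clade of a rooted tree (for conservation checks).
clade_sets <- function(phy) {
  ntip <- ape::Ntip(phy)
  out <- lapply((ntip + 1):(ntip + phy$Nnode), function(nd) {
    sort(ape::extract.clade(phy, nd)$tip.label)
  })
  unique(lapply(out, paste, collapse = "|"))
}
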