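## tiny tree with a single branch spanning 10 -> 0 Ma on one side
lin_tree <- function() {
  phy <- ape::read.tree(text = "(A,B);")
  chrono_tree(phy, c(0, 0, 10))
}

test_that("gradual-model interpolation is linear with exact endpoints", {
  ct <- lin_tree()
  tt <- ancestral_states(ct, c(A = 5, B = 5))  # root value 5
  tt$traits["nd1", ] <- 0                      # pin parent value for the example
  sl <- interpolate_at_time(tt, 5)
  expect_equal(unname(sl$values[sl$branch == "A", 1]), 2.5)
  expect_equal(unname(interpolate_at_time(tt, 0)$values["A", 1]), 5)   # child end
  sl10 <- interpolate_at_time(tt, 10)          # root age: root's own value, once
  expect_equal(nrow(sl10$values), 1)
  expect_equal(unname(sl10$values[1, 1]), 0)
  expect_equal(nrow(interpolate_at_time(tt, 11)$values), 0)  # older than root
})

test_that("slice membership and values match the brute-force branch scan", {
  set.seed(41)
  for (i in 1:20) {
    ct <- rand_chrono(sample(8:20, 1))
    x <- matrix(rnorm(2 * ape::Ntip(ct$phy)), ncol = 2,
                dimnames = list(ct$phy$tip.label, c("a", "b")))
    tt <- ancestral_states(ct, x)
    for (t in c(runif(3, 0, root_age(ct)), ct$ages[sample(length(ct$ages), 1)])) {
      got <- interpolate_at_time(tt, t)
      ref <- oracle_slice(tt, t)
      expect_equal(nrow(got$values), if (is.null(ref)) 0 else nrow(ref))
      if (!is.null(ref) && nrow(ref))
        expect_equal(sort(as.numeric(got$values)), sort(as.numeric(ref)),
                     tolerance = 1e-10)
    }
  }
})

test_that("an internal node lying exactly on a midpoint is counted once", {
  ## ((A,B),C) with the inner node exactly at t = 5
  phy <- ape::read.tree(text = "((A,B),C);")
  ct <- chrono_tree(phy, c(0, 0, 0, 10, 5))
  tt <- ancestral_states(ct, c(A = 1, B = 3, C = 8))
  sl <- interpolate_at_time(tt, 5)
  ## branches crossing t=5: root->C and root->nd2 (ending exactly at 5);
  ## nd2's two daughter branches must NOT contribute again
  expect_equal(nrow(sl$values), 2)
  expect_setequal(sl$branch, c("C", "nd2"))
})

test_that("sum of variances matches hand values and is additive and symmetric", {
  expect_equal(sum_of_variances(matrix(c(0, 2), ncol = 1)), 2)
  expect_equal(sum_of_variances(matrix(c(0, 2, 0, 2), ncol = 2)), 4)
  expect_equal(sum_of_variances(matrix(3, 5, 2)), 0)
  expect_true(is.na(sum_of_variances(matrix(1, 1, 3))))
  set.seed(43)
  m <- matrix(rnorm(30), 10, 3)
  expect_equal(sum_of_variances(m), sum_of_variances(m[sample(10), ]))
  expect_equal(sum_of_variances(m),
               sum(vapply(1:3, function(j) var(m[, j]), numeric(1))))
})

test_that("per-bin lineage counts equal brute-force branch-interval counts", {
  set.seed(45)
  ## star tree: every bin below the root crosses all n branches
  n <- 12
  star <- chrono_tree(ape::read.tree(text = paste0("(", paste0("t", 1:n, collapse = ","), ");")),
                      c(rep(0, n), 50))
  tt_star <- ancestral_states(star, setNames(rnorm(n), paste0("t", 1:n)))
  bins <- time_bins(older = c(40, 30, 20, 10), younger = c(30, 20, 10, 0))
  dc <- disparity_curve(tt_star, bins)
  expect_equal(dc$n_lineages, rep(n, 4))
  ## random trees against the oracle count
  for (i in 1:5) {
    ct <- rand_chrono(10)
    tt <- ancestral_states(ct, setNames(rnorm(10), ct$phy$tip.label))
    bins <- time_bins(older = seq(root_age(ct), root_age(ct) / 5, length.out = 5),
                      younger = seq(root_age(ct), root_age(ct) / 5, length.out = 5) -
                        root_age(ct) / 6)
    dc <- disparity_curve(tt, bins)
    refn <- vapply(bins$midpoint, function(t) {
      r <- oracle_slice(tt, t)
      if (is.null(r)) 0L else nrow(r)
    }, integer(1))
    expect_equal(dc$n_lineages, as.integer(refn))
    expect_true(all(is.na(dc$sov) | dc$sov >= 0))
    expect_true(all(is.na(dc$sov[dc$n_lineages < 2])))
  }
})

test_that("ensemble summaries follow the sort-based quantile oracle", {
  set.seed(47)
  ct <- rand_chrono(8)
  tt <- ancestral_states(ct, setNames(rnorm(8), ct$phy$tip.label))
  bins <- time_bins(older = c(root_age(ct) * 0.9, root_age(ct) * 0.45),
                    younger = c(root_age(ct) * 0.45, 0))
  template <- disparity_curve(tt, bins)
  curves <- lapply(1:1000, function(i) {
    cu <- template
    cu$sov <- rexp(nrow(cu))
    cu
  })
  es <- ensemble_summary(curves)
  sov <- sapply(curves, `[[`, "sov")
  for (b in 1:2) {
    v <- sort(sov[b, ])
    expect_equal(es$median[b], median(v))
    expect_equal(es$q025[b], quantile(v, 0.025, names = FALSE))
    expect_equal(es$q975[b], quantile(v, 0.975, names = FALSE))
    expect_equal(es$min[b], v[1])
    expect_equal(es$max[b], v[1000])
  }
  expect_true(all(es$min <= es$q025 & es$q025 <= es$median &
                  es$median <= es$q975 & es$q975 <= es$max))
  ## single curve: median = min = max
  e1 <- ensemble_summary(list(template))
  ok <- !is.na(template$sov)
  expect_equal(e1$median[ok], template$sov[ok])
  expect_equal(e1$min[ok], template$sov[ok])
  expect_equal(e1$max[ok], template$sov[ok])
  ## mismatched bin series refused
  other <- disparity_curve(tt, time_bins(older = 5, younger = 1))
  expect_error(ensemble_summary(list(template, other)), "bin series")
})

test_that("clade subsets carry values over and reproduce whole-tree slices", {
  set.seed(49)
  ct <- rand_chrono(12)
  tt <- ancestral_states(ct, matrix(rnorm(24), 12, 2,
                                    dimnames = list(ct$phy$tip.label, NULL)))
  expect_equal(clade_subset(tt, ct$phy$tip.label)$traits, tt$traits)
  ## brute-force MRCA check + value preservation
  tips <- sample(ct$phy$tip.label, 4)
  sub <- clade_subset(tt, tips)
  mrca <- ape::getMRCA(ct$phy, tips)
  expect_equal(root_age(sub$tree), ct$ages[mrca])
  expect_equal(sub$traits[rownames(sub$traits), ],
               tt$traits[rownames(sub$traits), ])
  ## restriction property: whole-tree slice cut to the clade == clade slice
  t <- root_age(sub$tree) * 0.6
  whole <- interpolate_at_time(tt, t)
  part <- interpolate_at_time(sub, t)
  keep <- whole$branch %in% rownames(sub$traits)
  expect_equal(sort(as.numeric(whole$values[keep, ])),
               sort(as.numeric(part$values)), tolerance = 1e-12)
  expect_error(clade_subset(tt, c("nope", tips)), "unknown")
})

test_that("dropping fossils keeps extant relationships and path lengths", {
  st <- simulate_study(seed = 17)
  ranges <- st$ranges
  nfossil <- sum(!is_extant(ranges))
  expect_gt(nfossil, 0)
  ## use the dated true tree so path lengths are meaningful
  phy <- st$true_tree$phy
  out <- drop_fossils(phy, ranges)
  expect_equal(ape::Ntip(out$topology), ape::Ntip(phy) - nfossil)
  expect_true(all(is_extant(out$ranges)))
  keep <- out$topology$tip.label
  d_before <- ape::cophenetic.phylo(phy)[keep, keep]
  d_after <- ape::cophenetic.phylo(out$topology)[keep, keep]
  expect_equal(d_after, d_before, tolerance = 1e-9)
  ## all-extant input is unchanged
  ext <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  rng2 <- strat_ranges(data.frame(tip_id = c("A", "B", "C"),
                                  older_bound = 0, younger_bound = 0))
  expect_equal(ape::Ntip(drop_fossils(ext, rng2)$topology), 3)
})
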