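test_that("random polytomy resolution is binary and clade-conserving", {
  set.seed(11)
  bin <- ape::read.tree(text = "((A,B),(C,D));")
  expect_setequal(clade_sets(resolve_polytomies_random(bin)), clade_sets(bin))
  poly <- ape::read.tree(text = "((A,B,C,D),(E,(F,G,H)));")
  for (i in 1:10) {
    res <- resolve_polytomies_random(poly)
    expect_true(ape::is.binary(res))
    expect_setequal(res$tip.label, poly$tip.label)
    expect_true(all(clade_sets(poly) %in% clade_sets(res)))
  }
})

test_that("fossil age sampling follows the two stated modes", {
  rng <- strat_ranges(data.frame(
    tip_id = c("foss", "ext", "u"),
    older_bound = c(100.5, 0, 10),
    younger_bound = c(93.9, 0, 0)))
  a <- sample_fossil_ages(rng, "older_bound")
  expect_equal(unname(a[c("foss", "ext")]), c(100.5, 0))
  set.seed(5)
  draws <- replicate(1e4, sample_fossil_ages(rng, "uniform")[["u"]])
  expect_true(all(draws >= 0 & draws <= 10))
  expect_gt(ks.test(draws, "punif", 0, 10)$p.value, 0.001)
  ## extant tips stay at zero in uniform mode too
  expect_true(all(replicate(20, sample_fossil_ages(rng, "uniform")[["ext"]]) == 0))
})

test_that("'equal' time-scaling reproduces the worked example and its invariants", {
  topo <- ape::read.tree(text = "((A,B),C);")
  ct <- time_scale_equal(topo, c(A = 10, B = 5, C = 0), vartime = 1)
  ages <- node_ages(ct)
  expect_equal(unname(ages[c("A", "B", "C")]), c(10, 5, 0))
  expect_equal(unname(ages["nd1"]), 11)       # root: oldest tip + vartime
  expect_true(all(ct$phy$edge.length > 0))
  ## clock tree with constraints at the true ages: non-root nodes pinned
  clock <- ape::read.tree(text = "((A:10,B:10):5,(C:12,D:12):3);")
  cons <- list(list(tips = c("A", "B"), min_age = 10),
               list(tips = c("C", "D"), min_age = 12),
               list(tips = c("A", "C"), min_age = 15))
  ct2 <- time_scale_equal(clock, c(A = 0, B = 0, C = 0, D = 0), cons, vartime = 1)
  ages2 <- node_ages(ct2)
  expect_equal(unname(ages2[c("nd2", "nd3")]), c(10, 12))
  expect_equal(unname(ages2["nd1"]), 16)      # root constraint + vartime
})

test_that("'equal' scaling matches the independent reference on many trees", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  trees <- c(ape::read.tree(text = "(A,B);"),
             do.call(c, lapply(3:5, function(n) phangorn::allTrees(n, rooted = TRUE))),
             ape::read.tree(text = "(t1,t2,t3,t4);"),
             ape::read.tree(text = "((t1,t2,t3),(t4,t5));"))
  for (phy in trees) {
    phy$edge.length <- NULL
    tips <- phy$tip.label
    ta <- setNames(round(runif(length(tips), 0, 40), 2), tips)
    ta[sample(length(ta), 1)] <- 0
    cons <- list()
    if (length(tips) >= 3 && runif(1) < 0.5) {
      pick <- sample(tips, 2)
      cons <- list(list(tips = pick, min_age = runif(1, 0, 50)))
    }
    ct <- time_scale_equal(phy, ta, cons, vartime = 1)
    ref_ages <- oracle_equal(ct$phy, ta, cons, vartime = 1)
    expect_equal(ct$ages, ref_ages, tolerance = 1e-10)
    ## invariants: positive durations, exact tip ages, constraints, root span
    expect_true(all(ct$phy$edge.length > 0))
    expect_equal(unname(tip_ages(ct)[tips]), unname(ta[tips]), tolerance = 1e-12)
    for (con in cons)
      expect_gte(node_ages(ct)[ct$phy$node.label[ape::getMRCA(ct$phy, con$tips) -
                                                  length(tips)]],
                 con$min_age - 1e-9)
    minima <- if (length(cons)) vapply(cons, `[[`, numeric(1), "min_age") else 0
    expect_equal(root_age(ct), max(c(ta, minima)) + 1, tolerance = 1e-12)
  }
})

test_that("tree-set ensembles honour their specification and reproduce exactly", {
  st <- simulate_study(seed = 3)
  spec <- timescale_spec("uniform", TRUE, n_replicates = 4, seed = 9)
  ts1 <- build_tree_set(st$topology, st$ranges, st$constraint_sets, spec)
  ts2 <- build_tree_set(st$topology, st$ranges, st$constraint_sets, spec)
  expect_length(ts1, 4)
  for (r in 1:4) {
    expect_identical(ts1[[r]]$ages, ts2[[r]]$ages)
    expect_identical(ape::write.tree(ts1[[r]]$phy), ape::write.tree(ts2[[r]]$phy))
    expect_true(ape::is.binary(ts1[[r]]$phy))
    ## constraint satisfaction for the drawn set
    ci <- attr(ts1[[r]], "constraint_set")
    for (con in st$constraint_sets[[ci]]) {
      nd <- ape::getMRCA(ts1[[r]]$phy, con$tips)
      expect_gte(ts1[[r]]$ages[nd], con$min_age - 1e-9)
    }
    ## tip ages inside their stratigraphic ranges
    ta <- tip_ages(ts1[[r]])[st$ranges$tip_id]
    expect_true(all(ta >= st$ranges$younger_bound - 1e-9 &
                    ta <= st$ranges$older_bound + 1e-9))
  }
  ## older-bound mode pins fossil tips exactly at the lower unit boundary
  spec1 <- timescale_spec("older_bound", TRUE, n_replicates = 1, seed = 2)
  ts3 <- build_tree_set(st$topology, st$ranges, list(), spec1)
  expect_equal(unname(tip_ages(ts3[[1]])[st$ranges$tip_id]),
               st$ranges$older_bound, tolerance = 1e-12)
  ## unresolved mode keeps the polytomies
  spec2 <- timescale_spec("uniform", FALSE, n_replicates = 1, seed = 2)
  ts4 <- build_tree_set(st$topology, st$ranges, list(), spec2)
  expect_equal(ts4[[1]]$phy$Nnode, st$topology$Nnode)
})

test_that("chrono trees round-trip through Newick plus tip ages", {
  st <- simulate_study(seed = 13)
  ct <- build_tree_set(st$topology, st$ranges, list(),
                       timescale_spec("uniform", TRUE, 1, seed = 4))[[1]]
  f <- tempfile(fileext = ".nwk")
  write_chrono_tree(ct, f)
  back <- read_chrono_tree(f, tip_ages(ct))
  expect_equal(sort(node_ages(back)), sort(node_ages(ct)), tolerance = 1e-9)
})
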