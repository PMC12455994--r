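# Topological distance, distance-length trend, tanglegram report.

test_that("worked split-distance examples", {
  t1 <- ape::read.tree(text = "((a,b),c,(d,e));")
  t2 <- ape::read.tree(text = "((a,c),b,(d,e));")
  expect_equal(topo_distance(t1, t1), 0)
  # one nearest-neighbour interchange on 5 taxa: distance 2
  expect_equal(topo_distance(t1, t2), 2)
  # star tree vs resolved: distance = number of resolved internal splits
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_equal(topo_distance(star, t1), 2)
  # scaling conventions
  expect_equal(topo_distance(t1, t2, scaling = "half"), 1)
  expect_equal(topo_distance(t1, t2, scaling = "double"), 4)
})

test_that("distance agrees with the graph oracle and ape on random trees", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(5:8, 1)
    ta <- ape::rtree(n, tip.label = paste0("t", 1:n))
    tb <- ape::rtree(n, tip.label = paste0("t", 1:n))
    d <- topo_distance(ta, tb)
    expect_equal(d, oracle_topo_distance(ta, tb), info = paste("rep", i))
    expect_equal(d, unname(ape::dist.topo(ape::unroot(ta),
                                          ape::unroot(tb),
                                          method = "PH85")[1]))
  }
})

test_that("distance is a metric on resolved topologies", {
  set.seed(42)
  for (i in 1:10) {
    trees <- lapply(1:3, function(k) ape::rtree(8, tip.label = paste0("t", 1:8)))
    d12 <- topo_distance(trees[[1]], trees[[2]])
    d21 <- topo_distance(trees[[2]], trees[[1]])
    d13 <- topo_distance(trees[[1]], trees[[3]])
    d23 <- topo_distance(trees[[2]], trees[[3]])
    expect_equal(d12, d21)
    expect_gte(d12 + d23, d13)  # triangle inequality
  }
  tr <- ape::rtree(8)
  expect_equal(topo_distance(tr, tr), 0)
})

test_that("distance ignores rooting and leaf order", {
  set.seed(43)
  ta <- ape::rtree(7, tip.label = paste0("t", 1:7))
  tb <- ape::rtree(7, tip.label = paste0("t", 1:7))
  d <- topo_distance(ta, tb)
  expect_equal(topo_distance(ape::root(ta, "t3", resolve.root = TRUE), tb), d)
  expect_equal(topo_distance(ape::rotateConstr(ta, sample(ta$tip.label)),
                             tb), d)
})

test_that("degenerate leaf sets are flagged", {
  ta <- ape::rtree(6, tip.label = paste0("a", 1:6))
  tb <- ape::rtree(6, tip.label = c(paste0("a", 1:3), paste0("b", 1:3)))
  expect_warning(d <- topo_distance(ta, tb), "shared")
  expect_true(is.na(d))
  tdup <- ta
  tdup$tip.label[2] <- "a1"
  expect_error(topo_distance(tdup, ta), "duplicate")
})

test_that("restriction to shared leaves happens before comparison", {
  ta <- ape::read.tree(text = "((a,b),(c,(d,e)),f);")
  tb <- ape::read.tree(text = "((a,b),(c,(d,x)),y);")
  d <- topo_distance(ta, tb)   # shared: a b c d (+ structure)
  shared <- intersect(ta$tip.label, tb$tip.label)
  expect_equal(d, oracle_topo_distance(ape::keep.tip(ta, shared),
                                       ape::keep.tip(tb, shared)))
})

test_that("distance-length trend and outlier flags behave", {
  rec <- data.frame(gene_id = paste0("g", 1:10),
                    mean_gene_length = seq(300, 1200, length.out = 10),
                    distance = c(8, 7, 9, 6, 5, 4, 3, 2, 1, 0))
  tr <- distance_vs_length(rec)
  expect_lt(tr$rho, -0.9)
  expect_lt(tr$p, 0.01)
  # constant distances: undefined trend
  rec$distance <- 4
  expect_warning(tr0 <- distance_vs_length(rec), "constant")
  expect_true(is.na(tr0$rho))
  # a band maximum is flagged as an outlier
  rec2 <- data.frame(gene_id = paste0("g", 1:8),
                     mean_gene_length = rep(1000, 8),
                     distance = c(rep(2, 7), 12))
  tr2 <- suppressWarnings(distance_vs_length(rec2))
  expect_true(tr2$records$outlier[8])
  expect_false(any(tr2$records$outlier[1:7]))
})

test_that("tanglegram orderings reach zero crossings on identical trees", {
  set.seed(44)
  sp <- ape::rtree(8, tip.label = paste0("t", 1:8))
  rep0 <- paired_tree_report(sp, sp)
  expect_equal(rep0$crossings, 0)
  expect_equal(sort(rep0$gene_order), sort(rep0$species_order))
  # disjoint leaf sets error
  gt <- ape::rtree(5, tip.label = paste0("x", 1:5))
  expect_error(paired_tree_report(sp, gt), "shared")
})

test_that("tanglegram heuristic is near the brute-force optimum", {
  # brute force: enumerate every child-order flip combination
  brute_min <- function(sp, gt) {
    ref <- stats::setNames(seq_along(sp$tip.label),
                           paired_tree_report(sp, sp)$species_order)
    n <- length(gt$tip.label)
    kids <- vector("list", max(gt$edge))
    for (i in seq_len(nrow(gt$edge)))
      kids[[gt$edge[i, 1]]] <- c(kids[[gt$edge[i, 1]]], gt$edge[i, 2])
    root <- setdiff(gt$edge[, 1], gt$edge[, 2])[1]
    orders <- function(node) {
      if (node <= n) return(list(node))
      subs <- lapply(kids[[node]], orders)
      out <- list()
      for (perm in list(seq_along(subs), rev(seq_along(subs)))) {
        combos <- Reduce(function(acc, s) {
          unlist(lapply(acc, function(a) lapply(s, function(x) c(a, x))),
                 recursive = FALSE)
        }, subs[perm], accumulate = FALSE,
        init = list(integer(0)))
        out <- c(out, combos)
      }
      unique(out)
    }
    all_orders <- orders(root)
    crossings <- vapply(all_orders, function(lv) {
      p <- ref[gt$tip.label[lv]]
      sum(vapply(seq_along(p), function(i) sum(p[seq_len(i - 1)] > p[i]),
                 numeric(1)))
    }, numeric(1))
    min(crossings)
  }
  set.seed(45)
  for (i in 1:5) {
    sp <- ape::rtree(7, tip.label = paste0("t", 1:7))
    gt <- phangorn::rSPR(sp, moves = 1)
    rep1 <- paired_tree_report(sp, gt)
    bm <- brute_min(sp, gt)
    expect_lte(rep1$crossings, max(2 * bm, bm))
    if (topo_distance(sp, gt) > 0) expect_gte(rep1$crossings, 0)
  }
})

test_that("tree_distances table merges gene lengths", {
  ts <- generate_tree_set(10, 12, hgt_rate = 0.5, seed = 8)
  td <- tree_distances(ts$species_tree, ts$gene_trees,
                       lengths = ts$records)
  expect_equal(nrow(td), 12)
  expect_true(all(c("distance", "mean_gene_length") %in% names(td)))
  expect_true(all(td$distance[ts$records$true_moves == 0] == 0))
})
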