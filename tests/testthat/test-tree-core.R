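test_that("read_newick parses minimal trees and preserves labels", {
  tr <- read_newick("(A:1,B:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 2)

  tr2 <- read_newick("((A:1,B:1)90:1,C:2);")
  expect_true("90" %in% tr2$node.label)

  tr3 <- read_newick("(('sp one':1,B:1):1,C:2);")
  expect_true("sp one" %in% tr3$tip.label)
})

test_that("malformed newick reports a character offset", {
  expect_error(read_newick("((A:1,B:2);"), "unclosed")
  expect_error(read_newick("(A:1,B:2));"), "offset 10")
  expect_error(read_newick("(A:1,'B:2);"), "unterminated quote.*offset 6")
})

test_that("newick round-trips through write_newick", {
  set.seed(42)
  for (i in 1:100) {
    tr <- random_noisy_tree(sample(4:15, 1))
    s <- write_newick(tr)
    tr2 <- read_newick(s)
    expect_equal(read_newick(write_newick(tr2)), tr2)
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)
    expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
  }
})

test_that("node ages and chronogram construction agree", {
  tr <- simulate_time_tree(10, 1500, seed = 7)
  ages <- node_ages(tr)
  expect_equal(ages[1:10], rep(0, 10), ignore_attr = TRUE)
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  expect_equal(ages[root], 1500)
  tr2 <- set_node_ages(tr, ages)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-10)
  bad <- ages
  bad[root] <- min(ages[tr$edge[, 2][tr$edge[, 1] == root]]) - 1
  expect_error(set_node_ages(tr, bad), "older")
})

test_that("mad_root solves clock trees exactly", {
  # perfect clock, internal branch length 2: root at its midpoint, mad 0
  res <- mad_root(read_newick("((A:1,B:1):2,(C:1,D:1):0);"))
  expect_equal(res$mad, 0, tolerance = 1e-12)
  expect_true(setequal(res$branch_tips, c("A", "B")) ||
                setequal(res$branch_tips, c("C", "D")))
  expect_equal(res$rho, 1, tolerance = 1e-9)
  expect_true(ape::is.ultrametric(res$tree, tol = 1e-8))

  # symmetric 2-cherry with internal branch 0.5: rho* = 0.25
  res2 <- mad_root(read_newick("((A:1,B:1):0.25,(C:1,D:1):0.25);"))
  expect_equal(res2$mad, 0, tolerance = 1e-12)
  expect_equal(res2$rho, 0.25, tolerance = 1e-9)

  # any clock tree: mad 0 and the rooted result is ultrametric
  for (seed in 1:5) {
    ct <- simulate_time_tree(8, 1, seed = seed)
    r <- mad_root(ct)
    expect_equal(r$mad, 0, tolerance = 1e-8)
    expect_true(ape::is.ultrametric(r$tree, tol = 1e-6))
  }
})

test_that("mad_root rejects degenerate input", {
  expect_error(mad_root(read_newick("(A:1,B:1);")), "3 tips")
  expect_error(mad_root(read_newick("((A:0,B:0):0,(C:0,D:0):0);")), "zero")
})

test_that("mad_root matches the exhaustive grid oracle", {
  set.seed(101)
  for (i in 1:12) {
    tr <- random_noisy_tree(8)
    got <- mad_root(tr)
    want <- mad_grid_oracle(tr, step = 1e-3)
    expect_lt(abs(got$mad - want$mad) / want$mad, 1e-3)
    expect_true(setequal(got$branch_tips, want$tips) ||
                  setequal(setdiff(tr$tip.label, got$branch_tips),
                           want$tips))
  }
})

test_that("mad_root is positive off-clock (mad = 0 iff clock about root)", {
  set.seed(3)
  tr <- random_noisy_tree(8)
  expect_gt(mad_root(tr)$mad, 1e-4)
})

test_that("find_monophyletic_clades recovers maximal shared-rank clades", {
  tr <- read_newick("(((a1:1,a2:1):1,a3:2):1,b1:3);")
  ann <- data.frame(tip_label = c("a1", "a2", "a3", "b1"),
                    genus = c("a", "a", "a", "b"))
  got <- find_monophyletic_clades(tr, ann, "genus")
  expect_equal(nrow(got), 2)
  big <- got[got$size == 3, ]
  expect_equal(big$value, "a")
  expect_setequal(big$tips[[1]], c("a1", "a2", "a3"))
  expect_error(find_monophyletic_clades(tr, ann, "phylum"), "absent")
})

test_that("interleaved groups give only singleton clades", {
  tr <- read_newick("(((x1:1,y1:1):1,x2:2):1,y2:3);")
  ann <- data.frame(tip_label = c("x1", "y1", "x2", "y2"),
                    genus = c("x", "y", "x", "y"))
  got <- find_monophyletic_clades(tr, ann, "genus")
  expect_true(all(got$size == 1))
  expect_equal(nrow(got), 4)
})

test_that("planted monophyletic blocks are recovered exactly", {
  set.seed(11)
  for (i in 1:20) {
    tr <- simulate_time_tree(16, 1)
    fx <- try(make_taxonomy_fixture(tr, block_sizes = c(4, 3)),
              silent = TRUE)
    if (inherits(fx, "try-error")) next  # tree lacks clades of those sizes
    got <- find_monophyletic_clades(tr, fx$annotations, "order")
    for (bl in fx$truth$blocks) {
      row <- got[got$value == bl$value, ]
      expect_equal(nrow(row), 1)
      expect_setequal(row$tips[[1]], bl$tips)
    }
    # oracle: every node's tip set scanned directly
    below <- relclock:::tips_below(tr)
    vals <- fx$annotations$order[match(tr$tip.label,
                                       fx$annotations$tip_label)]
    for (r in seq_len(nrow(got))) {
      tv <- vals[match(got$tips[[r]], tr$tip.label)]
      expect_length(unique(tv), 1)
    }
    # disjoint by maximality
    all_tips <- unlist(got$tips)
    expect_equal(anyDuplicated(all_tips), 0)
  }
})

find_clade_of_size <- function(tr, size, excluded = logical(0)) {
  below <- relclock:::tips_below(tr)
  ntip <- ape::Ntip(tr)
  for (v in (ntip + 1):(ntip + tr$Nnode)) {
    if (sum(below[[v]]) == size &&
        (!length(excluded) || !any(excluded[below[[v]]]))) {
      return(v)
    }
  }
  NA_integer_
}

test_that("subsample_clades keeps min(k, size) plus all background", {
  # seed chosen so the fixture tree contains a 4-tip clade
  tr <- NULL
  for (seed in 1:50) {
    cand <- simulate_time_tree(10, 1, seed = seed)
    if (!is.na(find_clade_of_size(cand, 4))) { tr <- cand; break }
  }
  expect_false(is.null(tr))
  below <- relclock:::tips_below(tr)
  v4 <- find_clade_of_size(tr, 4)
  clade <- list(tr$tip.label[below[[v4]]])
  kept2 <- subsample_clades(tr, clade, k = 2)
  expect_length(kept2, 10 - 4 + 2)
  expect_true(all(setdiff(tr$tip.label, clade[[1]]) %in% kept2))
  # k = 2 keeps the maximally divergent pair
  d <- ape::cophenetic.phylo(tr)[clade[[1]], clade[[1]]]
  pair <- intersect(kept2, clade[[1]])
  expect_equal(d[pair[1], pair[2]], max(d))
  # singleton clade survives any k
  expect_length(subsample_clades(tr, list(tr$tip.label[1]), k = 2), 10)
})

test_that("subsample_clades k=1 count oracle", {
  # search fixed seeds for a tree with disjoint clades of sizes 4 and 2
  tr <- NULL
  for (seed in 1:100) {
    cand <- simulate_time_tree(10, 1, seed = seed)
    v4c <- find_clade_of_size(cand, 4)
    if (is.na(v4c)) next
    bl <- relclock:::tips_below(cand)
    if (!is.na(find_clade_of_size(cand, 2, excluded = bl[[v4c]]))) {
      tr <- cand; break
    }
  }
  expect_false(is.null(tr))
  below <- relclock:::tips_below(tr)
  v4 <- find_clade_of_size(tr, 4)
  free <- !below[[v4]]
  v2 <- find_clade_of_size(tr, 2, excluded = below[[v4]])
  single <- tr$tip.label[which(free & !below[[v2]])[1]]
  clades <- list(tr$tip.label[below[[v4]]], tr$tip.label[below[[v2]]],
                 single)
  kept <- subsample_clades(tr, clades, k = 1)
  expect_length(kept, 3 + (10 - 4 - 2 - 1))
})

test_that("clade_composition labels majority clades maximally", {
  # 10-tip clade with 7 of one phylum: share 0.70 > 0.67
  nwk <- paste0("((", paste0("p", 1:7, ":1", collapse = ","),
                ",q1:1,q2:1,q3:1):1,out:2);")
  tr <- read_newick(nwk)
  ann <- data.frame(tip_label = tr$tip.label,
                    phylum = c(rep("P", 7), rep("Q", 3), "O"))
  got <- clade_composition(tr, ann, "phylum", threshold = 0.67)
  lab <- got[got$size == 10, ]
  expect_equal(lab$label, "P")
  expect_equal(lab$share, 0.7)

  # pure clade: share 1
  tr2 <- read_newick("((a1:1,a2:1):1,b:2);")
  ann2 <- data.frame(tip_label = c("a1", "a2", "b"),
                     phylum = c("A", "A", "B"))
  got2 <- clade_composition(tr2, ann2, "phylum")
  expect_true(any(got2$share == 1 & got2$label == "A" & got2$size == 2))
})

test_that("clade_composition maximality: parent below threshold wins child", {
  # parent share 0.60 (6 of 10), child share 0.75 (6 of 8)
  nwk <- paste0("(((", paste0("a", 1:6, ":1", collapse = ","),
                ",x1:1,x2:1):1,x3:1,x4:1):1,out:2);")
  tr <- read_newick(nwk)
  ann <- data.frame(tip_label = tr$tip.label,
                    phylum = c(rep("A", 6), rep("X", 4), "O"))
  got <- clade_composition(tr, ann, "phylum", threshold = 0.67)
  lab <- got[got$label == "A", ]
  expect_equal(lab$size, 8)
  expect_equal(lab$share, 0.75)
  # per-node oracle: no labeled clade's parent satisfies the rule
  parent <- relclock:::node_parents(tr)
  below <- relclock:::tips_below(tr)
  vals <- ann$phylum[match(tr$tip.label, ann$tip_label)]
  for (v in got$node) {
    p <- parent[v]
    if (is.na(p)) next
    shares <- table(vals[below[[p]]]) / sum(below[[p]])
    expect_lte(max(shares), 0.67)
  }
})
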