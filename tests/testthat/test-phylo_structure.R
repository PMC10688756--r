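test_that("patristic distances match hand computation and path sums", {
  d <- cophenetic_matrix(tiny_tree())
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))

  # ultrametric tree: max distance = 2 x depth
  tr <- simulate_tree(12, seed = 4)
  depth <- max(ape::node.depth.edgelength(tr))
  expect_equal(max(cophenetic_matrix(tr)), 2 * depth, tolerance = 1e-8)

  # random non-ultrametric tree against the brute-force path-sum oracle
  set.seed(8)
  tr2 <- ape::rtree(10)
  d2 <- cophenetic_matrix(tr2)
  expect_equal(d2, brute_cophenetic(tr2)[rownames(d2), colnames(d2)],
               tolerance = 1e-10)
})

test_that("phylogeny-weighted composition rows are compositional", {
  cm <- tiny_cm()
  tree <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  p <- phylo_weighted_composition(cm, tree)
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)

  # identical sites give identical rows
  inc <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0))
  colnames(inc) <- c("A", "B", "C", "D")
  cm2 <- community_matrix(inc, cbind(lon = c(-50, -51), lat = c(-20, -21)))
  p2 <- phylo_weighted_composition(cm2, tree)
  expect_equal(p2["s1", ], p2["s2", ])

  # star tree with equal branch lengths: every species pair equally
  # distant, so all present species carry equal weight and all absent
  # species carry equal (smaller) weight
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  p3 <- phylo_weighted_composition(cm, star)
  expect_equal(p3["s1", "A"], p3["s1", "B"])
  expect_equal(p3["s1", "C"], p3["s1", "D"])
  expect_gt(p3["s1", "A"], p3["s1", "C"])
})

test_that("PCoA recovers closed-form and Euclidean configurations", {
  # three mutually equidistant objects at dissimilarity 1: eigenvalues
  # 1/2, 1/2, 0 and two axes of 50% each
  d <- matrix(1, 3, 3) - diag(3)
  res <- pcoa_axes(stats::as.dist(d))
  expect_equal(res$eigenvalues, c(0.5, 0.5, 0), tolerance = 1e-10)
  expect_equal(res$fraction_of_variation, c(0.5, 0.5), tolerance = 1e-10)

  # exact distances of a random Euclidean configuration are reproduced
  # among the axis scores
  set.seed(21)
  x <- matrix(rnorm(8 * 3), 8, 3)
  res2 <- pcoa_axes(dist(x))
  expect_equal(as.matrix(dist(res2$scores)), as.matrix(dist(x)),
               tolerance = 1e-8)

  # axis scores are orthogonal with squared norms equal to eigenvalues
  g <- unname(crossprod(res2$scores))
  expect_equal(g, diag(diag(g)), tolerance = 1e-8)
})

test_that("PCPS separates clade-segregated communities on axis 1", {
  # two deeply split clades; sites drawn from one clade or the other
  tree <- ape::read.tree(text = paste0(
    "((a1:1,(a2:0.5,a3:0.5):0.5):9,(b1:1,(b2:0.5,b3:0.5):0.5):9);"))
  inc <- rbind(x1 = c(1, 1, 0, 0, 0, 0), x2 = c(1, 0, 1, 0, 0, 0),
               x3 = c(0, 1, 1, 0, 0, 0), y1 = c(0, 0, 0, 1, 1, 0),
               y2 = c(0, 0, 0, 1, 0, 1), y3 = c(0, 0, 0, 0, 1, 1))
  colnames(inc) <- tree$tip.label
  cm <- community_matrix(inc, cbind(lon = runif(6, -55, -35),
                                    lat = runif(6, -30, -5)))
  res <- pcps(cm, tree)
  a <- res$scores[c("x1", "x2", "x3"), "PCPS1"]
  b <- res$scores[c("y1", "y2", "y3"), "PCPS1"]
  expect_true(max(a) < min(b) || max(b) < min(a))
  expect_true(all(diff(res$eigenvalues) <= 1e-12))

  # duplicated sites get coincident scores
  inc2 <- rbind(inc, x1b = inc["x1", ])
  cm2 <- community_matrix(inc2, cbind(lon = runif(7, -55, -35),
                                      lat = runif(7, -30, -5)))
  res2 <- pcps(cm2, tree)
  expect_equal(res2$scores["x1", ], res2$scores["x1b", ], tolerance = 1e-8)
})

test_that("MDCC insertion is ultrametric within the clade and invertible", {
  tr <- tiny_tree()
  tr2 <- add_taxon_at_mdcc(tr, "X", c("A", "B"))
  expect_equal(ape::Ntip(tr2), 4L)
  d <- cophenetic_matrix(tr2)
  expect_equal(d["X", "A"], 2)
  expect_equal(d["X", "C"], 4)

  # pruning the inserted tip recovers all original distances
  d0 <- cophenetic_matrix(ape::drop.tip(tr2, "X"))
  expect_equal(d0, cophenetic_matrix(tr)[rownames(d0), colnames(d0)])

  expect_error(add_taxon_at_mdcc(tr, "A", c("A", "B")), "already present")
  tr4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  expect_error(add_taxon_at_mdcc(tr4, "X", c("A", "C")),
               "not monophyletic")
})

test_that("repeated insertions grow the tip count as expected", {
  tr <- simulate_tree(20, seed = 6)
  for (i in 1:4) {
    clade <- attr(assign_direct_development(tr, 0.2, 1L, seed = i),
                  "clades")[[1]]
    tr <- add_taxon_at_mdcc(tr, paste0("put", i), clade)
  }
  expect_equal(ape::Ntip(tr), 24L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
})
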