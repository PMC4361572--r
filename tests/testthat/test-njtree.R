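test_that("two- and three-taxon trees follow the closed forms", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  t2 <- njBuild(d2)
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(t2$edge.length, c(0.2, 0.2))
  expect_equal(sum(t2$edge.length), 0.4)  # pendant sum equals d exactly

  d3 <- matrix(0, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  d3["A", "B"] <- 0.3; d3["A", "C"] <- 0.5; d3["B", "C"] <- 0.6
  d3 <- d3 + t(d3)
  t3 <- njBuild(d3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[["A"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(lens[["B"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(lens[["C"]], (0.5 + 0.6 - 0.3) / 2)
  expect_error(njBuild(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("the four-taxon additive matrix recovers its generating tree", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- njBuild(d)
  # path lengths on the reconstructed tree must reproduce the matrix
  expect_equal(unname(as.matrix(stats::cophenetic(tr))[LETTERS[1:4],
                                                       LETTERS[1:4]]),
               unname(d), tolerance = 1e-12)
  # AB|CD split present with internal branch 1
  pend <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                   tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 4]])
  expect_equal(pend[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(internal, 1)
})

test_that("neighbor joining is consistent on additive matrices", {
  for (case in 1:25) {
    n <- sample(4:12, 1)
    truth <- randAdditiveTree(n, seed = 3000 + case)
    d <- as.matrix(stats::cophenetic(truth))
    tr <- njBuild(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(truth), tr)), 0)
    # all pairwise path lengths reproduced => branch lengths recovered
    expect_equal(as.matrix(stats::cophenetic(tr))[rownames(d), rownames(d)],
                 d, tolerance = 1e-9)
    # independent implementation agrees on the topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(d), tr)), 0)
  }
})

test_that("tie-breaking is deterministic and leaf order does not change splits", {
  aln <- randAln(8, 60, seed = 42)
  d <- distValues(distanceMatrix(aln))
  t1 <- njBuild(d)
  t2 <- njBuild(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  perm <- c(5, 3, 8, 1, 7, 2, 6, 4)
  t3 <- njBuild(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(t1, t3)), 0)
  # fully tied matrix still resolves, reproducibly
  dt <- matrix(0.5, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  diag(dt) <- 0
  expect_identical(ape::write.tree(njBuild(dt)),
                   ape::write.tree(njBuild(dt)))
})

test_that("negative branch estimates clamp to zero by default", {
  # strongly non-additive matrix provokes negative pendant estimates
  d <- matrix(c(0, 0.1, 0.6, 0.55,
                0.1, 0, 0.62, 0.6,
                0.6, 0.62, 0, 0.02,
                0.55, 0.6, 0.02, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  kept <- njBuild(d, negativeBranchPolicy = "keep")
  clamped <- njBuild(d, negativeBranchPolicy = "clamp")
  expect_true(all(clamped$edge.length >= 0))
  expect_equal(pmax(kept$edge.length, 0), clamped$edge.length,
               tolerance = 1e-12)
})

test_that("bootstrap gives full support to an unambiguous block split", {
  set.seed(808)
  base1 <- paste(AA[sample.int(20, 200, TRUE)], collapse = "")
  ch <- strsplit(base1, "")[[1]]
  flip <- sample(200, 100)
  ch[flip] <- AA[(match(ch[flip], AA) + 9) %% 20 + 1]
  base2 <- paste(ch, collapse = "")
  seqs <- c(setNames(rep(base1, 5), paste0("L", 1:5)),
            setNames(rep(base2, 5), paste0("R", 1:5)))
  aln <- alnFrom(seqs)
  tr <- bootstrapSupport(aln, nReps = 100, seed = 9)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the L|R bipartition: find the node whose clade is exactly one block
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  ntip <- 10
  blockNode <- which(vapply(seq_along(pp), function(i) {
    tips <- sort(labs[pp[[i]]])
    identical(tips, paste0("L", 1:5)) || identical(tips, paste0("R", 1:5))
  }, logical(1)))
  expect_true(length(blockNode) >= 1)
  expect_true(all(sup[blockNode] == 100))
})

test_that("bootstrap supports are reproducible under the same seed", {
  aln <- randAln(7, 80, seed = 33)
  t1 <- bootstrapSupport(aln, nReps = 30, seed = 4)
  t2 <- bootstrapSupport(aln, nReps = 30, seed = 4)
  expect_identical(t1$node.label, t2$node.label)
  expect_error(bootstrapSupport(aln, nReps = 0, seed = 1), "nReps")
})

test_that("column permutation leaves the point-estimate tree unchanged", {
  aln <- randAln(7, 80, seed = 12)
  m <- as.matrix(alignedSeqs(aln))
  perm <- sample(ncol(m))
  seqs2 <- setNames(apply(m[, perm], 1, paste, collapse = ""), rownames(m))
  t1 <- njBuild(distanceMatrix(aln))
  t2 <- njBuild(distanceMatrix(alnFrom(seqs2)))
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("Newick serialization writes 6-decimal lengths and round-trips", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  path <- tempfile(fileext = ".nwk")
  writeNewickTree(njBuild(d2), path)
  expect_equal(readLines(path), "(A:0.200000,B:0.200000);")

  aln <- randAln(8, 100, seed = 3)
  tr <- bootstrapSupport(aln, nReps = 20, seed = 5)
  writeNewickTree(tr, path)
  back <- readNewickTree(path)
  expect_equal(as.numeric(ape::dist.topo(tr, back)), 0)
  expect_equal(sort(back$edge.length), sort(round(tr$edge.length, 6)),
               tolerance = 1e-9)
  expect_setequal(back$node.label[-1], tr$node.label[-1])
  # a known support value appears as an internal node label
  expect_true(any(grepl(paste0(")", tr$node.label[2], ":"),
                        readLines(path), fixed = TRUE)))

  bad <- tempfile()
  writeLines("((A:1,B:1;", bad)
  expect_error(readNewickTree(bad), "parse error")
})

test_that("bifurcation counts follow the rooted path-depth definition", {
  d3 <- matrix(0.4, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(d3) <- 0
  expect_equal(countBifurcations(njBuild(d3), "A", rooting = "lastjoin"), 1L)

  # perfectly balanced 8-leaf tree: depth 3 from the midpoint root
  bal <- ape::read.tree(text = paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);"))
  for (leaf in LETTERS[1:8])
    expect_equal(countBifurcations(bal, leaf, rooting = "midpoint"), 3L)
  expect_error(countBifurcations(bal, "Z"), "unknown leaf")
})

test_that("bifurcation counts match an independent parent-walk oracle", {
  tr <- randAdditiveTree(20, seed = 77)
  rt <- phangorn::midpoint(tr)
  ntip <- length(rt$tip.label)
  parent <- integer(max(rt$edge))
  parent[rt$edge[, 2]] <- rt$edge[, 1]
  for (leaf in sample(rt$tip.label, 8)) {
    nd <- match(leaf, rt$tip.label)
    count <- 0L
    while (parent[nd] != 0) {
      nd <- parent[nd]
      count <- count + 1L
    }
    expect_equal(countBifurcations(tr, leaf, rooting = "midpoint"), count)
  }
})
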