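# neighbor joining, bootstrap clade support, Newick I/O, tree queries

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: iteratively join the pair
#' minimizing `Q(i,j) = (r-2) d(i,j) - R(i) - R(j)` (`R` = row sum, `r` =
#' current taxa count), with pendant branches
#' `v_i = d(i,j)/2 + (R(i)-R(j)) / (2(r-2))` and reduced distances
#' `d(u,k) = (d(i,k)+d(j,k)-d(i,j))/2`. Ties in the Q minimization are
#' broken deterministically by the lexicographically smallest pair in
#' current label order, so results are reproducible across platforms.
#' Consistent on additive matrices: recovers the generating topology and
#' branch lengths exactly.
#'
#' @param dm a [PDistanceMatrix-class] or labeled symmetric matrix, n >= 2.
#' @param negativeBranchPolicy `"clamp"` (default) truncates negative
#'   branch-length estimates at zero; `"keep"` preserves raw values.
#' @return an unrooted `ape::phylo` (basal trichotomy for n >= 3; a single
#'   split edge for n = 2).
#' @export
njBuild <- function(dm, negativeBranchPolicy = c("clamp", "keep")) {
  negativeBranchPolicy <- match.arg(negativeBranchPolicy)
  d <- if (methods::is(dm, "PDistanceMatrix")) distValues(dm) else dm
  n <- nrow(d)
  if (is.null(n) || n < 2)
    stop("input error: need at least 2 taxa")
  if (anyNA(d))
    stop("input error: distance matrix contains undefined entries")
  labs <- rownames(d)
  clamp <- function(x) if (negativeBranchPolicy == "clamp") pmax(x, 0) else x
  blen <- function(x) sprintf("%.17g", x)
  if (n == 2) {
    h <- clamp(d[1, 2] / 2)
    nwk <- paste0("(", labs[1], ":", blen(h), ",", labs[2], ":", blen(h),
                  ");")
    return(ape::read.tree(text = nwk))
  }
  sub <- labs                 # Newick substring per active node
  D <- d
  while (length(sub) > 3) {
    r <- length(sub)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    vi <- clamp(vi); vj <- clamp(vj)
    newSub <- paste0("(", sub[i], ":", blen(vi), ",", sub[j], ":",
                     blen(vj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    D <- D2
    sub <- c(sub[keep], newSub)
  }
  # final three-way join (unrooted star at the last internal node)
  v <- c((D[1, 2] + D[1, 3] - D[2, 3]) / 2,
         (D[1, 2] + D[2, 3] - D[1, 3]) / 2,
         (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  v <- clamp(v)
  nwk <- paste0("(", sub[1], ":", blen(v[1]), ",", sub[2], ":", blen(v[2]),
                ",", sub[3], ":", blen(v[3]), ");")
  ape::read.tree(text = nwk)
}

# canonical bipartition keys for every non-root internal node.
# key = sorted tip labels of the side NOT containing the overall smallest
# label, so the key is invariant to which side of the split is stored.
.bipartitionKeys <- function(tree) {
  ntip <- length(tree$tip.label)
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  anchor <- min(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  root <- ntip + 1L
  nodes <- (ntip + 2L):(ntip + tree$Nnode)
  keys <- vapply(nodes, function(nd) {
    tips <- labels[pp[[nd - ntip]]]
    if (anchor %in% tips) tips <- setdiff(labels, tips)
    paste(sort(tips), collapse = "|")
  }, "")
  names(keys) <- as.character(nodes)
  keys
}

#' Bootstrap clade support for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes the distance
#' matrix and NJ tree per replicate, and annotates each internal edge of
#' the point-estimate tree with the percentage of replicates containing
#' the same bipartition. Replicate `r` draws from a deterministic stream
#' derived from `(seed, r)`, so seeded runs are reproducible and partial
#' re-runs agree.
#'
#' @param x a [TaxAlignment-class].
#' @param policy gap-deletion policy passed to [distanceMatrix()].
#' @param nReps number of bootstrap replicates (>= 1).
#' @param seed master integer seed.
#' @param negativeBranchPolicy passed to [njBuild()].
#' @return the point-estimate `phylo` with supports (0..100) in
#'   `node.label` (root label empty).
#' @export
bootstrapSupport <- function(x, policy = "pairwise", nReps = 100, seed = 1,
                             negativeBranchPolicy = "clamp") {
  if (nReps < 1)
    stop("input error: nReps must be >= 1")
  enc <- .encodeAlignment(alignedSeqs(x))
  point <- njBuild(distanceMatrix(x, policy), negativeBranchPolicy)
  keys <- .bipartitionKeys(point)
  counts <- stats::setNames(numeric(length(keys)), keys)
  L <- ncol(enc)
  njFromEnc <- function(e) {
    res <- .pdistFromEncoded(e, policy)
    d <- res$d
    dimnames(d) <- list(rownames(enc), rownames(enc))
    if (anyNA(d)) return(NULL)
    njBuild(d, negativeBranchPolicy)
  }
  for (r in seq_len(nReps)) {
    set.seed(.substream(seed, "bootstrap", r))
    cols <- sample.int(L, L, replace = TRUE)
    bt <- njFromEnc(enc[, cols, drop = FALSE])
    if (is.null(bt)) next
    bk <- .bipartitionKeys(bt)
    hit <- keys %in% bk
    counts[hit] <- counts[hit] + 1
  }
  support <- round(100 * counts / nReps, 1)
  point$node.label <- c("", as.character(support))
  point
}

#' Write / read a tree in Newick format
#'
#' Serializes branch lengths with 6 decimals and bootstrap supports as
#' internal node labels; `readNewickTree(writeNewickTree(t))` reproduces
#' topology, lengths (to the written precision) and supports.
#'
#' @param tree an `ape::phylo`.
#' @param path file path.
#' @return `writeNewickTree`: the path, invisibly. `readNewickTree`: a
#'   `phylo`.
#' @export
writeNewickTree <- function(tree, path) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- tree$edge.length
  edgeOf <- stats::setNames(seq_len(nrow(tree$edge)), tree$edge[, 2])
  lab <- function(nd) {
    if (nd <= ntip) return(tree$tip.label[nd])
    nl <- tree$node.label[nd - ntip]
    if (is.null(nl) || is.na(nl)) "" else nl
  }
  rec <- function(nd) {
    core <- if (nd <= ntip) lab(nd) else
      paste0("(", paste(vapply(kids[[as.character(nd)]], rec, ""),
                        collapse = ","), ")", lab(nd))
    e <- edgeOf[as.character(nd)]
    if (is.na(e)) core else paste0(core, ":", sprintf("%.6f", elen[e]))
  }
  root <- ntip + 1L
  writeLines(paste0(rec(root), ";"), path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  tr <- tryCatch(ape::read.tree(path), error = function(e) e,
                 warning = function(w) w)
  if (!inherits(tr, "phylo") || is.null(tr))
    stop("parse error: malformed Newick in ", path,
         if (inherits(tr, "condition")) paste0(" (", conditionMessage(tr), ")"))
  tr
}

#' Count bifurcations on the root-to-leaf path
#'
#' Number of internal nodes on the unique path from the display root to a
#' leaf (root included, leaf excluded) — used as a proxy for the number of
#' evolutionary steps a sequence has undergone in the displayed tree. The
#' count depends on the rooting, which is therefore an explicit policy.
#'
#' @param tree an `ape::phylo` with >= 3 leaves.
#' @param leaf a tip label.
#' @param rooting `"midpoint"` (default; roots at the midpoint of the
#'   longest tip-to-tip path via [phangorn::midpoint()]) or `"lastjoin"`
#'   (uses the tree as stored, rooted at its basal node).
#' @return integer bifurcation count.
#' @export
countBifurcations <- function(tree, leaf, rooting = c("midpoint",
                                                      "lastjoin")) {
  rooting <- match.arg(rooting)
  if (!(leaf %in% tree$tip.label))
    stop("input error: unknown leaf '", leaf, "'")
  if (length(tree$tip.label) < 3)
    stop("input error: need at least 3 leaves")
  rt <- if (rooting == "midpoint") phangorn::midpoint(tree) else tree
  ntip <- length(rt$tip.label)
  tip <- match(leaf, rt$tip.label)
  path <- ape::nodepath(rt, from = ntip + 1L, to = tip)
  sum(path > ntip)
}
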