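# pairwise p-distances, per-taxon distance statistics, identity, group test

#' p-distance between two aligned sequences
#'
#' Proportion of differing sites among compared sites. Under pairwise
#' deletion a column is compared when both symbols are standard residues
#' (gaps and `X` excluded); under complete deletion a precomputed gap-free
#' column mask defines the compared columns.
#'
#' @param a,b aligned residue strings of equal length.
#' @param policy `"pairwise"` (default) or `"complete"`.
#' @param completeMask logical column mask (required for `"complete"`).
#' @return `list(d, sites)`; `d` is `NA` when `sites == 0` (undefined
#'   distance).
#' @examples
#' pDistance("ACDEF", "ACDEY")  # 1 difference / 5 sites
#' pDistance("AC-EF", "ACDEF")  # gap column excluded
#' @export
pDistance <- function(a, b, policy = c("pairwise", "complete"),
                      completeMask = NULL) {
  policy <- match.arg(policy)
  if (nchar(a) != nchar(b))
    stop("alignment error: sequences differ in length")
  ca <- match(strsplit(a, "")[[1]], AA20)
  cb <- match(strsplit(b, "")[[1]], AA20)
  if (policy == "complete") {
    if (is.null(completeMask))
      stop("input error: complete deletion requires a column mask")
    use <- completeMask
  } else {
    use <- !is.na(ca) & !is.na(cb)
  }
  sites <- sum(use)
  if (sites == 0)
    return(list(d = NA_real_, sites = 0L))
  list(d = sum(ca[use] != cb[use]) / sites, sites = as.integer(sites))
}

# pairwise mismatch counting over an encoded alignment via one-hot
# cross-products: matches = sum_s X_s X_s', valid = cross-product of
# non-NA indicators.
.pdistFromEncoded <- function(enc, policy) {
  if (policy == "complete") {
    keep <- colSums(is.na(enc)) == 0
    enc <- enc[, keep, drop = FALSE]
  }
  n <- nrow(enc)
  valid <- (!is.na(enc)) * 1
  V <- tcrossprod(valid)
  M <- matrix(0, n, n)
  encZ <- enc
  encZ[is.na(encZ)] <- 0L
  for (s in seq_len(20)) {
    Xs <- (encZ == s) * 1
    if (any(Xs > 0)) M <- M + tcrossprod(Xs)
  }
  D <- (V - M) / V            # NaN where V == 0
  D[V == 0] <- NA_real_
  diag(D) <- 0
  list(d = D, sites = matrix(as.integer(V), n, n))
}

#' Pairwise p-distance matrix
#'
#' Computes all pairwise p-distances of an alignment under the chosen
#' gap-deletion policy.
#'
#' @param x a [TaxAlignment-class] (>= 2 records).
#' @param policy `"pairwise"` (default) or `"complete"` deletion.
#' @param onUndefined `"error"` (default) aborts listing pairs with zero
#'   comparable sites; `"flag"` stores them as `NA`.
#' @return a [PDistanceMatrix-class].
#' @export
distanceMatrix <- function(x, policy = c("pairwise", "complete"),
                           onUndefined = c("error", "flag")) {
  policy <- match.arg(policy)
  onUndefined <- match.arg(onUndefined)
  if (length(x) < 2)
    stop("input error: need at least 2 records for a distance matrix")
  enc <- .encodeAlignment(alignedSeqs(x))
  res <- .pdistFromEncoded(enc, policy)
  und <- is.na(res$d) & upper.tri(res$d)
  if (any(und) && onUndefined == "error") {
    idx <- which(und, arr.ind = TRUE)
    pairs <- apply(utils::head(idx, 10), 1, function(r)
      paste0(accessions(x)[r[1]], "~", accessions(x)[r[2]]))
    stop("undefined distance (0 comparable sites) for pair(s): ",
         paste(pairs, collapse = ", "))
  }
  methods::new("PDistanceMatrix", labels = accessions(x), d = res$d,
               sites = res$sites, deletionPolicy = policy)
}

#' Percent identity of a pairwise alignment
#'
#' `100 *` (columns with identical standard residues) `/` (total alignment
#' columns). The denominator is the full alignment length including gap
#' columns; columns where either symbol is a gap or `X` never count as
#' identical.
#'
#' @param a,b aligned residue strings of equal, positive length.
#' @return identity percentage.
#' @examples
#' percentIdentity("AAAA", "AAAT")  # 75
#' @export
percentIdentity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("alignment error: sequences differ in length")
  if (nchar(a) == 0)
    stop("input error: zero alignment columns")
  ca <- match(strsplit(a, "")[[1]], AA20)
  cb <- match(strsplit(b, "")[[1]], AA20)
  ident <- !is.na(ca) & !is.na(cb) & ca == cb
  100 * sum(ident) / length(ca)
}

# per-sequence mean distance to the other members of a set (rows idx)
.perSeqMeans <- function(d, idx) {
  if (length(idx) < 2) return(rep(NA_real_, length(idx)))
  sub <- d[idx, idx, drop = FALSE]
  (rowSums(sub, na.rm = TRUE)) / (length(idx) - 1)
}

#' Per-taxon p-distance statistics at a rank
#'
#' For every distinct taxon at the requested rank (full-path keys), report
#' the number of member sequences and the mean/SD of p-distance. Under the
#' default `per-sequence-mean` policy the observation unit is each member
#' sequence's mean distance to all other members of the taxon (singletons
#' report `NA`); under `all-pairs` the statistics are over all within-taxon
#' pairwise distances. The special rank `"all"` yields the global statistic
#' over each sequence's mean distance to all other sequences.
#'
#' @param dm a [PDistanceMatrix-class].
#' @param lineages a lineage `data.frame` (or `TaxAlignment` taxonomy)
#'   covering every matrix label.
#' @param rank one of `"all"`, `"kingdom"`, ..., `"genus"`, `"organism"`.
#' @param unitPolicy `"per-sequence-mean"` (default) or `"all-pairs"`.
#' @return a `data.frame` with columns `rank`, `taxon` (full path), `n`,
#'   `mean`, `sd`, `unit_policy`.
#' @export
groupDistanceTable <- function(dm, lineages,
                               rank = "all",
                               unitPolicy = c("per-sequence-mean",
                                              "all-pairs")) {
  unitPolicy <- match.arg(unitPolicy)
  if (methods::is(lineages, "TaxAlignment"))
    lineages <- as.data.frame(taxonomy(lineages))
  lineages <- as.data.frame(lineages)
  if (!(rank %in% c("all", TAX_RANKS)))
    stop("input error: unknown rank '", rank, "'")
  d <- distValues(dm)
  labs <- distLabels(dm)
  li <- match(labs, lineages$accession)
  if (anyNA(li))
    stop("input error: lineage missing for ",
         paste(utils::head(labs[is.na(li)], 5), collapse = ", "))
  lin <- lineages[li, , drop = FALSE]
  key <- if (rank == "all") rep("all", length(labs)) else
    .taxonPaths(lin, match(rank, TAX_RANKS))
  groups <- split(seq_along(labs), key)
  groups <- groups[order(names(groups))]
  rows <- lapply(names(groups), function(tx) {
    idx <- groups[[tx]]
    n <- length(idx)
    if (unitPolicy == "per-sequence-mean") {
      obs <- .perSeqMeans(d, idx)
      data.frame(rank = rank, taxon = tx, n = n,
                 mean = if (n > 1) mean(obs) else NA_real_,
                 sd = if (n > 2) stats::sd(obs) else
                   if (n == 2) stats::sd(obs) else NA_real_,
                 unit_policy = unitPolicy, stringsAsFactors = FALSE)
    } else {
      sub <- d[idx, idx, drop = FALSE]
      pairs <- sub[upper.tri(sub)]
      data.frame(rank = rank, taxon = tx, n = n,
                 mean = if (n > 1) mean(pairs, na.rm = TRUE) else NA_real_,
                 sd = if (n > 2 || n == 2) {
                   if (length(pairs) > 1) stats::sd(pairs) else NA_real_
                 } else NA_real_,
                 unit_policy = unitPolicy, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom,
#' two-sided. Thin wrapper over [stats::t.test()] with input validation.
#'
#' @param x,y numeric observation vectors, each of length >= 2.
#' @return `list(t, df, p)`.
#' @export
welchTTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("input error: each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    stop("input error: both groups have zero variance")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Write / read a square PHYLIP distance matrix
#'
#' Plain-text square PHYLIP format: first line is the sequence count, each
#' following line a label followed by the full distance row.
#'
#' @param dm a [PDistanceMatrix-class] (or labeled symmetric matrix).
#' @param path file path.
#' @return `writePhylipDist`: the path, invisibly. `readPhylipDist`: a
#'   labeled symmetric numeric matrix.
#' @export
writePhylipDist <- function(dm, path) {
  d <- if (methods::is(dm, "PDistanceMatrix")) distValues(dm) else dm
  labs <- rownames(d)
  pad <- max(10L, max(nchar(labs)) + 2L)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste0(formatC(labs[i], width = -pad),
                      paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writePhylipDist
#' @export
readPhylipDist <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 1)
    stop("parse error: malformed PHYLIP distance file ", path)
  toks <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  labs <- vapply(toks, `[`, "", 1)
  d <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  d
}
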