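#' TaxAlignment: an aligned protein family with per-record taxonomy
#'
#' Container coupling an aligned amino-acid sequence set
#' ([Biostrings::AAStringSet], equal widths, gap character `-`) with a
#' per-record taxonomy table carrying the seven-rank lineage
#' (kingdom, phylum, class, order, family, genus, organism), a fragment
#' flag, and a completeness flag. Lineage fields may be `NA` until a
#' lineage table has been bound with [bindTaxonomy()].
#'
#' @slot seqs an `AAStringSet` of aligned sequences; names are accessions.
#' @slot taxonomy a [S4Vectors::DataFrame] with one row per sequence and
#'   columns `accession`, the seven rank columns, `fragment` (logical) and
#'   `complete` (logical).
#'
#' @seealso [readAlignmentFasta()], [bindTaxonomy()], [rankSummary()]
#' @export
setClass("TaxAlignment",
  representation(seqs = "AAStringSet", taxonomy = "DataFrame"))

setValidity("TaxAlignment", function(object) {
  msgs <- character()
  w <- Biostrings::width(object@seqs)
  if (length(w) > 0 && length(unique(w)) != 1)
    msgs <- c(msgs, "alignment error: sequences have ragged lengths")
  need <- c("accession", TAX_RANKS, "fragment", "complete")
  if (!all(need %in% colnames(object@taxonomy)))
    msgs <- c(msgs, paste("taxonomy is missing columns:",
                          paste(setdiff(need, colnames(object@taxonomy)),
                                collapse = ", ")))
  if (nrow(object@taxonomy) != length(object@seqs))
    msgs <- c(msgs, "taxonomy row count does not match sequence count")
  else if (length(object@seqs) &&
           !identical(as.character(object@taxonomy$accession),
                      names(object@seqs)))
    msgs <- c(msgs, "taxonomy accessions do not match sequence names")
  if (length(msgs)) msgs else TRUE
})

# empty taxonomy frame for a set of accessions
.emptyTaxonomy <- function(accessions) {
  df <- S4Vectors::DataFrame(accession = accessions)
  for (r in TAX_RANKS) df[[r]] <- rep(NA_character_, length(accessions))
  df$fragment <- rep(NA, length(accessions))
  df$complete <- rep(NA, length(accessions))
  df
}

#' Construct a TaxAlignment
#'
#' @param seqs an `AAStringSet` (or named character vector) of aligned
#'   sequences; names are used as accessions.
#' @param taxonomy optional per-record taxonomy `DataFrame`/`data.frame`;
#'   when omitted an all-`NA` taxonomy is attached.
#' @return a [TaxAlignment-class] object.
#' @export
TaxAlignment <- function(seqs, taxonomy = NULL) {
  if (!methods::is(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs)))
    stop("input error: sequences must be named with accessions")
  if (is.null(taxonomy)) taxonomy <- .emptyTaxonomy(names(seqs))
  if (!methods::is(taxonomy, "DataFrame"))
    taxonomy <- S4Vectors::DataFrame(taxonomy)
  methods::new("TaxAlignment", seqs = seqs, taxonomy = taxonomy)
}

#' @describeIn TaxAlignment-class number of records
#' @param x a `TaxAlignment`
#' @export
setMethod("length", "TaxAlignment", function(x) length(x@seqs))

#' Accessors for TaxAlignment
#'
#' `alignedSeqs()` returns the `AAStringSet`; `taxonomy()` the per-record
#' taxonomy `DataFrame`; `accessions()` the accession vector;
#' `nColumns()` the common alignment width.
#'
#' @param x a [TaxAlignment-class]
#' @return see individual descriptions.
#' @export
alignedSeqs <- function(x) x@seqs

#' @rdname alignedSeqs
#' @export
taxonomy <- function(x) x@taxonomy

#' @rdname alignedSeqs
#' @export
accessions <- function(x) names(x@seqs)

#' @rdname alignedSeqs
#' @export
nColumns <- function(x) {
  if (length(x@seqs) == 0) 0L else unique(Biostrings::width(x@seqs))[1]
}

#' @describeIn TaxAlignment-class subset records by index, logical mask or
#'   accession
#' @param i subscript
#' @param j,drop,... ignored
#' @export
setMethod("[", "TaxAlignment", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  methods::new("TaxAlignment", seqs = x@seqs[i],
               taxonomy = x@taxonomy[i, , drop = FALSE])
})

setMethod("show", "TaxAlignment", function(object) {
  nc <- if (length(object)) nColumns(object) else 0L
  cat("TaxAlignment with", length(object), "sequences x", nc, "columns\n")
  tx <- object@taxonomy
  ncomp <- sum(tx$complete %in% TRUE)
  cat("  complete lineages:", ncomp,
      " fragments:", sum(tx$fragment %in% TRUE), "\n")
  if (length(object)) {
    shown <- utils::head(names(object@seqs), 4)
    cat("  accessions:", paste(shown, collapse = ", "),
        if (length(object) > 4) "..." else "", "\n")
  }
})

#' PDistanceMatrix: pairwise p-distances with per-pair site counts
#'
#' Symmetric labeled matrix of uncorrected p-distances in `[0, 1]` together
#' with, for every pair, the number of alignment columns actually compared
#' under the gap-deletion policy. Entries whose comparable-site count is
#' zero are undefined and stored as `NA` (permissive mode only).
#'
#' @slot labels accession vector (row/column order).
#' @slot d symmetric numeric matrix of p-distances.
#' @slot sites symmetric integer matrix of compared-site counts.
#' @slot deletionPolicy `"pairwise"` or `"complete"`.
#' @seealso [distanceMatrix()], [pDistance()]
#' @export
setClass("PDistanceMatrix",
  representation(labels = "character", d = "matrix", sites = "matrix",
                 deletionPolicy = "character"))

setValidity("PDistanceMatrix", function(object) {
  msgs <- character()
  n <- length(object@labels)
  if (!all(dim(object@d) == c(n, n)) || !all(dim(object@sites) == c(n, n)))
    msgs <- c(msgs, "matrix dimensions do not match label count")
  dd <- object@d
  if (any(abs(dd - t(dd)) > 1e-12, na.rm = TRUE))
    msgs <- c(msgs, "distance matrix is not symmetric")
  if (any(diag(dd) != 0, na.rm = TRUE))
    msgs <- c(msgs, "nonzero diagonal")
  ok <- dd[!is.na(dd)]
  if (any(ok < 0 | ok > 1))
    msgs <- c(msgs, "p-distances outside [0, 1]")
  if (!object@deletionPolicy %in% c("pairwise", "complete"))
    msgs <- c(msgs, "unknown deletion policy")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn PDistanceMatrix-class number of sequences
#' @param x a `PDistanceMatrix`
#' @export
setMethod("length", "PDistanceMatrix", function(x) length(x@labels))

#' Accessors for PDistanceMatrix
#'
#' `distValues()` returns the full symmetric numeric matrix (dimnames set
#' to labels); `siteCounts()` the compared-site count matrix;
#' `distLabels()` the label vector; `deletionPolicy()` the gap policy used.
#'
#' @param x a [PDistanceMatrix-class]
#' @return see individual descriptions.
#' @export
distValues <- function(x) {
  d <- x@d
  dimnames(d) <- list(x@labels, x@labels)
  d
}

#' @rdname distValues
#' @export
siteCounts <- function(x) {
  s <- x@sites
  dimnames(s) <- list(x@labels, x@labels)
  s
}

#' @rdname distValues
#' @export
distLabels <- function(x) x@labels

#' @rdname distValues
#' @export
deletionPolicy <- function(x) x@deletionPolicy

setMethod("show", "PDistanceMatrix", function(object) {
  n <- length(object@labels)
  off <- object@d[upper.tri(object@d)]
  cat("PDistanceMatrix:", n, "sequences,", object@deletionPolicy,
      "deletion\n")
  if (n > 1)
    cat(sprintf("  mean p-distance %.4f (range %.4f-%.4f, %d undefined)\n",
                mean(off, na.rm = TRUE),
                suppressWarnings(min(off, na.rm = TRUE)),
                suppressWarnings(max(off, na.rm = TRUE)),
                sum(is.na(off))))
})
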