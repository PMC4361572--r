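# reading, validating, filtering and summarizing lineage-annotated alignments

#' Read an aligned amino-acid FASTA file
#'
#' Reads a multiple sequence alignment in FASTA format (gap character `-`).
#' The accession is the first whitespace-delimited token of each header.
#' All sequences must have equal length; the allowed alphabet is the 20
#' standard amino acids plus `-`, and optionally the ambiguity code `X`.
#'
#' @param path path to the FASTA file.
#' @param alphabetPolicy `"allow-X"` (default) tolerates `X` ambiguity
#'   codes (they are excluded from compared sites downstream);
#'   `"strict"` rejects them.
#' @return a [TaxAlignment-class] with an empty (all-`NA`) taxonomy.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">A1", "ACDEF", ">B1", "AC-EF"), fa)
#' aln <- readAlignmentFasta(fa)
#' nColumns(aln)
#' @export
readAlignmentFasta <- function(path, alphabetPolicy = c("allow-X", "strict")) {
  alphabetPolicy <- match.arg(alphabetPolicy)
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0)
    stop("input error: no sequences in ", path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1)
    stop("alignment error: ragged sequence lengths (",
         paste(unique(w), collapse = ", "), ") in ", path)
  allowed <- c(AA20, "-", if (alphabetPolicy == "allow-X") "X")
  found <- Biostrings::uniqueLetters(seqs)
  bad <- setdiff(found, allowed)
  if (length(bad))
    stop("alphabet error: illegal symbol(s) ", paste(bad, collapse = " "),
         " under policy '", alphabetPolicy, "'")
  TaxAlignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param x a [TaxAlignment-class] (or `AAStringSet`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAlignmentFasta <- function(x, path) {
  seqs <- if (methods::is(x, "TaxAlignment")) alignedSeqs(x) else x
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a taxonomic lineage table
#'
#' Reads a TSV with header columns `accession`, `kingdom`, `phylum`,
#' `class`, `order`, `family`, `genus`, `organism`, `fragment` (0/1).
#' Rows with any empty rank field are flagged incomplete (`complete =
#' FALSE`); their rank fields are kept as given, empty cells becoming `NA`.
#'
#' @param path path to the TSV file.
#' @return a `data.frame` with the nine columns plus a logical `complete`
#'   column; `fragment` is returned as logical.
#' @export
readLineageTable <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE,
                          na.strings = character())
  need <- c("accession", TAX_RANKS, "fragment")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop("schema error: lineage table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$accession))
    stop("input error: duplicate accession(s): ",
         paste(unique(df$accession[duplicated(df$accession)]),
               collapse = ", "))
  for (r in TAX_RANKS) df[[r]][!nzchar(trimws(df[[r]]))] <- NA_character_
  df$complete <- !Reduce(`|`, lapply(df[TAX_RANKS], is.na))
  df$fragment <- df$fragment %in% c("1", "TRUE", "true")
  df[, c("accession", TAX_RANKS, "fragment", "complete")]
}

#' Write a lineage table to TSV
#'
#' @param table a lineage `data.frame` as returned by [readLineageTable()]
#'   (the `complete` column, if present, is dropped; `fragment` is written
#'   as 0/1; `NA` ranks are written as empty cells).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLineageTable <- function(table, path) {
  out <- as.data.frame(table)[, c("accession", TAX_RANKS, "fragment")]
  out$fragment <- as.integer(out$fragment %in% c(TRUE, 1, "1"))
  for (r in TAX_RANKS) out[[r]][is.na(out[[r]])] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Remove fragment-annotated records
#'
#' Splits an alignment into non-fragment (kept) and fragment (removed)
#' records, preserving order. Fragment flags are taken from the bound
#' taxonomy, or from `table` when supplied.
#'
#' @param x a [TaxAlignment-class].
#' @param table optional lineage table (see [readLineageTable()]) supplying
#'   the fragment flags when the alignment's taxonomy does not carry them.
#' @return `list(kept = TaxAlignment, removed = TaxAlignment)`.
#' @export
filterFragments <- function(x, table = NULL) {
  frag <- taxonomy(x)$fragment
  if (!is.null(table)) {
    idx <- match(accessions(x), table$accession)
    frag <- table$fragment[idx]
    tx <- x@taxonomy
    tx$fragment <- frag
    x@taxonomy <- tx
  }
  if (anyNA(frag))
    stop("input error: fragment flag missing for ",
         sum(is.na(frag)), " record(s); supply a lineage table")
  list(kept = x[!frag], removed = x[frag])
}

#' Bind taxonomic lineages to an alignment and filter
#'
#' Restricts the alignment to records that appear in the lineage table,
#' have a complete seven-rank lineage, and (optionally) match a
#' superkingdom filter; each retained record carries its lineage.
#'
#' @param x a [TaxAlignment-class].
#' @param table lineage table from [readLineageTable()].
#' @param superkingdomFilter a kingdom name (e.g. `"Bacteria"`) or `NULL`
#'   for no filter.
#' @return a [TaxAlignment-class] with populated taxonomy.
#' @export
bindTaxonomy <- function(x, table, superkingdomFilter = NULL) {
  table <- as.data.frame(table)
  if (is.null(table$complete))
    table$complete <- !Reduce(`|`, lapply(table[TAX_RANKS], function(v)
      is.na(v) | !nzchar(v)))
  table$fragment <- table$fragment %in% c(TRUE, 1L, "1")
  idx <- match(accessions(x), table$accession)
  keep <- !is.na(idx)
  keep[keep] <- table$complete[idx[keep]]
  if (!is.null(superkingdomFilter)) {
    keep[keep] <- table$kingdom[idx[keep]] %in% superkingdomFilter
  }
  if (sum(keep) < 2)
    stop("input error: fewer than 2 records remain after taxonomy binding")
  out <- x[keep]
  tdf <- table[idx[keep], , drop = FALSE]
  tx <- S4Vectors::DataFrame(accession = accessions(out))
  for (r in TAX_RANKS) tx[[r]] <- tdf[[r]]
  tx$fragment <- tdf$fragment
  tx$complete <- tdf$complete
  out@taxonomy <- tx
  methods::validObject(out)
  out
}

#' Distinct-taxon counts per rank
#'
#' Counts distinct taxa at each rank from phylum down to organism, using
#' full-path keys (a genus name reused under two families counts twice).
#' All records must carry complete lineages.
#'
#' @param x a [TaxAlignment-class] with complete lineages, or a lineage
#'   `data.frame` restricted to complete rows.
#' @return a `data.frame` with columns `rank` and `distinct_count`
#'   (phylum..organism) and attribute `n_records`.
#' @export
rankSummary <- function(x) {
  lin <- if (methods::is(x, "TaxAlignment")) as.data.frame(taxonomy(x)) else
    as.data.frame(x)
  if (nrow(lin) == 0)
    stop("input error: no records")
  if (any(!Reduce(`&`, lapply(lin[TAX_RANKS], function(v) !is.na(v)))))
    stop("precondition error: incomplete lineage present; bind and filter first")
  counts <- vapply(2:7, function(depth) {
    length(unique(.taxonPaths(lin, depth)))
  }, integer(1))
  out <- data.frame(rank = TAX_RANKS[2:7], distinct_count = counts,
                    stringsAsFactors = FALSE)
  attr(out, "n_records") <- nrow(lin)
  out
}

#' Ungapped sequence-length statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of ungapped
#' residue counts. With a single record the SD is reported as `NA`.
#'
#' @param x a [TaxAlignment-class] or `AAStringSet`.
#' @return `list(mean, sd, n)`.
#' @export
sequenceLengthStats <- function(x) {
  seqs <- if (methods::is(x, "TaxAlignment")) alignedSeqs(x) else x
  if (length(seqs) == 0)
    stop("input error: no sequences")
  gaps <- Biostrings::letterFrequency(seqs, letters = "-")[, 1]
  len <- Biostrings::width(seqs) - gaps
  list(mean = mean(len),
       sd = if (length(len) > 1) stats::sd(len) else NA_real_,
       n = length(len))
}
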