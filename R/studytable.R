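# synthetic stand-ins for the published dataset's bookkeeping objects

# distribute `total` units over `k` parts, each part >= 1, with a skewed
# (Zipf-like) allocation of the surplus; deterministic under the current
# RNG state
.partition <- function(total, k) {
  if (total < k) stop("config error: cannot give ", k, " parts from ", total)
  counts <- rep(1L, k)
  extra <- total - k
  if (extra > 0) {
    take <- sample.int(k, extra, replace = TRUE, prob = 1 / seq_len(k))
    tb <- tabulate(take, nbins = k)
    counts <- counts + tb
  }
  counts
}

#' Synthetic study-scale lineage table and alignment
#'
#' Generates a dataset whose bookkeeping structure emulates a large
#' chaperone-family study: `nTotal` records of which `nFragments` carry a
#' fragment annotation; among the non-fragments, a few archaeal and
#' eukaryotic records, a block of bacterial records with incomplete
#' lineages, and `nComplete` bacterial records with full seven-rank
#' lineages covering exactly the configured numbers of distinct phyla,
#' classes, orders, families, genera and organisms (clan sizes are
#' unequal, with a Zipf-skewed allocation). Ungapped sequence lengths are
#' drawn around `lengthMean`/`lengthSd` for non-fragments and around
#' `fragmentLengthMean` for fragments. Everything is synthetic — the
#' function exists so the record-filtering and distinct-count machinery
#' can be exercised end-to-end at realistic scale without external data.
#'
#' @param seed integer seed.
#' @param nTotal total records.
#' @param nFragments fragment-annotated records (excluded by
#'   [filterFragments()]).
#' @param nArchaea,nEukaryota complete non-bacterial records.
#' @param nComplete complete-lineage bacterial records.
#' @param taxa named counts of distinct taxa the complete bacterial
#'   records must cover.
#' @param L alignment columns.
#' @param lengthMean,lengthSd,fragmentLengthMean,fragmentLengthSd
#'   ungapped-length distribution parameters.
#' @return `list(alignment = TaxAlignment, table = data.frame)`; the table
#'   has the [readLineageTable()] schema.
#' @export
simulateStudyTable <- function(seed = 1,
                               nTotal = 5162, nFragments = 21,
                               nArchaea = 1, nEukaryota = 3,
                               nComplete = 3813,
                               taxa = c(phylum = 4, class = 11, order = 41,
                                        family = 82, genus = 269,
                                        organism = 3744),
                               L = 250, lengthMean = 157, lengthSd = 27,
                               fragmentLengthMean = 113,
                               fragmentLengthSd = 50) {
  nIncomplete <- nTotal - nFragments - nArchaea - nEukaryota - nComplete
  if (nIncomplete < 0)
    stop("config error: counts exceed nTotal")
  set.seed(.substream(seed, "studytable"))
  # nested partitions give exactly the configured distinct counts
  classPer <- .partition(taxa[["class"]], taxa[["phylum"]])
  orderPer <- .partition(taxa[["order"]], taxa[["class"]])
  familyPer <- .partition(taxa[["family"]], taxa[["order"]])
  genusPer <- .partition(taxa[["genus"]], taxa[["family"]])
  orgPer <- .partition(taxa[["organism"]], taxa[["genus"]])
  seqPer <- .partition(nComplete, taxa[["organism"]])
  rows <- vector("list", nComplete)
  ri <- 0L
  oi <- 0L; gi <- 0L; fi <- 0L; odi <- 0L; ci <- 0L
  for (p in seq_len(taxa[["phylum"]])) {
    for (cc in seq_len(classPer[p])) {
      ci <- ci + 1L
      for (od in seq_len(orderPer[ci])) {
        odi <- odi + 1L
        for (f in seq_len(familyPer[odi])) {
          fi <- fi + 1L
          for (g in seq_len(genusPer[fi])) {
            gi <- gi + 1L
            for (o in seq_len(orgPer[gi])) {
              oi <- oi + 1L
              for (s in seq_len(seqPer[oi])) {
                ri <- ri + 1L
                rows[[ri]] <- c(paste0("Phy", p), paste0("Cla", cc),
                                paste0("Ord", od), paste0("Fam", f),
                                paste0("Gen", g), paste0("Org", o))
              }
            }
          }
        }
      }
    }
  }
  lin <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  colnames(lin) <- TAX_RANKS[-1]
  complete <- data.frame(accession = sprintf("B%05d", seq_len(nComplete)),
                         kingdom = "Bacteria", lin, fragment = 0L,
                         stringsAsFactors = FALSE)
  other <- function(n, prefix, kingdom, fragment = 0L, incompleteAt = NULL) {
    if (n == 0) return(NULL)
    df <- data.frame(accession = sprintf("%s%05d", prefix, seq_len(n)),
                     kingdom = kingdom, phylum = paste0(kingdom, "Phy"),
                     class = paste0(kingdom, "Cla"),
                     order = paste0(kingdom, "Ord"),
                     family = paste0(kingdom, "Fam"),
                     genus = paste0(kingdom, "Gen"),
                     organism = sprintf("%sOrg%d", kingdom, seq_len(n)),
                     fragment = fragment, stringsAsFactors = FALSE)
    if (!is.null(incompleteAt)) {
      blank <- sample(incompleteAt, n, replace = TRUE)
      for (i in seq_len(n)) df[i, blank[i]] <- ""
    }
    df
  }
  incomplete <- other(nIncomplete, "I", "Bacteria",
                      incompleteAt = c("class", "family", "genus",
                                       "organism"))
  archaea <- other(nArchaea, "A", "Archaea")
  eukaryota <- other(nEukaryota, "E", "Eukaryota")
  fragments <- other(nFragments, "F", "Bacteria", fragment = 1L)
  table <- rbind(complete, incomplete, archaea, eukaryota, fragments)
  # sequences: random residues, gap-padded at the end to the drawn length
  n <- nrow(table)
  isFrag <- table$fragment == 1L
  len <- integer(n)
  len[!isFrag] <- pmin(L, pmax(40L, round(stats::rnorm(sum(!isFrag),
                                                       lengthMean,
                                                       lengthSd))))
  len[isFrag] <- pmin(L, pmax(20L, round(stats::rnorm(sum(isFrag),
                                                      fragmentLengthMean,
                                                      fragmentLengthSd))))
  seqs <- vapply(len, function(l)
    paste0(paste(AA20[sample.int(20L, l, replace = TRUE)], collapse = ""),
           strrep("-", L - l)), "")
  aln <- TaxAlignment(Biostrings::AAStringSet(stats::setNames(seqs,
                                                              table$accession)))
  list(alignment = aln, table = table)
}

#' Synthetic worked-example sequence pair
#'
#' A deterministic, synthetic stand-in for a pairwise alignment of two
#' divergent family members whose ungapped lengths are 155 and 161
#' residues in a 169-column alignment: sequence A lacks a 14-residue turn
#' present in sequence B, sequence B is trimmed by 8 terminal columns, and
#' 82 of the 169 columns carry identical residues, so the identity under
#' the alignment-length denominator is `100 * 82/169 = 48.521%`. Used to
#' document and exercise the [percentIdentity()] denominator convention on
#' a pair with realistic indel structure. Not real protein sequence data.
#'
#' @return a named `AAStringSet` of two aligned sequences
#'   (`SYNPAIR_A`, `SYNPAIR_B`).
#' @export
workedPairAlignment <- function() {
  L <- 169L
  gapsA <- 70:83            # the internal turn absent from A (14 cols)
  gapsB <- c(1:4, 166:169)  # terminal trimming of B (8 cols)
  both <- setdiff(seq_len(L), c(gapsA, gapsB))   # 147 comparable columns
  identCols <- both[1:82]
  diffCols <- setdiff(both, identCols)
  set.seed(420417)
  a <- b <- character(L)
  shared <- AA20[sample.int(20L, length(identCols), replace = TRUE)]
  a[identCols] <- shared
  b[identCols] <- shared
  ra <- AA20[sample.int(20L, length(diffCols), replace = TRUE)]
  rb <- AA20[((match(ra, AA20) + sample.int(19L, length(diffCols),
                                            replace = TRUE) - 1L) %% 20L) +
               1L]
  a[diffCols] <- ra
  b[diffCols] <- rb
  fillA <- setdiff(seq_len(L), c(gapsA, identCols, diffCols))
  a[fillA] <- AA20[sample.int(20L, length(fillA), replace = TRUE)]
  fillB <- setdiff(seq_len(L), c(gapsB, identCols, diffCols))
  b[fillB] <- AA20[sample.int(20L, length(fillB), replace = TRUE)]
  a[gapsA] <- "-"
  b[gapsB] <- "-"
  Biostrings::AAStringSet(c(SYNPAIR_A = paste(a, collapse = ""),
                            SYNPAIR_B = paste(b, collapse = "")))
}
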