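# hierarchical sequence-evolution simulator with known ground truth

#' Simulation configuration
#'
#' Parameters for [simulateDataset()]. Sequences evolve along a
#' rank-structured guide tree under a symmetric 20-state substitution
#' model: on a branch at rank transition `r`, each site independently
#' substitutes with probability `m[r]`, uniformly to one of the 19 other
#' residues. Defaults give a desk-scale dataset with divergence decreasing
#' toward the leaves (a vertical-descent regime).
#'
#' @param fanout named list of child counts for ranks
#'   `phylum`..`organism`; each entry a single count or a `c(min, max)`
#'   range sampled per parent. The default ranges produce unequal clan
#'   sizes, mirroring the wildly unbalanced group sizes of real taxonomic
#'   samples; balanced clans are a degenerate special case in which the
#'   parent-wide observation unit carries no between-clan signal.
#' @param seqsPerOrganism sequences per organism (count or range).
#' @param L alignment columns.
#' @param m named vector of per-branch substitution probabilities for the
#'   transitions `phylum`..`organism` plus the terminal `sequence` branch;
#'   each in `[0, 19/20)`.
#' @param hgtRate per-leaf probability of a cross-clan transfer event
#'   (see [injectHgt()]).
#' @param hgtCrossingRank rank at which transfer donors must differ.
#' @param seed master integer seed.
#' @return a `sim_config` list.
#' @export
simConfig <- function(fanout = list(phylum = c(2, 4), class = c(1, 3),
                                    order = c(1, 3), family = c(1, 3),
                                    genus = c(1, 3), organism = c(1, 3)),
                      seqsPerOrganism = c(1, 3), L = 170,
                      m = c(phylum = 0.15, class = 0.10, order = 0.07,
                            family = 0.05, genus = 0.03, organism = 0.02,
                            sequence = 0.01),
                      hgtRate = 0, hgtCrossingRank = "genus", seed = 1) {
  fanout <- as.list(fanout)
  need <- TAX_RANKS[-1]
  if (!all(need %in% names(fanout)))
    stop("config error: fanout needs entries for ",
         paste(need, collapse = ", "))
  if (any(unlist(fanout) < 1))
    stop("config error: all fan-outs must be >= 1")
  mneed <- c(need, "sequence")
  if (!all(mneed %in% names(m)))
    stop("config error: m needs entries for ", paste(mneed, collapse = ", "))
  if (any(m < 0) || any(m >= 19 / 20))
    stop("config error: each m must lie in [0, 19/20)")
  if (L < 1) stop("config error: L must be >= 1")
  if (hgtRate < 0 || hgtRate > 1)
    stop("config error: hgtRate must lie in [0, 1]")
  structure(list(fanout = fanout, seqsPerOrganism = seqsPerOrganism,
                 L = as.integer(L), m = m, hgtRate = hgtRate,
                 hgtCrossingRank = hgtCrossingRank,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected p-distance under the symmetric 20-state model
#'
#' Closed-form probability that the two endpoints of a path differ at a
#' site, given the per-branch substitution probabilities along the path:
#' `1 - (1/20 + (19/20) prod_i (1 - 20 m_i / 19))`. The analytic oracle
#' tying the simulator to the distance machinery.
#'
#' @param pathM numeric vector of branch substitution probabilities, each
#'   in `[0, 19/20)`; an empty path gives 0.
#' @return expected p-distance.
#' @examples
#' expectedPDistance(0.1)          # one branch: exactly m
#' expectedPDistance(c(0.1, 0.1))  # ~0.18947
#' @export
expectedPDistance <- function(pathM) {
  if (length(pathM) == 0) return(0)
  if (any(pathM < 0) || any(pathM >= 19 / 20))
    stop("input error: each entry must lie in [0, 19/20)")
  1 - (1 / 20 + (19 / 20) * prod(1 - 20 * pathM / 19))
}

# mutate an integer-coded sequence along one branch with per-site rate m
.mutateSeq <- function(x, m) {
  hit <- stats::runif(length(x)) < m
  nh <- sum(hit)
  if (nh > 0) {
    off <- sample.int(19L, nh, replace = TRUE)
    x[hit] <- ((x[hit] - 1L + off) %% 20L) + 1L
  }
  x
}

.drawCount <- function(spec) {
  if (length(spec) == 1) return(as.integer(spec))
  sample(seq.int(spec[1], spec[2]), 1)
}

#' Simulate a taxonomically structured aligned dataset
#'
#' Builds a rank-structured guide tree from the configured fan-outs, draws
#' a uniform random root sequence, evolves it along every branch under the
#' symmetric substitution model (rate `m[rank]` per branch), and emits the
#' leaf sequences as a gap-free [TaxAlignment-class] with a complete
#' lineage table. Child taxon names are reused across parents (e.g.
#' `Cla1` under every phylum) so full-path disambiguation is exercised
#' downstream. When `hgtRate > 0`, [injectHgt()] is applied afterwards.
#' All draws flow from the master seed through named substreams (tree,
#' root, per-branch mutations, transfer events), so adding transfer events
#' does not perturb the base sequences, and the whole result is
#' reproducible from the seed.
#'
#' @param config a `sim_config` from [simConfig()].
#' @return a `sim_result` list: `alignment` ([TaxAlignment-class]),
#'   `lineageTable` (`data.frame`), `guideNewick` (character),
#'   `tipPaths` (per-accession list of root-path branch rates, the ground
#'   truth for [expectedLeafDistance()]), `hgtEvents` (`data.frame`),
#'   `config`.
#' @export
simulateDataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(simConfig, config)
  L <- config$L
  m <- config$m
  prefixes <- c(phylum = "Phy", class = "Cla", order = "Ord",
                family = "Fam", genus = "Gen", organism = "Org")
  # topology draws (counts) in deterministic preorder, own substream
  set.seed(.substream(config$seed, "tree"))
  nodes <- list(list(name = "Bacteria", path = "Bacteria", rank = 0L))
  levels <- list(nodes)
  for (depth in 1:6) {
    rank <- TAX_RANKS[depth + 1L]
    nxt <- list()
    for (parent in levels[[depth]]) {
      nch <- .drawCount(config$fanout[[rank]])
      for (i in seq_len(nch)) {
        nm <- paste0(prefixes[[rank]], i)
        nxt[[length(nxt) + 1L]] <- list(
          name = nm, path = paste0(parent$path, "/", nm),
          rank = depth, parentPath = parent$path)
      }
    }
    levels[[depth + 1L]] <- nxt
  }
  tipCounts <- vapply(levels[[7L]], function(org)
    .drawCount(config$seqsPerOrganism), 0L)
  # root sequence
  set.seed(.substream(config$seed, "root"))
  rootSeq <- sample.int(20L, L, replace = TRUE)
  # evolve along branches; branch id = preorder index, own substream each
  seqsByPath <- list(Bacteria = rootSeq)
  branchId <- 0L
  for (depth in 1:6) {
    rate <- m[[TAX_RANKS[depth + 1L]]]
    for (node in levels[[depth + 1L]]) {
      branchId <- branchId + 1L
      set.seed(.substream(config$seed, "branch", branchId))
      seqsByPath[[node$path]] <- .mutateSeq(seqsByPath[[node$parentPath]],
                                            rate)
    }
  }
  # terminal sequence branches
  accs <- character(0)
  tipSeqs <- list()
  lineageRows <- list()
  tipPaths <- list()
  counter <- 0L
  for (oi in seq_along(levels[[7L]])) {
    org <- levels[[7L]][[oi]]
    segs <- strsplit(org$path, "/", fixed = TRUE)[[1]]
    pathRates <- vapply(2:7, function(dd) m[[TAX_RANKS[dd]]], 0)
    for (s in seq_len(tipCounts[oi])) {
      counter <- counter + 1L
      branchId <- branchId + 1L
      acc <- sprintf("S%05d", counter)
      set.seed(.substream(config$seed, "branch", branchId))
      tipSeqs[[acc]] <- .mutateSeq(seqsByPath[[org$path]], m[["sequence"]])
      accs <- c(accs, acc)
      lineageRows[[acc]] <- segs
      tipPaths[[acc]] <- list(nodes = c(cumpaste(segs), acc),
                              m = c(pathRates, m[["sequence"]]))
    }
  }
  lin <- as.data.frame(do.call(rbind, lineageRows), stringsAsFactors = FALSE)
  colnames(lin) <- TAX_RANKS
  lineageTable <- data.frame(accession = accs, lin, fragment = FALSE,
                             complete = TRUE, stringsAsFactors = FALSE,
                             row.names = NULL)
  seqMat <- do.call(rbind, tipSeqs)
  chars <- apply(seqMat, 1, function(r) paste(AA20[r], collapse = ""))
  aln <- TaxAlignment(Biostrings::AAStringSet(stats::setNames(chars, accs)))
  aln <- bindTaxonomy(aln, lineageTable, superkingdomFilter = NULL)
  guide <- .guideNewick(levels, tipCounts, m, accs)
  res <- structure(list(alignment = aln, lineageTable = lineageTable,
                        guideNewick = guide, tipPaths = tipPaths,
                        hgtEvents = .emptyHgtLog(), config = config),
                   class = "sim_result")
  if (config$hgtRate > 0)
    res <- injectHgt(res, config$hgtRate, config$hgtCrossingRank,
                     seed = config$seed)
  res
}

# cumulative full-path keys along a lineage vector
cumpaste <- function(segs) {
  Reduce(function(a, b) paste0(a, "/", b), segs, accumulate = TRUE)
}

.emptyHgtLog <- function() {
  data.frame(recipient = character(0), donor = character(0),
             crossing_rank = character(0), note = character(0),
             stringsAsFactors = FALSE)
}

# ground-truth guide tree in Newick, edge lengths = per-branch m
.guideNewick <- function(levels, tipCounts, m, accs) {
  counter <- 0L
  build <- function(depth, idx) {
    node <- levels[[depth]][[idx]]
    if (depth == 7L) {
      n <- tipCounts[idx]
      tips <- vapply(seq_len(n), function(s) {
        counter <<- counter + 1L
        paste0(accs[counter], ":", sprintf("%.6f", m[["sequence"]]))
      }, "")
      return(paste0("(", paste(tips, collapse = ","), ")"))
    }
    childIdx <- which(vapply(levels[[depth + 1L]],
                             function(nd) nd$parentPath == node$path,
                             logical(1)))
    rate <- m[[TAX_RANKS[depth + 1L]]]
    subs <- vapply(childIdx, function(ci)
      paste0(build(depth + 1L, ci), ":", sprintf("%.6f", rate)), "")
    paste0("(", paste(subs, collapse = ","), ")")
  }
  paste0(build(1L, 1L), ";")
}

#' Expected p-distance between two simulated leaves
#'
#' Looks up the ground-truth branch rates on the path between two leaves
#' of a simulation (branches below their last common ancestor on both
#' sides) and evaluates [expectedPDistance()] on them.
#'
#' @param result a `sim_result` from [simulateDataset()].
#' @param a,b leaf accessions.
#' @return expected p-distance for that pair.
#' @export
expectedLeafDistance <- function(result, a, b) {
  pa <- result$tipPaths[[a]]; pb <- result$tipPaths[[b]]
  if (is.null(pa) || is.null(pb))
    stop("input error: unknown accession")
  common <- sum(cumall(pa$nodes[seq_len(min(length(pa$nodes),
                                            length(pb$nodes)))] ==
                         pb$nodes[seq_len(min(length(pa$nodes),
                                              length(pb$nodes)))]))
  # branch j leads into path node j+1; branches below the common prefix
  # are those with j + 1 > common, i.e. j >= common
  expectedPDistance(c(pa$m[seq_along(pa$m) >= common],
                      pb$m[seq_along(pb$m) >= common]))
}

cumall <- function(x) cumprod(as.numeric(x)) > 0

#' Inject cross-clan transfer events
#'
#' Emulates horizontal gene transfer: each leaf, independently with
#' probability `hgtRate`, has its sequence replaced by a copy of a donor
#' leaf from a different clan at `crossingRank`, re-mutated along one
#' terminal branch (rate `m["sequence"]`). Lineage labels are left
#' unchanged — the signature of transfer is that the sequence moves while
#' the taxonomy does not. Events are logged; a leaf with no eligible donor
#' clan is skipped and logged. Draws use a dedicated substream, so the
#' untouched sequences are byte-identical to the input.
#'
#' @param result a `sim_result` from [simulateDataset()].
#' @param hgtRate per-leaf transfer probability in `[0, 1]`.
#' @param crossingRank rank at which donor and recipient must differ
#'   (default `"genus"`).
#' @param seed integer seed (defaults to the simulation's master seed).
#' @return the modified `sim_result`, with `hgtEvents` filled in.
#' @export
injectHgt <- function(result, hgtRate, crossingRank = "genus",
                      seed = result$config$seed) {
  if (hgtRate < 0 || hgtRate > 1)
    stop("input error: hgtRate must lie in [0, 1]")
  if (!(crossingRank %in% TAX_RANKS[-1]))
    stop("input error: unknown crossing rank '", crossingRank, "'")
  if (hgtRate == 0) {
    result$hgtEvents <- .emptyHgtLog()
    return(result)
  }
  aln <- result$alignment
  lin <- as.data.frame(taxonomy(aln))
  depth <- match(crossingRank, TAX_RANKS)
  clan <- .taxonPaths(lin, depth)
  enc <- .encodeAlignment(alignedSeqs(aln))
  mSeq <- result$config$m[["sequence"]]
  events <- list()
  accs <- accessions(aln)
  for (i in seq_along(accs)) {
    set.seed(.substream(seed, "hgt", i))
    if (stats::runif(1) >= hgtRate) next
    donors <- which(clan != clan[i])
    if (length(donors) == 0) {
      events[[length(events) + 1L]] <-
        data.frame(recipient = accs[i], donor = NA_character_,
                   crossing_rank = crossingRank, note = "skipped:no-donor",
                   stringsAsFactors = FALSE)
      next
    }
    don <- donors[sample.int(length(donors), 1)]
    enc[i, ] <- .mutateSeq(enc[don, ], mSeq)
    events[[length(events) + 1L]] <-
      data.frame(recipient = accs[i], donor = accs[don],
                 crossing_rank = crossingRank, note = "transferred",
                 stringsAsFactors = FALSE)
  }
  chars <- apply(enc, 1, function(r) paste(AA20[r], collapse = ""))
  newAln <- TaxAlignment(Biostrings::AAStringSet(stats::setNames(chars,
                                                                 accs)),
                         taxonomy = taxonomy(aln))
  result$alignment <- newAln
  result$hgtEvents <- if (length(events)) do.call(rbind, events) else
    .emptyHgtLog()
  result
}

#' Write a simulated dataset as standard pipeline inputs
#'
#' Writes the aligned FASTA, the lineage TSV, and a ground-truth JSON
#' (config echo, guide tree in Newick, transfer-event log, seed).
#'
#' @param result a `sim_result`.
#' @param dir output directory (created if needed).
#' @return named vector of the three file paths, invisibly.
#' @export
writeDataset <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "alignment.fasta")
  tsv <- file.path(dir, "lineage.tsv")
  js <- file.path(dir, "truth.json")
  writeAlignmentFasta(result$alignment, fa)
  writeLineageTable(result$lineageTable, tsv)
  cfg <- result$config
  truth <- list(config = list(fanout = cfg$fanout,
                              seqsPerOrganism = cfg$seqsPerOrganism,
                              L = cfg$L, m = as.list(cfg$m),
                              hgtRate = cfg$hgtRate,
                              hgtCrossingRank = cfg$hgtCrossingRank,
                              seed = cfg$seed),
                guide_newick = result$guideNewick,
                hgt_events = result$hgtEvents,
                seed = cfg$seed)
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(fasta = fa, lineage = tsv, truth = js))
}
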