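# fixtures are built in code; nothing is read from disk except temp files

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

alnFrom <- function(...) {
  TaxAlignment(Biostrings::AAStringSet(c(...)))
}

# random aligned sequences with optional gaps / ambiguity codes
randAln <- function(n, L, seed, gapProb = 0, xProb = 0) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    ch <- AA[sample.int(20, L, replace = TRUE)]
    r <- runif(L)
    ch[r < gapProb] <- "-"
    ch[r >= gapProb & r < gapProb + xProb] <- "X"
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- sprintf("T%02d", seq_len(n))
  alnFrom(seqs)
}

writeTmpFasta <- function(seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), path)
  path
}

# brute-force per-column p-distance oracle (independent of the package's
# cross-product implementation)
brutePDist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca %in% AA & cb %in% AA
  sites <- sum(ok)
  list(d = if (sites == 0) NA_real_ else sum(ca[ok] != cb[ok]) / sites,
       sites = sites)
}

bruteDistMatrix <- function(aln) {
  seqs <- as.character(clanvar::alignedSeqs(aln))
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  s <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      r <- brutePDist(seqs[i], seqs[j])
      d[i, j] <- r$d
      s[i, j] <- r$sites
    }
  }
  diag(d) <- 0
  list(d = d, sites = s)
}

# lineage table rows; ranks default to a single shared path
lineageRow <- function(accession, kingdom = "Bacteria", phylum = "P1",
                       class = "C1", order = "O1", family = "F1",
                       genus = "G1", organism = "S1", fragment = 0L) {
  data.frame(accession = accession, kingdom = kingdom, phylum = phylum,
             class = class, order = order, family = family, genus = genus,
             organism = organism, fragment = fragment,
             stringsAsFactors = FALSE)
}

completeTable <- function(df) {
  df$complete <- !Reduce(`|`, lapply(
    df[c("kingdom", "phylum", "class", "order", "family", "genus",
         "organism")], function(v) is.na(v) | !nzchar(v)))
  df$fragment <- df$fragment %in% c(1, "1", TRUE)
  df
}

# random unrooted binary tree with positive branch lengths (additive truth)
randAdditiveTree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  tr
}

# independent variance-component oracle built on stats::aov mean squares
aovVarComp <- function(groups) {
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  sm <- summary(stats::aov(y ~ g))[[1]]
  MS_A <- sm$`Mean Sq`[1]
  MS_W <- sm$`Mean Sq`[2]
  ni <- lengths(groups)
  N <- sum(ni)
  k <- length(ni)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  s2A <- max(0, (MS_A - MS_W) / n0)
  list(MS_A = MS_A, MS_W = MS_W, n0 = n0, s2_A = s2A, s2_W = MS_W,
       pct_inter = if (s2A + MS_W > 0) 100 * s2A / (s2A + MS_W) else 0)
}

# small simulated dataset reused across tests
smallSimConfig <- function(seed = 1, ...) {
  simConfig(fanout = list(phylum = 2, class = 2, order = 1, family = 2,
                          genus = 2, organism = 2),
            seqsPerOrganism = 2, L = 120, seed = seed, ...)
}
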