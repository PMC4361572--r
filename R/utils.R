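# shared constants and internal helpers

#' Taxonomic ranks used throughout the package, kingdom first.
#' @keywords internal
#' @noRd
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "organism")

# the 20 standard amino acids; '-' is the gap, 'X' the ambiguity code
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Deterministic sub-seed for a named random substream. Keeps every draw
# reproducible from one master seed while isolating streams (tree topology,
# root sequence, per-branch mutations, bootstrap replicates, transfer
# events) from one another, so e.g. adding transfer events does not perturb
# the base sequences. Result stays below 2^31.
.substream <- function(seed, name, i = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  ((as.numeric(seed) %% 2147483647) * 1009 + h * 9176 + as.numeric(i) * 31) %%
    2147483647
}

# Encode aligned residues as an integer matrix (1..20), with gaps and 'X'
# ambiguity codes as NA: those columns are excluded from compared sites.
.encodeAlignment <- function(seqs) {
  m <- as.matrix(seqs)
  enc <- match(m, AA20)
  dim(enc) <- dim(m)
  rownames(enc) <- names(seqs)
  enc
}

# Full-path taxon keys at a given depth (1 = kingdom ... 7 = organism).
# Full paths prevent silent merging of identically named taxa under
# different parents.
.taxonPaths <- function(lineage, depth, sep = "/") {
  cols <- TAX_RANKS[seq_len(depth)]
  do.call(paste, c(as.list(as.data.frame(lineage[, cols, drop = FALSE])),
                   sep = sep))
}

# Fixed-format numeric rendering for report files (byte-stable output).
.fmtNum <- function(x, digits = 6) {
  out <- ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
  out
}

.writeReportTsv <- function(df, path, numericDigits = 6) {
  out <- df
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.integer(out[[nm]]))
      out[[nm]] <- .fmtNum(out[[nm]], numericDigits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}
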