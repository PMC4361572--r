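# inter- vs intra-clan variance partitioning by unbalanced model-II ANOVA

#' Clan-grouped per-sequence distance observations at a bifurcation
#'
#' For a parent taxon (full-path key, e.g. `"Bacteria/Proteobacteria"`),
#' collects one observation per member sequence, grouped by the parent's
#' immediate sub-taxa ("clans") at the next rank. Under the default
#' `parent-wide` unit, the observation for a sequence is its mean
#' p-distance to all other sequences in the parent taxon; `within-clan`
#' restricts the averaging to the sequence's own clan (singleton clans
#' then contribute no observation and are dropped).
#'
#' @param dm a [PDistanceMatrix-class].
#' @param lineages lineage `data.frame` (or `TaxAlignment`) covering every
#'   matrix label; complete lineages only.
#' @param parentTaxon full-path taxon key; `"Bacteria"` (a kingdom) up to a
#'   genus-level path. Children are taken at the next rank down.
#' @param unitPolicy `"parent-wide"` (default) or `"within-clan"`.
#' @return a list of class `clan_obs`: `parent_taxon`, `parent_rank`,
#'   `child_rank`, `groups` (named list of numeric observation vectors),
#'   `k`, `N`, `computable`, `reason`, `unit_policy`.
#' @export
clanGroups <- function(dm, lineages, parentTaxon,
                       unitPolicy = c("parent-wide", "within-clan")) {
  unitPolicy <- match.arg(unitPolicy)
  if (methods::is(lineages, "TaxAlignment"))
    lineages <- as.data.frame(taxonomy(lineages))
  lineages <- as.data.frame(lineages)
  depth <- length(strsplit(parentTaxon, "/", fixed = TRUE)[[1]])
  if (depth >= 7)
    stop("input error: parent must be above organism rank")
  labs <- distLabels(dm)
  li <- match(labs, lineages$accession)
  lin <- lineages[li, , drop = FALSE]
  parentKey <- .taxonPaths(lin, depth)
  members <- which(parentKey == parentTaxon)
  if (length(members) == 0)
    stop("input error: no sequences under parent taxon '", parentTaxon, "'")
  childKey <- .taxonPaths(lin, depth + 1L)[members]
  d <- distValues(dm)
  if (unitPolicy == "parent-wide") {
    obs <- .perSeqMeans(d, members)
    groups <- lapply(split(obs, childKey), function(o) o[!is.na(o)])
  } else {
    groups <- lapply(split(members, childKey), function(idx) {
      o <- .perSeqMeans(d, idx)
      o[!is.na(o)]
    })
  }
  groups <- groups[order(names(groups))]
  groups <- groups[vapply(groups, length, 0L) > 0]
  k <- length(groups)
  N <- sum(vapply(groups, length, 0L))
  out <- list(parent_taxon = parentTaxon,
              parent_rank = TAX_RANKS[depth],
              child_rank = TAX_RANKS[depth + 1L],
              groups = groups, k = k, N = N,
              computable = k >= 2, reason = if (k >= 2) "" else "k<2",
              unit_policy = unitPolicy)
  class(out) <- "clan_obs"
  out
}

# row template so uncomputable bifurcations still tabulate
.vcRow <- function(meta, k = NA_integer_, N = NA_integer_, n0 = NA_real_,
                   MS_A = NA_real_, MS_W = NA_real_, s2_A = NA_real_,
                   s2_W = NA_real_, pct_inter = NA_real_,
                   pct_intra = NA_real_, computable = FALSE, reason = "") {
  data.frame(parent_rank = meta$parent_rank, parent_taxon = meta$parent_taxon,
             child_rank = meta$child_rank, k = k, N = N, n0 = n0,
             MS_A = MS_A, MS_W = MS_W, s2_A = s2_A, s2_W = s2_W,
             pct_inter = pct_inter, pct_intra = pct_intra,
             computable = computable, reason = reason,
             stringsAsFactors = FALSE)
}

#' Unbalanced one-way model-II (random effects) ANOVA variance components
#'
#' Decomposes the variance of observations grouped into k clans into
#' among-clan and within-clan components using the expected-mean-squares
#' estimator for unbalanced designs:
#' `SS_A = sum n_i (ybar_i - ybar)^2`, `SS_W = sum (y_ij - ybar_i)^2`,
#' `MS_A = SS_A/(k-1)`, `MS_W = SS_W/(N-k)`,
#' `n0 = (N - sum n_i^2 / N)/(k-1)`,
#' `s2_A = max(0, (MS_A - MS_W)/n0)`, `s2_W = MS_W`, and
#' `pct_inter = 100 s2_A / (s2_A + s2_W)`. Negative among-clan estimates
#' are truncated at zero and flagged (`reason = "truncated"`); zero total
#' variance yields `pct_inter = 0` with `reason = "degenerate"`.
#'
#' @param x a `clan_obs` object from [clanGroups()], or a named list of
#'   numeric observation vectors (one per clan).
#' @return a one-row `data.frame` with columns `parent_rank`,
#'   `parent_taxon`, `child_rank`, `k`, `N`, `n0`, `MS_A`, `MS_W`, `s2_A`,
#'   `s2_W`, `pct_inter`, `pct_intra`, `computable`, `reason`.
#' @examples
#' model2Anova(list(A = c(0.1, 0.2), B = c(0.5, 0.6, 0.7)))
#' @export
model2Anova <- function(x) {
  if (inherits(x, "clan_obs")) {
    meta <- x[c("parent_rank", "parent_taxon", "child_rank")]
    groups <- x$groups
    if (!x$computable)
      return(.vcRow(meta, k = x$k, N = x$N, reason = x$reason))
  } else {
    meta <- list(parent_rank = NA_character_, parent_taxon = NA_character_,
                 child_rank = NA_character_)
    groups <- x
  }
  ni <- vapply(groups, length, 0L)
  k <- length(groups)
  N <- sum(ni)
  if (k < 2)
    return(.vcRow(meta, k = k, N = N, reason = "k<2"))
  if (N - k < 1)
    return(.vcRow(meta, k = k, N = N, reason = "N=k"))
  y <- unlist(groups, use.names = FALSE)
  gm <- vapply(groups, mean, 0)
  ybar <- sum(y) / N
  SS_A <- sum(ni * (gm - ybar)^2)
  SS_W <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  MS_A <- SS_A / (k - 1)
  MS_W <- SS_W / (N - k)
  n0 <- (N - sum(ni^2) / N) / (k - 1)
  reason <- ""
  raw_s2A <- (MS_A - MS_W) / n0
  s2_A <- raw_s2A
  if (s2_A < 0) {
    s2_A <- 0
    reason <- "truncated"
  }
  s2_W <- MS_W
  tot <- s2_A + s2_W
  if (tot <= 0) {
    pct_inter <- 0
    reason <- "degenerate"
  } else {
    pct_inter <- 100 * s2_A / tot
  }
  .vcRow(meta, k = k, N = N, n0 = n0, MS_A = MS_A, MS_W = MS_W,
         s2_A = s2_A, s2_W = s2_W, pct_inter = pct_inter,
         pct_intra = 100 - pct_inter, computable = TRUE, reason = reason)
}

#' Variance partition at every taxonomic bifurcation
#'
#' Walks the lineage from kingdom down to genus-level parents (children at
#' organism rank included when at least two organisms are represented) and
#' computes the inter-/intra-clan variance decomposition of per-sequence
#' mean p-distances at each parent via [clanGroups()] + [model2Anova()].
#' Uncomputable bifurcations (a single child clan, or no within-group
#' degrees of freedom) are retained as rows with their reason; they are
#' data, not errors.
#'
#' @inheritParams clanGroups
#' @return a `data.frame`, one row per internal taxon, ordered by rank
#'   then full-path taxon name; columns as in [model2Anova()].
#' @export
lineageVariancePartition <- function(dm, lineages,
                                     unitPolicy = c("parent-wide",
                                                    "within-clan")) {
  unitPolicy <- match.arg(unitPolicy)
  if (methods::is(lineages, "TaxAlignment"))
    lineages <- as.data.frame(taxonomy(lineages))
  lineages <- as.data.frame(lineages)
  labs <- distLabels(dm)
  lin <- lineages[match(labs, lineages$accession), , drop = FALSE]
  rows <- list()
  for (depth in 1:6) {
    parents <- sort(unique(.taxonPaths(lin, depth)))
    for (p in parents) {
      obs <- clanGroups(dm, lin, p, unitPolicy)
      rows[[length(rows) + 1L]] <- model2Anova(obs)
    }
  }
  do.call(rbind, rows)
}
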