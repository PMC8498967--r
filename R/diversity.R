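## Community-ecology diversity indices applied to a genome's TE
## complement, treating masked bp per taxon the way an ecologist treats
## individuals per species.

#' TE community proportions from an abundance table
#'
#' Converts per-taxon genome percentages into a normalized proportion
#' vector. By default, mass not classified to the table's level
#' (`"unclassified"`) is dropped before renormalization, mirroring the
#' exclusion of ambiguous classifications when communities are compared
#' across genomes; set `includeUnclassified = TRUE` for a sensitivity
#' analysis that keeps it as its own taxon.
#'
#' @param x an [AbundanceTable-class].
#' @param includeUnclassified keep the `"unclassified"` row as a taxon.
#' @return a [TECommunity-class].
#' @export
communityProportions <- function(x, includeUnclassified = FALSE) {
    t <- taxonTable(x)
    if (!includeUnclassified)
        t <- t[t$taxon != "unclassified", , drop = FALSE]
    t <- t[t$masked_bp > 0, , drop = FALSE]
    if (nrow(t) == 0L)
        .stopf("no classified mass retained at the %s level",
               abundanceLevel(x))
    teCommunity(t$taxon, t$masked_bp, level = abundanceLevel(x))
}

#' Shannon diversity index
#'
#' \eqn{H' = -\sum_i P_i \ln P_i}, the uncertainty in the taxon identity
#' of a random draw from the community, in nats (natural log, as the
#' formula is written). Zero for a single-taxon community, at most
#' \eqn{\ln k} for richness \eqn{k}.
#'
#' @param x a [TECommunity-class].
#' @return Shannon index in nats.
#' @examples
#' shannonIndex(teCommunity(c("a", "b"), c(1, 1)))  # ln 2
#' @export
shannonIndex <- function(x) {
    p <- taxonProportions(x)
    -sum(p * log(p))
}

#' Gini-Simpson diversity index
#'
#' \eqn{D = 1 - \sum_i P_i^2}, the probability that two random draws from
#' the community are different taxa. Zero for a single taxon, at most
#' \eqn{1 - 1/k} for richness \eqn{k}; weights dominant taxa more heavily
#' than the Shannon index.
#'
#' @param x a [TECommunity-class].
#' @return Gini-Simpson index in `[0, 1)`.
#' @examples
#' giniSimpsonIndex(teCommunity(c("a", "b"), c(1, 1)))  # 0.5
#' @export
giniSimpsonIndex <- function(x) {
    p <- taxonProportions(x)
    1 - sum(p^2)
}

#' Diversity summary of one community
#'
#' @param x a [TECommunity-class].
#' @return data.frame with `shannon` (nats), `gini_simpson`, `richness`.
#' @export
diversitySummary <- function(x) {
    data.frame(shannon = shannonIndex(x), gini_simpson = giniSimpsonIndex(x),
               richness = richness(x))
}

#' Compare TE diversity across genomes
#'
#' One diversity row per genome plus Spearman rank correlations of genome
#' size against each index (testing for a size--diversity relationship
#' across taxa, robust to the very different scales involved).
#'
#' @param communities named list of [TECommunity-class] objects (unique
#'   names).
#' @param genomeSizeGb numeric vector of genome sizes, parallel to
#'   `communities`.
#' @return list with `table` (name, genome_size_gb, shannon,
#'   gini_simpson, richness) and `correlation` (index, spearman_rho,
#'   p_value from two-sided tests).
#' @export
compareGenomes <- function(communities, genomeSizeGb) {
    if (length(communities) < 2L)
        .stopf("need at least two communities")
    nm <- names(communities)
    if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
        .stopf("communities must have unique non-empty names")
    if (length(genomeSizeGb) != length(communities))
        .stopf("genomeSizeGb must parallel communities")
    tab <- do.call(rbind, lapply(seq_along(communities), function(i)
        cbind(data.frame(name = nm[i], genome_size_gb = genomeSizeGb[i]),
              diversitySummary(communities[[i]]))))
    rownames(tab) <- NULL
    corRow <- function(index) {
        ct <- suppressWarnings(stats::cor.test(
            tab$genome_size_gb, tab[[index]], method = "spearman",
            alternative = "two.sided", exact = FALSE))
        data.frame(index = index, spearman_rho = unname(ct$estimate),
                   p_value = ct$p.value)
    }
    list(table = tab,
         correlation = rbind(corRow("shannon"), corRow("gini_simpson")))
}
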