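# Contingency counts between two partitions over the same universe.
contingency <- function(p, q) {
  if (!setequal(p$id, q$id)) {
    stop_universe("partitions are over different id universes")
  }
  qa <- q$cluster[match(p$id, q$id)]
  tab <- table(p$cluster, qa)
  matrix(tab, nrow = nrow(tab))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-adjusted pair-counting agreement: 1 means identical partitions
#' (up to label permutation), values near 0 mean the assignments are no more
#' similar than random. Computed from the contingency table via
#' (sum_ij C(n_ij,2) - E) / (0.5 [sum_i C(a_i,2) + sum_j C(b_j,2)] - E) with
#' E the expectation under random pairing.
#'
#' @param p,q Partition tibbles (`id`, `cluster`) over the same universe.
#' @return A number in \[-1, 1\].
#' @export
ari <- function(p, q) {
  n <- nrow(p)
  tab <- contingency(p, q)
  a <- rowSums(tab)
  b <- colSums(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(1)  # both partitions trivial
  (sum_ij - expected) / denom
}

entropy_counts <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

# Expected mutual information under the permutation (hypergeometric) model;
# log-space factorials guard against overflow for large marginals.
expected_mi <- function(a, b, n) {
  emi <- 0
  lfac <- lfactorial
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      log_p <- lfac(ai) + lfac(bj) + lfac(n - ai) + lfac(n - bj) -
        lfac(n) - lfac(nij) - lfac(ai - nij) - lfac(bj - nij) -
        lfac(n - ai - bj + nij)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(log_p))
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected for chance under the permutation model and
#' normalized by the arithmetic mean of the two partition entropies:
#' AMI = (I - E\[I\]) / (mean(H(p), H(q)) - E\[I\]). Identical partitions
#' score exactly 1; independent partitions score near 0. Two single-cluster
#' (or two all-singleton) partitions are a degenerate case and return 1.
#'
#' @inheritParams ari
#' @return A number no greater than 1.
#' @export
ami <- function(p, q) {
  n <- nrow(p)
  # identical groupings score exactly 1, bypassing EMI round-off
  cp <- canonical_labels(p)
  cq <- canonical_labels(q)
  if (identical(cp$cluster[order(cp$id)], cq$cluster[order(cq$id)])) {
    return(1)
  }
  tab <- contingency(p, q)
  a <- rowSums(tab)
  b <- colSums(tab)
  ha <- entropy_counts(a)
  hb <- entropy_counts(b)
  if (ha == 0 && hb == 0) return(1)
  nz <- which(tab > 0, arr.ind = TRUE)
  mi <- sum(vapply(seq_len(nrow(nz)), function(k) {
    nij <- tab[nz[k, 1], nz[k, 2]]
    nij / n * log(n * nij / (a[nz[k, 1]] * b[nz[k, 2]]))
  }, numeric(1)))
  emi <- expected_mi(a, b, n)
  denom <- (ha + hb) / 2 - emi
  if (denom == 0) return(0)
  (mi - emi) / denom
}

#' Agreement sweep across two cluster hierarchies
#'
#' Computes ARI and AMI for every pair of levels of two hierarchies (e.g.
#' homology cut-offs against K-means cut-offs), the standard way to compare
#' cluster definitions generated at a range of cut-offs for each pair of
#' methods. Partitions must share one id universe — project representative
#' labels back to members first where needed.
#'
#' @param hier_a,hier_b `cluster_hierarchy` objects (or named lists of
#'   partition tibbles) over the same id universe.
#' @return Tibble with columns `level_a`, `level_b`, `ari`, `ami`,
#'   `n_clusters_a`, `n_clusters_b`, in deterministic level order.
#' @export
agreement_sweep <- function(hier_a, hier_b) {
  la <- if (inherits(hier_a, "cluster_hierarchy")) hier_a$levels else hier_a
  lb <- if (inherits(hier_b, "cluster_hierarchy")) hier_b$levels else hier_b
  grid <- tidyr::expand_grid(level_a = names(la), level_b = names(lb))
  purrr::pmap_dfr(grid, function(level_a, level_b) {
    p <- la[[level_a]]
    q <- lb[[level_b]]
    tibble(
      level_a = level_a, level_b = level_b,
      ari = ari(p, q), ami = ami(p, q),
      n_clusters_a = n_distinct(p$cluster),
      n_clusters_b = n_distinct(q$cluster)
    )
  })
}
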