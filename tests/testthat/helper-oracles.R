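# Independent oracles and small generators shared across tests. Everything
# here is deliberately naive (quadratic/cubic) and written without touching
# the package's own code paths, so agreement is evidence, not tautology.

# seeded random graph over n nodes with ~m edges, bitscores in [lo, hi]
random_graph <- function(n, m, seed, lo = 50, hi = 300) {
  set.seed(seed)
  ids <- sprintf("n%05d", seq_len(n))
  a <- sample(ids, m, replace = TRUE)
  b <- sample(ids, m, replace = TRUE)
  keep <- a != b
  tibble::tibble(
    id1 = pmin(a[keep], b[keep]), id2 = pmax(a[keep], b[keep]),
    bitscore = runif(sum(keep), lo, hi)
  ) |>
    dplyr::distinct(id1, id2, .keep_all = TRUE) |>
    dplyr::arrange(id1, id2)
}

# connected components via igraph (independent in-memory oracle),
# canonically labeled by smallest member id
oracle_components <- function(edges, nodes, cutoff) {
  keep <- edges$bitscore >= cutoff
  g <- igraph::graph_from_data_frame(
    edges[keep, c("id1", "id2")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)$membership
  canon <- tapply(names(comp), comp, min)
  tibble::tibble(id = nodes,
                 cluster = as.vector(canon[as.character(comp[nodes])])) |>
    dplyr::arrange(id)
}

partition_equal <- function(p, q) {
  pp <- dplyr::arrange(tibble::as_tibble(p[c("id", "cluster")]), id)
  qq <- dplyr::arrange(tibble::as_tibble(q[c("id", "cluster")]), id)
  identical(pp$id, qq$id) &&
    identical(unname(pp$cluster), unname(qq$cluster))
}

# naive single linkage over a distance matrix: returns sorted merge heights
naive_single_linkage_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (j <= i) next
        d <- min(D[active[[i]], active[[j]]])
        if (d < best[1]) best <- c(d, i, j)
      }
    }
    heights <- c(heights, best[1])
    active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
    active[[best[3]]] <- NULL
  }
  sort(heights)
}

# naive WPGMA: distance of a merged cluster to others is the plain average
# of its two parts' distances; returns merge heights in merge order
naive_wpgma_heights <- function(D) {
  n <- nrow(D)
  act <- seq_len(n)
  heights <- numeric(0)
  while (length(act) > 1) {
    sub <- D[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    k <- arrayInd(which.min(sub), dim(sub))
    i <- act[k[1]]; j <- act[k[2]]
    heights <- c(heights, D[i, j])
    newd <- (D[i, ] + D[j, ]) / 2
    D[i, ] <- newd; D[, i] <- newd; D[i, i] <- 0
    act <- setdiff(act, j)
  }
  heights
}

# brute-force AMI pieces from a contingency table, via choose() products
# (a formulation independent of the package's log-factorial version)
oracle_ami_from_tab <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
  }
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    for (nij in max(1, a[i] + b[j] - n):min(a[i], b[j])) {
      p <- choose(b[j], nij) * choose(n - b[j], a[i] - nij) /
        choose(n, a[i])
      emi <- emi + nij / n * log(n * nij / (a[i] * b[j])) * p
    }
  }
  h <- function(x) { p <- x[x > 0] / sum(x); -sum(p * log(p)) }
  unname((mi - emi) / ((h(a) + h(b)) / 2 - emi))
}

random_partition <- function(ids, k, seed) {
  set.seed(seed)
  tibble::tibble(id = ids,
                 cluster = sample(paste0("c", seq_len(k)), length(ids),
                                  replace = TRUE))
}

# brute-force max root-to-leaf path length under each node of a phylo
phylo_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

# random amino-acid sequence and point mutants (independent of the
# package's fixture generator)
rand_seq <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

mutate_seq <- function(s, k) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(aa, ch[p]), 1)
  paste(ch, collapse = "")
}
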