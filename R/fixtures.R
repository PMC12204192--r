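AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

mutate_protein <- function(residues, rate) {
  if (rate <= 0) return(residues)
  chars <- strsplit(residues, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Synthetic m8 edge bands around a planted partition
#'
#' Draws bitscores from two well-separated normal bands: a high band for
#' within-cluster pairs (every within pair gets an edge, up to an optional
#' cap that preserves connectivity) and a low band for a sparse sample of
#' between-cluster pairs. Scores are truncated at zero. The bands must be
#' separable (means more than 3 SDs apart), so that any threshold between
#' them recovers the planted partition exactly.
#'
#' @param partition Partition tibble (`id`, `cluster`).
#' @param within_mu,within_sd High-band mean and SD (within clusters).
#' @param between_mu,between_sd Low-band mean and SD (between clusters).
#' @param between_prob Fraction of eligible between-cluster pairs that get
#'   an edge.
#' @param within_parent Optional coarser partition; between-cluster edges
#'   are drawn only for pairs sharing a parent cluster (pairs in different
#'   parents get no edge, emulating the E-value significance filter).
#' @param max_within_pairs Per-cluster cap on within edges; above it a
#'   connected random subset (spanning chain plus random extras) is used.
#' @param seed Integer seed.
#' @param path Optional path; when given, edges are also written as a
#'   12-column m8 file.
#' @return Edge tibble (`id1`, `id2`, `bitscore`), normalized ordering.
#' @export
make_edge_bands <- function(partition, within_mu = 250, within_sd = 15,
                            between_mu = 120, between_sd = 15,
                            between_prob = 0.05, within_parent = NULL,
                            max_within_pairs = 20000L, seed = 1L,
                            path = NULL) {
  if (within_mu - 3 * within_sd <= between_mu + 3 * between_sd) {
    stop_parameter("within and between bitscore bands must be separable")
  }
  set.seed(seed)
  ids <- partition$id
  clus <- split(ids, partition$cluster)

  within <- purrr::map_dfr(clus, function(members) {
    members <- sort(members)
    n <- length(members)
    if (n < 2) return(NULL)
    if (choose(n, 2) <= max_within_pairs) {
      pr <- t(combn(members, 2))
    } else {
      chain <- cbind(members[-n], members[-1])
      extra <- cbind(sample(members, max_within_pairs, replace = TRUE),
                     sample(members, max_within_pairs, replace = TRUE))
      extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
      pr <- unique(rbind(chain,
                         t(apply(extra, 1, sort))))
    }
    tibble(id1 = pr[, 1], id2 = pr[, 2],
           bitscore = pmax(0, rnorm(nrow(pr), within_mu, within_sd)))
  })

  parent_of <- if (is.null(within_parent)) {
    setNames(rep("all", length(ids)), ids)
  } else {
    setNames(within_parent$cluster[match(ids, within_parent$id)], ids)
  }
  cluster_of <- setNames(partition$cluster, ids)
  n_between <- ceiling(between_prob * length(ids) * 4)
  cand <- tibble(
    id1 = sample(ids, n_between, replace = TRUE),
    id2 = sample(ids, n_between, replace = TRUE)
  ) |>
    filter(.data$id1 != .data$id2,
           cluster_of[.data$id1] != cluster_of[.data$id2],
           parent_of[.data$id1] == parent_of[.data$id2]) |>
    mutate(a = pmin(.data$id1, .data$id2), b = pmax(.data$id1, .data$id2)) |>
    distinct(.data$a, .data$b)
  # spanning chain across the clusters of each parent group, so the low
  # (between-band) cut-off reliably reunites them into one component
  anchors <- partition |>
    group_by(.data$cluster) |>
    summarise(anchor = min(.data$id), .groups = "drop") |>
    mutate(parent = parent_of[.data$anchor]) |>
    arrange(.data$parent, .data$anchor)
  chain <- anchors |>
    group_by(.data$parent) |>
    dplyr::reframe(id1 = head(.data$anchor, -1),
                   id2 = tail(.data$anchor, -1)) |>
    select("id1", "id2")
  bpairs <- bind_rows(tibble(id1 = cand$a, id2 = cand$b), chain) |>
    mutate(a = pmin(.data$id1, .data$id2), b = pmax(.data$id1, .data$id2)) |>
    distinct(.data$a, .data$b)
  between <- tibble(id1 = bpairs$a, id2 = bpairs$b,
                    bitscore = pmax(0, rnorm(nrow(bpairs), between_mu,
                                             between_sd)))

  edges <- bind_rows(within, between) |>
    group_by(.data$id1, .data$id2) |>
    summarise(bitscore = max(.data$bitscore), .groups = "drop") |>
    arrange(.data$id1, .data$id2)
  if (!is.null(path)) write_m8(edges, path)
  edges
}

#' Write edges as a 12-column m8 file
#'
#' Emits the standard tabular hit format with placeholder alignment columns
#' (identity, length, positions) and a significant E-value, suitable for
#' exercising any m8 consumer.
#'
#' @param edges Edge tibble (`id1`, `id2`, `bitscore`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_m8 <- function(edges, path) {
  lines <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.1e\t%.1f",
                   edges$id1, edges$id2, 0.5, 150L, 70L, 3L, 1L, 150L, 1L,
                   150L, 1e-50, edges$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Generate a planted two-level sequence world
#'
#' Builds a complete, internally consistent synthetic dataset for the whole
#' pipeline: sequences with planted superfamily/family structure (family
#' centers are point-mutated superfamily ancestors; members are point-
#' mutated family centers), banded homology edges (high within-family band,
#' intermediate within-superfamily band, no cross-superfamily edges),
#' matching hierarchical embedding vectors, and per-family function and
#' genus annotations. Everything derives from the seed, so any acceptance
#' input is reproducible from (parameters, seed) alone.
#'
#' @param n_super Superfamilies.
#' @param fam_per_super Families per superfamily.
#' @param members_per_fam Members per family.
#' @param seq_len_range Ancestor length range (residues).
#' @param mut_rate_within Per-site substitution rate member vs family
#'   center; must be below `mut_rate_between`.
#' @param mut_rate_between Per-site substitution rate family center vs
#'   superfamily ancestor.
#' @param within_mu,between_mu Bitscore band means (within family /
#'   within superfamily).
#' @param band_sd Bitscore band standard deviation.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, FASTA, m8, vectors and truth
#'   tables are written there.
#' @return A list of class `planted_world`: `sequences`, `truth`, `edges`,
#'   `store` (an [edge_store()]), `embeddings`, `annotations`, `seed`.
#' @export
make_world <- function(n_super = 4L, fam_per_super = 3L,
                       members_per_fam = 20L, seq_len_range = c(120L, 280L),
                       mut_rate_within = 0.05, mut_rate_between = 0.3,
                       within_mu = 250, between_mu = 120, band_sd = 15,
                       seed = 1L, dir = NULL) {
  if (mut_rate_within >= mut_rate_between) {
    stop_parameter("mut_rate_within must be below mut_rate_between")
  }
  set.seed(seed)
  genus_pool <- c("Bacillus", "Escherichia", "Pseudomonas", "Streptomyces",
                  "Mycobacterium", "Synechocystis", "Thermus", "Vibrio",
                  "Rhodococcus", "Halobacterium", "Clostridium", "Nostoc")
  fun_pool <- c("biosynthesis", "oxidative_protection",
                "nutrient_scavenging", "flavin_supply", "regulation")
  rows <- list()
  for (s in seq_len(n_super)) {
    anc_len <- sample(seq(seq_len_range[1], seq_len_range[2]), 1)
    ancestor <- random_protein(anc_len)
    for (f in seq_len(fam_per_super)) {
      center <- mutate_protein(ancestor, mut_rate_between)
      fam_id <- sprintf("S%02dF%02d", s, f)
      fam_fun <- sample(fun_pool, 1)
      fam_genera <- sample(genus_pool, sample(1:3, 1))
      for (m in seq_len(members_per_fam)) {
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("%sM%03d", fam_id, m),
          superfamily = sprintf("S%02d", s),
          family = fam_id,
          residues = mutate_protein(center, mut_rate_within),
          fun = fam_fun,
          taxon_genus = sample(fam_genera, 1)
        )
      }
    }
  }
  tbl <- bind_rows(rows)
  truth <- tbl |> select("id", "superfamily", "family")
  sequences <- tbl |>
    mutate(description = paste0("planted ", .data$family)) |>
    select("id", "description", "residues")
  annotations <- tbl |> select("id", "fun", "taxon_genus")

  edges <- make_edge_bands(
    partition = tibble(id = truth$id, cluster = truth$family),
    within_mu = within_mu, within_sd = band_sd,
    between_mu = between_mu, between_sd = band_sd,
    within_parent = tibble(id = truth$id, cluster = truth$superfamily),
    between_prob = 0.1,
    seed = derive_seed(seed, "edges")
  )
  emb <- synth_embeddings(
    n_super = n_super, fam_per_super = fam_per_super,
    members_per_fam = members_per_fam,
    seed = derive_seed(seed, "embeddings")
  )
  stopifnot(identical(emb$truth$family, truth$family))

  world <- structure(
    list(sequences = sequences, truth = truth, edges = edges,
         store = edge_store(edges, nodes = truth$id),
         embeddings = emb$embeddings, annotations = annotations,
         seed = seed),
    class = "planted_world"
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sequences, file.path(dir, "sequences.fasta"))
    write_m8(edges, file.path(dir, "edges.m8"))
    write_embeddings(world$embeddings, file.path(dir, "vectors.tsv"))
    readr::write_tsv(truth, file.path(dir, "truth.tsv"))
    readr::write_tsv(annotations, file.path(dir, "annotations.tsv"))
  }
  world
}

#' @export
print.planted_world <- function(x, ...) {
  cat("<planted_world> ", nrow(x$sequences), " sequences, ",
      n_distinct(x$truth$superfamily), " superfamilies x ",
      n_distinct(x$truth$family) / n_distinct(x$truth$superfamily),
      " families, ", nrow(x$edges), " edges (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
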