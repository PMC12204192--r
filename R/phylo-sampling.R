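#' Sampling specification for even sequence-space sampling
#'
#' Defaults follow the tree-building protocol: walk neighborhoods starting
#' at bitscore 150, sample one representative from every cluster holding
#' 100-1,000 sequences, split larger clusters at +10-bitscore steps up to
#' 400, keep representatives of 100-300 residues, and (when anchor ids are
#' given) visit only descendants of the anchor-containing parent
#' neighborhoods at bitscore 102.
#'
#' @param base_cutoff First bitscore cut-off visited.
#' @param step Bitscore increment when recursing into oversized clusters.
#' @param max_cutoff Last cut-off; clusters still oversized here contribute
#'   one representative flagged `unresolved_at_max_cutoff`.
#' @param size_window Cluster-size window `c(min, max)` that triggers
#'   sampling.
#' @param length_window Representative length window in residues.
#' @param anchor_ids Optional sequence ids anchoring the walk.
#' @param anchor_level Bitscore at which anchor parent neighborhoods are
#'   taken.
#' @param method Representative selection: `"vector"` or `"hmm"` (fallback
#'   profile engine).
#' @return A list of class `sampling_spec`.
#' @export
sampling_spec <- function(base_cutoff = 150, step = 10, max_cutoff = 400,
                          size_window = c(100, 1000),
                          length_window = c(100, 300),
                          anchor_ids = NULL, anchor_level = 102,
                          method = c("vector", "hmm")) {
  method <- match.arg(method)
  if (size_window[1] >= size_window[2] ||
      length_window[1] >= length_window[2]) {
    stop_parameter("window minima must be below their maxima")
  }
  if (step <= 0 || base_cutoff > max_cutoff) {
    stop_parameter("need step > 0 and base_cutoff <= max_cutoff")
  }
  structure(
    list(base_cutoff = base_cutoff, step = step, max_cutoff = max_cutoff,
         size_window = size_window, length_window = length_window,
         anchor_ids = anchor_ids, anchor_level = anchor_level,
         method = method),
    class = "sampling_spec"
  )
}

choose_representative <- function(member_ids, sequences, embeddings, method) {
  if (length(member_ids) == 1) return(member_ids)
  if (method == "vector") {
    if (is.null(embeddings)) {
      stop_parameter("vector representative selection needs embeddings")
    }
    vector_representative(member_ids, embeddings)$representative
  } else {
    sub <- sequences[sequences$id %in% member_ids, , drop = FALSE]
    hmm_representative(sub, engine = "fallback")$representative
  }
}

#' Evenly sample representatives across sequence space
#'
#' Walks the homology cluster hierarchy from `base_cutoff` upward: clusters
#' whose size falls inside the size window contribute exactly one
#' representative; larger clusters are re-examined at the next (+step)
#' cut-off so that dense regions are split until they fit; clusters below
#' the window are skipped. Clusters still oversized at `max_cutoff` yield a
#' single flagged representative rather than leaving that region of
#' sequence space unsampled. Representatives with lengths outside the
#' length window are excluded and logged. The walk is deterministic:
#' clusters are visited in canonical id order.
#'
#' @param store An [edge_store()].
#' @param spec A [sampling_spec()].
#' @param sequences Tibble (`id`, `residues`) covering the store's universe.
#' @param embeddings Optional [embedding_matrix()] (required for
#'   `method = "vector"`).
#' @param chunk_edges Streaming chunk size for the components pass.
#' @return A `sample_report`: list with `chosen` (tibble `id`, `cluster`,
#'   `cutoff`, `size`, `note`) and `skipped` (tibble `cluster`, `cutoff`,
#'   `size`, `reason`).
#' @export
even_sample <- function(store, spec, sequences, embeddings = NULL,
                        chunk_edges = 1e6L) {
  stopifnot(inherits(spec, "sampling_spec"))
  cuts <- seq(spec$base_cutoff, spec$max_cutoff, by = spec$step)
  use_anchor <- !is.null(spec$anchor_ids)
  all_cuts <- if (use_anchor) sort(unique(c(spec$anchor_level, cuts))) else cuts
  hier <- components_multi(store, all_cuts, chunk_edges = chunk_edges)
  level_of <- function(c) paste0("bitscore:", format(c, trim = TRUE))

  allowed <- store$ids
  if (use_anchor) {
    missing <- setdiff(spec$anchor_ids, store$ids)
    if (length(missing) > 0) {
      stop_coverage(paste0("anchor id(s) not in the universe: ",
                           paste(head(missing, 5), collapse = ", ")))
    }
    anchor_part <- hier$levels[[level_of(spec$anchor_level)]]
    anchor_clusters <- unique(
      anchor_part$cluster[anchor_part$id %in% spec$anchor_ids])
    allowed <- anchor_part$id[anchor_part$cluster %in% anchor_clusters]
  }

  seq_len_of <- setNames(nchar(sequences$residues), sequences$id)
  chosen <- list()
  skipped <- list()

  take_rep <- function(members, cluster, cutoff, note) {
    rep_id <- choose_representative(members, sequences, embeddings,
                                    spec$method)
    if (seq_len_of[rep_id] < spec$length_window[1] ||
        seq_len_of[rep_id] > spec$length_window[2]) {
      skipped[[length(skipped) + 1L]] <<- tibble(
        cluster = cluster, cutoff = cutoff, size = length(members),
        reason = "rep_length_out_of_window")
    } else {
      chosen[[length(chosen) + 1L]] <<- tibble(
        id = rep_id, cluster = cluster, cutoff = cutoff,
        size = length(members), note = note)
    }
  }

  visit <- function(members, k) {
    part <- hier$levels[[level_of(cuts[k])]]
    sub <- part[part$id %in% members, , drop = FALSE]
    for (cl in sort(unique(sub$cluster))) {
      mem <- sub$id[sub$cluster == cl]
      n <- length(mem)
      if (n < spec$size_window[1]) {
        skipped[[length(skipped) + 1L]] <<- tibble(
          cluster = cl, cutoff = cuts[k], size = n, reason = "too_small")
      } else if (n <= spec$size_window[2]) {
        take_rep(mem, cl, cuts[k], NA_character_)
      } else if (k == length(cuts)) {
        take_rep(mem, cl, cuts[k], "unresolved_at_max_cutoff")
      } else {
        visit(mem, k + 1L)
      }
    }
  }
  visit(allowed, 1L)

  structure(
    list(
      chosen = if (length(chosen)) bind_rows(chosen) else
        tibble(id = character(), cluster = character(), cutoff = numeric(),
               size = integer(), note = character()),
      skipped = if (length(skipped)) bind_rows(skipped) else
        tibble(cluster = character(), cutoff = numeric(), size = integer(),
               reason = character()),
      spec = spec
    ),
    class = "sample_report"
  )
}

#' @export
print.sample_report <- function(x, ...) {
  cat("<sample_report> ", nrow(x$chosen), " representatives chosen, ",
      nrow(x$skipped), " clusters skipped\n", sep = "")
  if (nrow(x$skipped) > 0) {
    tab <- table(x$skipped$reason)
    for (r in names(tab)) cat("  skipped ", r, ": ", tab[[r]], "\n", sep = "")
  }
  invisible(x)
}

#' Compare sequence-space coverage of two samples
#'
#' Measures how much of the cluster landscape a second sample reaches that a
#' first one does not: the fraction of `sample_b` ids whose cluster contains
#' no `sample_a` id.
#'
#' @param sample_a,sample_b Character vectors of sequence ids (must be in
#'   the partition universe).
#' @param partition Partition tibble (`id`, `cluster`).
#' @return One-row tibble: `clusters_a`, `clusters_b`, `b_only_fraction`.
#' @export
coverage_compare <- function(sample_a, sample_b, partition) {
  miss <- setdiff(c(sample_a, sample_b), partition$id)
  if (length(miss) > 0) {
    stop_universe(paste0("sample id(s) outside the partition universe: ",
                         paste(head(miss, 5), collapse = ", ")))
  }
  cl_a <- unique(partition$cluster[partition$id %in% sample_a])
  cl_b_per_id <- partition$cluster[match(sample_b, partition$id)]
  tibble(
    clusters_a = length(cl_a),
    clusters_b = length(unique(cl_b_per_id)),
    b_only_fraction = mean(!(cl_b_per_id %in% cl_a))
  )
}
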