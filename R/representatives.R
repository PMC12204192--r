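blosum62 <- function() {
  # lazy data load from Biostrings
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

clean_residues <- function(x) {
  # strip alignment gaps; selenocysteine has no BLOSUM62 column, score as X
  chartr("U", "X", gsub("-", "", toupper(x), fixed = TRUE))
}

#' Global percent identity between two protein sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps: open 11,
#' extend 1); identity is the number of identical aligned positions divided
#' by the full alignment length (gap columns, including terminal gaps,
#' count), times 100. This convention affects absolute values, not
#' orderings, and is applied uniformly across the package.
#'
#' @param a,b Amino-acid strings.
#' @return Percent identity in \[0, 100\].
#' @export
global_identity <- function(a, b) {
  identity_to_ref(a, b)[1]
}

# vectorized: identity of each sequence in `many` to the single `ref`
identity_to_ref <- function(many, ref) {
  many <- clean_residues(many)
  ref <- clean_residues(ref)
  if (any(!nzchar(many)) || !nzchar(ref)) {
    stop_empty_input("sequences must be non-empty")
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(many), Biostrings::AAString(ref),
    substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1, type = "global"
  )
  width <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / width
}

# full pairwise identity matrix for one cluster (quadratic; cluster-scale)
pairwise_identity_matrix <- function(residues, ids) {
  n <- length(residues)
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n - 1)) {
    vals <- identity_to_ref(residues[(j + 1):n], residues[j])
    M[(j + 1):n, j] <- vals
    M[j, (j + 1):n] <- vals
  }
  M
}

run_mafft <- function(sequences, quiet = TRUE) {
  exe <- Sys.which("mafft")
  if (!nzchar(exe)) stop_tool_not_found("executable not found: mafft")
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  write_fasta(sequences, fin)
  status <- system2(exe, c("--quiet", shQuote(fin)), stdout = fout,
                    stderr = if (quiet) FALSE else "")
  if (status != 0) stop_external_tool("mafft failed")
  aln <- read_fasta(fout)
  tibble(id = aln$id, aligned = toupper(aln$residues))
}

# Position-specific scoring from an MSA: match columns are those with < 50%
# gaps; per-column amino-acid probabilities use a Laplace pseudocount of 1
# against a uniform background of 1/20; a member's score is the sum of its
# match-column log-odds (gaps contribute 0).
profile_scores <- function(msa) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  mat <- do.call(rbind, strsplit(msa$aligned, ""))
  gaps <- colMeans(mat == "-")
  match_cols <- which(gaps < 0.5)
  scores <- setNames(numeric(nrow(mat)), msa$id)
  for (j in match_cols) {
    col <- mat[, j]
    counts <- table(factor(col[col %in% aa], levels = aa))
    p <- (as.numeric(counts) + 1) / (sum(counts) + 20)
    logodds <- setNames(log(p / (1 / 20)), aa)
    known <- col %in% aa
    scores[known] <- scores[known] + logodds[col[known]]
  }
  scores
}

parse_hmmer_tblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(tibble(id = character(), score = numeric()))
  parts <- strsplit(trimws(lines), "\\s+")
  tibble(
    id = vapply(parts, `[`, character(1), 1),
    score = as.numeric(vapply(parts, `[`, character(1), 6))
  )
}

#' Select a cluster representative with a profile HMM
#'
#' Builds a profile from the cluster's multiple sequence alignment and
#' returns the member scoring highest against it — the sequence closest to
#' the cluster consensus. With `engine = "external"` the HMMER3 toolchain is
#' used (mafft alignment, `hmmbuild`, `hmmsearch`; full-sequence bitscore).
#' With `engine = "fallback"` a pure position-specific log-odds profile is
#' scored instead (match columns = columns with < 50% gaps, Laplace
#' pseudocount 1, uniform background), so tests and air-gapped runs need no
#' external binaries when sequences are already aligned or equal-length.
#' External and fallback scores use different scales and must not be mixed
#' in one report.
#'
#' @param sequences Cluster tibble (`id`, `residues`).
#' @param engine `"fallback"` or `"external"`.
#' @param msa Optional precomputed alignment tibble (`id`, `aligned`).
#' @return One-row tibble: `representative`, `method`, `engine`, `score`.
#' @export
hmm_representative <- function(sequences, engine = c("fallback", "external"),
                               msa = NULL) {
  engine <- match.arg(engine)
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  if (nrow(sequences) == 1) {
    return(tibble(representative = sequences$id, method = "hmm",
                  engine = engine, score = 0))
  }
  if (engine == "fallback") {
    if (is.null(msa)) {
      msa <- if (n_distinct(nchar(sequences$residues)) == 1) {
        tibble(id = sequences$id, aligned = toupper(sequences$residues))
      } else {
        run_mafft(sequences)
      }
    }
    scores <- profile_scores(msa)
  } else {
    for (exe in c("hmmbuild", "hmmsearch")) {
      if (!nzchar(Sys.which(exe))) {
        stop_tool_not_found(paste0("executable not found: ", exe))
      }
    }
    msa <- msa %||% run_mafft(sequences)
    msa_file <- tempfile(fileext = ".afa")
    write_fasta(tibble(id = msa$id, residues = msa$aligned), msa_file)
    hmm_file <- tempfile(fileext = ".hmm")
    seq_file <- tempfile(fileext = ".fasta")
    tbl_file <- tempfile(fileext = ".tbl")
    write_fasta(sequences, seq_file)
    if (system2(Sys.which("hmmbuild"),
                c("--amino", shQuote(hmm_file), shQuote(msa_file)),
                stdout = FALSE, stderr = FALSE) != 0) {
      stop_external_tool("hmmbuild failed")
    }
    if (system2(Sys.which("hmmsearch"),
                c("--tblout", shQuote(tbl_file), "--max", "-E", "1e6",
                  shQuote(hmm_file), shQuote(seq_file)),
                stdout = FALSE, stderr = FALSE) != 0) {
      stop_external_tool("hmmsearch failed")
    }
    hits <- parse_hmmer_tblout(tbl_file)
    scores <- setNames(rep(-Inf, nrow(sequences)), sequences$id)
    scores[hits$id] <- hits$score
  }
  ord <- order(-scores[sequences$id], sequences$id)
  best <- sequences$id[ord][1]
  tibble(representative = best, method = "hmm", engine = engine,
         score = unname(scores[best]))
}

#' Select a cluster representative nearest the embedding centroid
#'
#' Averages the member vectors and returns the member whose vector is
#' closest (Euclidean) to that mean; ties break to the smaller id.
#'
#' @param ids Cluster member ids.
#' @param embeddings An [embedding_matrix()] covering every member.
#' @return One-row tibble: `representative`, `method`, `score` (negative
#'   distance to the centroid).
#' @export
vector_representative <- function(ids, embeddings) {
  miss <- setdiff(ids, rownames(embeddings))
  if (length(miss) > 0) {
    stop_coverage(paste0("no vector for member(s): ",
                         paste(head(miss, 5), collapse = ", ")))
  }
  x <- unclass(embeddings)[ids, , drop = FALSE]
  ctr <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, ctr, `-`)^2))
  ord <- order(d, ids)
  tibble(representative = ids[ord][1], method = "vector",
         score = -unname(d[ord][1]))
}

#' Evaluate how well a representative stands for its cluster
#'
#' Three complementary metrics. `delta_id`: median %ID of members to the
#' representative minus the median %ID of (seeded, capped) random member
#' pairs — positive means the representative is closer to the cluster than
#' chance. `rank`: the percentile rank in \[0, 1\] of the representative's
#' median %ID among every member's median %ID to the rest of the cluster
#' (1 = most central member). `length_delta`: representative length minus
#' the median member length.
#'
#' @param sequences Cluster tibble (`id`, `residues`), at least 2 rows.
#' @param representative Id of the chosen representative (must be a member).
#' @param sample_pairs Cap on random member pairs for the baseline median.
#' @param seed Seed for the pair sampling.
#' @return One-row tibble: `delta_id`, `rank`, `length_delta`, `n_members`.
#' @export
evaluate_representative <- function(sequences, representative,
                                    sample_pairs = 10000L, seed = 1L) {
  stopifnot(nrow(sequences) >= 2, representative %in% sequences$id)
  ids <- sequences$id
  M <- pairwise_identity_matrix(sequences$residues, ids)
  others <- setdiff(ids, representative)
  rep_median <- median(M[others, representative])
  all_pairs <- which(upper.tri(M), arr.ind = TRUE)
  set.seed(seed)
  take <- if (nrow(all_pairs) > sample_pairs) {
    all_pairs[sample.int(nrow(all_pairs), sample_pairs), , drop = FALSE]
  } else {
    all_pairs
  }
  random_median <- median(M[take])
  member_medians <- vapply(ids, function(i) {
    median(M[setdiff(ids, i), i])
  }, numeric(1))
  tibble(
    delta_id = rep_median - random_median,
    rank = mean(member_medians <= member_medians[representative]),
    length_delta = nchar(sequences$residues[ids == representative]) -
      median(nchar(sequences$residues)),
    n_members = length(ids)
  )
}

#' Per-cluster property statistics
#'
#' For every cluster of at least `min_size` members: size, the median
#' global %ID of (sampled) within-cluster pairs, the median %ID of sampled
#' pairs straddling the cluster boundary, and the number of distinct genera
#' among members. The standard view of how cluster coherence and taxonomic
#' diversity change across clustering cut-offs.
#'
#' @param partition Partition tibble (`id`, `cluster`).
#' @param sequences Tibble (`id`, `residues`) covering the partition.
#' @param annotations Optional tibble with `id` and `taxon_genus`.
#' @param min_size Minimum cluster size considered.
#' @param sample_pairs Per-cluster cap on sampled pairs.
#' @param seed Seed for pair sampling.
#' @return Tibble: `cluster`, `size`, `within_id_median`,
#'   `between_id_median`, `n_genera`.
#' @export
cluster_properties <- function(partition, sequences, annotations = NULL,
                               min_size = 5L, sample_pairs = 100L,
                               seed = 1L) {
  res <- sequences$residues[match(partition$id, sequences$id)]
  if (anyNA(res)) stop_coverage("sequences missing for some partition ids")
  sizes <- count(partition, .data$cluster, name = "size")
  keep <- sizes$cluster[sizes$size >= min_size]
  purrr::map_dfr(sort(keep), function(cl) {
    inside <- which(partition$cluster == cl)
    outside <- which(partition$cluster != cl)
    set.seed(derive_seed(seed, cl))
    n_in <- min(sample_pairs, choose(length(inside), 2))
    wpairs <- matrix(nrow = 0, ncol = 2)
    if (n_in > 0) {
      wpairs <- unique(t(replicate(n_in, sort(sample(inside, 2)))))
    }
    within <- vapply(seq_len(nrow(wpairs)), function(k) {
      identity_to_ref(res[wpairs[k, 1]], res[wpairs[k, 2]])
    }, numeric(1))
    between <- numeric(0)
    if (length(outside) > 0) {
      n_bt <- min(sample_pairs, length(inside) * length(outside))
      bpairs <- cbind(sample(inside, n_bt, replace = TRUE),
                      sample(outside, n_bt, replace = TRUE))
      between <- vapply(seq_len(nrow(bpairs)), function(k) {
        identity_to_ref(res[bpairs[k, 1]], res[bpairs[k, 2]])
      }, numeric(1))
    }
    n_gen <- 0L
    if (!is.null(annotations) && "taxon_genus" %in% names(annotations)) {
      g <- annotations$taxon_genus[match(partition$id[inside],
                                         annotations$id)]
      n_gen <- n_distinct(g[!is.na(g)])
    }
    tibble(
      cluster = cl, size = length(inside),
      within_id_median = if (length(within)) median(within) else NA_real_,
      between_id_median = if (length(between)) median(between) else NA_real_,
      n_genera = n_gen
    )
  })
}
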