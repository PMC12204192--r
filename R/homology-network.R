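#' Edge store: a normalized sequence similarity network
#'
#' An `edge_store` holds the undirected, bitscore-weighted SSN together with
#' the full node universe (sequences without any significant hit are still
#' nodes; they become singleton clusters). Edges can live in memory (a
#' normalized tibble) or on disk as a normalized 3-column TSV, in which case
#' all downstream passes stream the file in chunks and peak memory stays
#' O(nodes + chunk).
#'
#' @param edges Normalized edge tibble (`id1`, `id2`, `bitscore`) as produced
#'   by [normalize_edges()], or a path to a normalized edge TSV written by
#'   [write_edge_store()].
#' @param nodes Character vector of all sequence ids in the universe. Must
#'   contain every id on an edge; defaults to the ids seen on edges.
#' @return An object of class `edge_store`.
#' @export
edge_store <- function(edges, nodes = NULL) {
  if (is.character(edges) && length(edges) == 1) {
    path <- edges
    if (!file.exists(path)) stop_format(paste0("edge file not found: ", path))
    edge_ids <- character(0)
    n_edges <- 0L
    con <- file(path, open = "r")
    on.exit(close(con), add = TRUE)
    repeat {
      lines <- readLines(con, n = 500000L)
      if (length(lines) == 0) break
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      if (any(lengths(parts) < 3L)) stop_format("edge file rows need 3 columns")
      n_edges <- n_edges + length(parts)
      edge_ids <- unique(c(edge_ids,
                           unlist(lapply(parts, function(p) p[1:2]),
                                  use.names = FALSE)))
    }
    ids <- if (is.null(nodes)) sort(unique(edge_ids)) else sort(unique(nodes))
    if (!all(edge_ids %in% ids)) {
      stop_universe("edge endpoints missing from the node universe")
    }
    obj <- list(path = path, ids = ids, n_edges = n_edges)
  } else {
    stopifnot(all(c("id1", "id2", "bitscore") %in% names(edges)))
    ids <- if (is.null(nodes)) {
      sort(unique(c(edges$id1, edges$id2)))
    } else {
      sort(unique(nodes))
    }
    if (!all(c(edges$id1, edges$id2) %in% ids)) {
      stop_universe("edge endpoints missing from the node universe")
    }
    obj <- list(
      ia = match(edges$id1, ids),
      ib = match(edges$id2, ids),
      bits = as.numeric(edges$bitscore),
      ids = ids,
      n_edges = nrow(edges)
    )
  }
  structure(obj, class = "edge_store")
}

#' @export
print.edge_store <- function(x, ...) {
  backing <- if (is.null(x$path)) "in-memory" else paste0("file: ", x$path)
  cat("<edge_store> ", x$n_edges, " edges over ", length(x$ids),
      " nodes (", backing, ")\n", sep = "")
  invisible(x)
}

#' Write an edge store's edges to a normalized TSV
#'
#' @param store An `edge_store`.
#' @param path Output path (3 columns, no header: id1, id2, bitscore).
#' @return An `edge_store` backed by the written file.
#' @export
write_edge_store <- function(store, path) {
  con <- file(path, open = "w")
  iterate_edges(store, 500000L, function(ia, ib, bits) {
    writeLines(paste(store$ids[ia], store$ids[ib],
                     format(bits, trim = TRUE, scientific = FALSE),
                     sep = "\t"), con)
  })
  close(con)
  edge_store(path, nodes = store$ids)
}

# Applies fun(ia, ib, bits) to successive chunks of at most chunk_edges
# edges, with endpoints given as indices into store$ids. This is the single
# streaming primitive every multi-pass algorithm (components, sampling)
# shares. chunk_edges = Inf processes everything in one chunk.
iterate_edges <- function(store, chunk_edges, fun) {
  stopifnot(inherits(store, "edge_store"), chunk_edges >= 1)
  if (!is.null(store$path)) {
    con <- file(store$path, open = "r")
    on.exit(close(con), add = TRUE)
    n <- if (is.finite(chunk_edges)) as.integer(chunk_edges) else 500000L
    repeat {
      lines <- readLines(con, n = n)
      if (length(lines) == 0) break
      lines <- lines[nzchar(lines)]
      parts <- strsplit(lines, "\t", fixed = TRUE)
      mat <- vapply(parts, function(p) p[1:3], character(3))
      fun(match(mat[1, ], store$ids), match(mat[2, ], store$ids),
          as.numeric(mat[3, ]))
    }
  } else {
    m <- store$n_edges
    if (m == 0) return(invisible(NULL))
    size <- if (is.finite(chunk_edges)) as.integer(chunk_edges) else m
    starts <- seq(1L, m, by = size)
    for (s in starts) {
      e <- min(s + size - 1L, m)
      fun(store$ia[s:e], store$ib[s:e], store$bits[s:e])
    }
  }
  invisible(NULL)
}

#' Build (or ingest) the all-vs-all homology edge set
#'
#' Runs an external all-vs-all search over the FASTA and normalizes its m8
#' output into an [edge_store()], or ingests a precomputed m8 file without
#' any tool call. The default tool is MMSeqs `easy-search` (BLOSUM62,
#' E-value < 1e-3, maximum hits raised to 1,000 so dense superfamilies are
#' not truncated); `tool = "blast"` drives NCBI BLAST+ (`makeblastdb` +
#' `blastp -outfmt 6`), which emits the same tabular dialect.
#'
#' @param fasta Path to the protein FASTA (defines the node universe).
#' @param m8 Optional path to a precomputed m8 file; when given no external
#'   tool is invoked.
#' @param tool `"mmseqs"` or `"blast"`.
#' @param max_hits Maximum number of hits per query.
#' @param evalue_max E-value significance filter.
#' @param work_dir Directory for tool scratch output.
#' @return An in-memory `edge_store` over the FASTA's ids.
#' @export
run_allvsall_search <- function(fasta, m8 = NULL, tool = c("mmseqs", "blast"),
                                max_hits = 1000L, evalue_max = 1e-3,
                                work_dir = tempfile("allvsall")) {
  tool <- match.arg(tool)
  nodes <- read_fasta(fasta)$id
  if (is.null(m8)) {
    dir.create(work_dir, recursive = TRUE, showWarnings = FALSE)
    m8 <- file.path(work_dir, "hits.m8")
    if (tool == "mmseqs") {
      exe <- Sys.which("mmseqs")
      if (!nzchar(exe)) stop_tool_not_found("executable not found: mmseqs")
      status <- system2(exe, c("easy-search", shQuote(fasta), shQuote(fasta),
                               shQuote(m8), shQuote(file.path(work_dir, "tmp")),
                               "--max-seqs", max_hits, "-e", evalue_max),
                        stdout = FALSE, stderr = file.path(work_dir, "err"))
      if (status != 0) {
        stop_external_tool(paste0("mmseqs failed (exit ", status, "): ",
                                  paste(readLines(file.path(work_dir, "err")),
                                        collapse = "\n")))
      }
    } else {
      for (exe in c("makeblastdb", "blastp")) {
        if (!nzchar(Sys.which(exe))) {
          stop_tool_not_found(paste0("executable not found: ", exe))
        }
      }
      db <- file.path(work_dir, "db")
      err <- file.path(work_dir, "err")
      status <- system2(Sys.which("makeblastdb"),
                        c("-in", shQuote(fasta), "-dbtype", "prot",
                          "-out", shQuote(db)),
                        stdout = FALSE, stderr = err)
      if (status == 0) {
        status <- system2(Sys.which("blastp"),
                          c("-query", shQuote(fasta), "-db", shQuote(db),
                            "-outfmt", "6", "-evalue", evalue_max,
                            "-max_target_seqs", max_hits,
                            "-out", shQuote(m8)),
                          stdout = FALSE, stderr = err)
      }
      if (status != 0) {
        stop_external_tool(paste0("blast failed (exit ", status, "): ",
                                  paste(readLines(err), collapse = "\n")))
      }
    }
  }
  edges <- normalize_edges(read_m8(m8), evalue_max = evalue_max)
  edge_store(edges, nodes = nodes)
}

#' Sample bitscores from an edge store
#'
#' Single-pass uniform reservoir sample of edge bitscores, so the edge file
#' never needs to fit in memory. With `max_sample` at least the edge count
#' the full population multiset is returned; the default cap of one million
#' bitscores is ample for placing percentile cut-offs.
#'
#' @param store An `edge_store`.
#' @param max_sample Maximum sample size.
#' @param seed Integer seed (reservoir decisions are reproducible).
#' @param chunk_edges Streaming chunk size.
#' @return Numeric vector of sampled bitscores.
#' @export
sample_bitscores <- function(store, max_sample = 1e6, seed = 1L,
                             chunk_edges = 1e6L) {
  if (store$n_edges == 0) stop_empty_input("edge store has no edges")
  k <- as.integer(min(max_sample, store$n_edges))
  reservoir <- numeric(k)
  seen <- 0L
  set.seed(seed)
  iterate_edges(store, chunk_edges, function(ia, ib, bits) {
    for (b in bits) {
      seen <<- seen + 1L
      if (seen <= k) {
        reservoir[seen] <<- b
      } else {
        j <- sample.int(seen, 1L)
        if (j <= k) reservoir[j] <<- b
      }
    }
  })
  reservoir
}

#' Percentile bitscore cut-offs
#'
#' Places clustering cut-offs at empirical quantiles of the bitscore
#' distribution (default percentiles 10, 25, 50, 75, 90), using linear
#' interpolation between order statistics (quantile type 7) and rounding to
#' integer bitscores. Duplicate thresholds after rounding are collapsed with
#' a warning.
#'
#' @param bitscores Numeric vector of (sampled) bitscores.
#' @param percentiles Strictly increasing percentiles in (0, 100).
#' @return A `cutoff_set`: list with `cutoffs` (strictly increasing integer
#'   thresholds) and `provenance` (percentiles, sample size).
#' @export
percentile_cutoffs <- function(bitscores, percentiles = c(10, 25, 50, 75, 90)) {
  if (length(bitscores) == 0) stop_empty_input("no bitscores supplied")
  if (any(percentiles <= 0 | percentiles >= 100) ||
      any(diff(percentiles) <= 0)) {
    stop_parameter("percentiles must be strictly increasing within (0, 100)")
  }
  # half-up rounding (not banker's), so e.g. the 50th percentile of 1..100
  # (50.5) becomes 51
  q <- floor(unname(quantile(bitscores, probs = percentiles / 100,
                             type = 7)) + 0.5)
  keep <- !duplicated(q)
  if (any(!keep)) {
    warn(paste0("percentile cut-offs collapsed to ", sum(keep),
                " distinct threshold(s) after rounding"))
  }
  structure(
    list(cutoffs = q[keep],
         provenance = list(percentiles = percentiles,
                           n_sample = length(bitscores))),
    class = "cutoff_set"
  )
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("<cutoff_set> ", paste(x$cutoffs, collapse = ", "),
      " (percentiles ", paste(x$provenance$percentiles, collapse = ", "),
      " of ", x$provenance$n_sample, " bitscores)\n", sep = "")
  invisible(x)
}

as_cutoffs <- function(x) {
  if (inherits(x, "cutoff_set")) x$cutoffs else as.numeric(x)
}
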