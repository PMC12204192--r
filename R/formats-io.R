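#' Read a protein FASTA file
#'
#' Reads amino-acid sequences into a tibble, one row per record. Record order
#' follows file order; the id is the header token up to the first whitespace
#' and the remainder becomes the description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format(paste0("FASTA file not found: ", path))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_format(paste0("cannot parse FASTA '", path, "': ",
                                           conditionMessage(e)))
  )
  if (length(set) == 0) stop_empty_input(paste0("FASTA file is empty: ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop_duplicate_id(paste0("duplicate sequence id(s) in FASTA: ",
                             paste(head(dup, 5), collapse = ", ")))
  }
  tibble(id = unname(ids), description = unname(desc),
         residues = unname(as.character(set)))
}

#' Write sequences to a FASTA file
#'
#' @param sequences Tibble with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(sequences)))
  desc <- sequences[["description"]] %||% rep("", nrow(sequences))
  header <- ifelse(nzchar(desc), paste(sequences$id, desc), sequences$id)
  lines <- unlist(purrr::map2(header, sequences$residues, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

m8_cols <- c("query_id", "target_id", "fident", "alnlen", "mismatch",
             "gapopen", "qstart", "qend", "tstart", "tend", "evalue",
             "bitscore")

parse_m8_lines <- function(lines, first_line_no) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 12L)
  if (length(bad) > 0) {
    stop_format(paste0("m8 line ", first_line_no + bad[1] - 1L, " has ",
                       nfield[bad[1]], " columns (12 required)"),
                line = first_line_no + bad[1] - 1L)
  }
  mat <- vapply(parts, function(p) p[c(1L, 2L, 11L, 12L)], character(4))
  tibble(
    query_id = mat[1, ],
    target_id = mat[2, ],
    bitscore = as.numeric(mat[4, ]),
    evalue = as.numeric(mat[3, ])
  )
}

#' Stream a BLAST/MMSeqs tabular (m8) hit file in chunks
#'
#' Parses the 12-column tabular dialect shared by `blastp -outfmt 6` and
#' MMSeqs `easy-search`: query, target, fident, alnlen, mismatch, gapopen,
#' qstart, qend, tstart, tend, evalue, bitscore. Extra trailing columns are
#' tolerated and ignored; lines with fewer than 12 columns raise a format
#' error naming the line. The file is never loaded whole: `callback` is
#' invoked on successive tibbles of at most `chunk_edges` edges.
#'
#' @param path Path to the m8 file.
#' @param chunk_edges Maximum edges per chunk (positive integer).
#' @param callback Function called with each chunk tibble (columns
#'   `query_id`, `target_id`, `bitscore`, `evalue`).
#' @return The total number of edges streamed, invisibly.
#' @export
stream_m8 <- function(path, chunk_edges = 1e6L, callback) {
  stopifnot(chunk_edges >= 1)
  if (!file.exists(path)) stop_format(paste0("m8 file not found: ", path))
  con <- file(path, open = "r")
  on.exit(close(con), add = TRUE)
  line_no <- 1L
  total <- 0L
  repeat {
    lines <- readLines(con, n = chunk_edges)
    if (length(lines) == 0) break
    keep <- nzchar(lines)
    if (any(keep)) {
      chunk <- parse_m8_lines(lines[keep], line_no)
      total <- total + nrow(chunk)
      callback(chunk)
    }
    line_no <- line_no + length(lines)
  }
  invisible(total)
}

#' Read an entire m8 file as a tibble of edges
#'
#' Convenience wrapper over [stream_m8()] for files that fit in memory.
#'
#' @inheritParams stream_m8
#' @return Tibble with columns `query_id`, `target_id`, `bitscore`, `evalue`.
#' @export
read_m8 <- function(path) {
  chunks <- list()
  stream_m8(path, 1e6L, function(x) chunks[[length(chunks) + 1L]] <<- x)
  if (length(chunks) == 0) {
    return(tibble(query_id = character(), target_id = character(),
                  bitscore = numeric(), evalue = numeric()))
  }
  bind_rows(chunks)
}

#' Normalize a batch of homology edges
#'
#' Applies the standard SSN hygiene rules: self-hits are dropped, hits with
#' E-value at or above `evalue_max` are dropped (the conventional
#' significance filter is E-value < 1e-3), and reciprocal or repeated hits on
#' the same unordered pair are merged keeping the maximum bitscore. Pairs are
#' stored with the lexicographically smaller id first and rows are sorted, so
#' the result is deterministic and idempotent.
#'
#' @param edges Tibble with columns `query_id`, `target_id`, `bitscore` and
#'   optionally `evalue` (edges with missing E-value are kept).
#' @param evalue_max Exclusive E-value upper bound.
#' @return Normalized tibble with columns `id1`, `id2`, `bitscore`.
#' @export
normalize_edges <- function(edges, evalue_max = 1e-3) {
  if (all(c("id1", "id2") %in% names(edges))) {
    edges <- rename(edges, query_id = "id1", target_id = "id2")
  }
  ev <- edges[["evalue"]] %||% rep(NA_real_, nrow(edges))
  keep <- edges$query_id != edges$target_id & (is.na(ev) | ev < evalue_max)
  edges <- edges[keep, , drop = FALSE]
  out <- tibble(
    id1 = pmin(edges$query_id, edges$target_id),
    id2 = pmax(edges$query_id, edges$target_id),
    bitscore = edges$bitscore
  )
  out |>
    group_by(.data$id1, .data$id2) |>
    summarise(bitscore = max(.data$bitscore), .groups = "drop") |>
    arrange(.data$id1, .data$id2)
}

#' Write / read cluster-map tables
#'
#' A cluster map is the long, tidy form of one or more partitions: one row
#' per (sequence, level), tab-separated with a header
#' `sequence_id  level  cluster_id`, rows sorted by level then id.
#'
#' @param assignment Tibble with columns `id`, `level`, `cluster`.
#' @param path File path.
#' @return `write_cluster_map()` returns `path` invisibly;
#'   `read_cluster_map()` returns the assignment tibble.
#' @export
write_cluster_map <- function(assignment, path) {
  stopifnot(all(c("id", "level", "cluster") %in% names(assignment)))
  out <- assignment |>
    select(sequence_id = "id", level = "level", cluster_id = "cluster") |>
    arrange(.data$level, .data$sequence_id)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @param levels Optional character vector of expected level labels; labels in
#'   the file outside this set raise a format error.
#' @rdname write_cluster_map
#' @export
read_cluster_map <- function(path, levels = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sequence_id", "level", "cluster_id") %in% names(tbl))) {
    stop_format(paste0("not a cluster-map file (bad header): ", path))
  }
  if (!is.null(levels) && !all(tbl$level %in% levels)) {
    bad <- setdiff(unique(tbl$level), levels)
    stop_format(paste0("unknown level label(s) in ", path, ": ",
                       paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(tbl[c("sequence_id", "level")])) {
    stop_duplicate_id(paste0("duplicate (id, level) rows in ", path))
  }
  tibble(id = tbl$sequence_id, level = tbl$level, cluster = tbl$cluster_id)
}

#' Write / read Newick trees
#'
#' Thin wrappers around ape's Newick support with validation and stable
#' numeric formatting, so `read_newick(write_newick(t))` preserves topology,
#' leaf names and branch lengths to well below 1e-9.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional path; when `NULL` the Newick string is returned.
#' @return `write_newick()` returns the Newick string (invisibly if written
#'   to a file); `read_newick()` returns a `phylo`.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    stop_duplicate_id("tree leaf names must be unique")
  }
  txt <- ape::write.tree(tree, digits = 12)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @param x A Newick string, or a path to a file holding one.
#' @rdname write_newick
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1 && file.exists(x)) paste(readLines(x), collapse = "") else x
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close) stop_format("unbalanced parentheses in Newick string")
  if (n_open == 0) {
    # leaf-only tree, e.g. "A;" or "A:1.5;" (ape cannot represent it alone)
    body <- sub(";\\s*$", "", trimws(txt))
    if (!nzchar(body)) stop_format("cannot parse Newick string")
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    len <- if (length(parts) > 1) as.numeric(parts[2]) else 0
    return(structure(
      list(edge = matrix(c(2L, 1L), 1, 2), edge.length = len,
           tip.label = parts[1], Nnode = 1L),
      class = "phylo", order = "cladewise"))
  }
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop_format("cannot parse Newick string")
  tree
}

#' Deterministic colors for annotation categories
#'
#' Categories are hashed (seeded FNV-1a) onto the HCL wheel, so the same
#' category always maps to the same color across runs and machines.
#'
#' @param categories Character vector of category labels.
#' @param seed Integer mixed into the hash.
#' @return Named vector of hex colors.
#' @export
category_colors <- function(categories, seed = 0L) {
  cats <- sort(unique(as.character(categories)))
  h <- (str_hash32(paste0(seed, ":", cats)) %% 360)
  cols <- grDevices::hcl(h = h, c = 60, l = 60)
  setNames(cols, cats)
}

#' Write iTOL annotation dataset files
#'
#' Emits an iTOL `DATASET_COLORSTRIP` text file coloring every annotated leaf
#' by its category, with a deterministic (hash-seeded) category palette.
#' Only ids present in `assignment` may appear in `annotations`.
#'
#' @param assignment Tibble with a column `id` giving the leaf universe.
#' @param annotations Tibble with columns `id` and the annotation column
#'   named by `field`.
#' @param path Output file path.
#' @param field Name of the annotation column to color by.
#' @param label Dataset label shown in iTOL.
#' @param seed Integer seed for the color hash.
#' @return `path`, invisibly.
#' @export
write_itol_annotations <- function(assignment, annotations, path,
                                   field = "function", label = field,
                                   seed = 0L) {
  stopifnot("id" %in% names(assignment), "id" %in% names(annotations))
  if (!all(annotations$id %in% assignment$id)) {
    stop_universe("annotation ids must be a subset of assignment ids")
  }
  ann <- annotations[!is.na(annotations[[field]]), c("id", field)]
  ann <- ann[order(ann$id), , drop = FALSE]
  pal <- category_colors(ann[[field]], seed = seed)
  header <- c(
    "DATASET_COLORSTRIP",
    "SEPARATOR TAB",
    paste0("DATASET_LABEL\t", label),
    "COLOR\t#7570b3",
    "STRIP_WIDTH\t25",
    "DATA"
  )
  data_lines <- if (nrow(ann) > 0) {
    paste(ann$id, pal[ann[[field]]], ann[[field]], sep = "\t")
  } else character()
  writeLines(c(header, data_lines), path)
  invisible(path)
}
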