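#' Embedding matrix: one fixed-length vector per sequence
#'
#' A thin wrapper around a numeric matrix with sequence ids as row names and
#' a provenance record (where the vectors came from, whether they have been
#' reduced). Protein language-model states enter the package through this
#' container — either precomputed vectors read from disk or synthetic
#' fixtures — so no model inference or GPU is ever required.
#'
#' @param mat Numeric matrix, rows = sequences.
#' @param ids Sequence ids (defaults to `rownames(mat)`).
#' @param provenance List with fields such as `source`, `model_name`,
#'   `pooling`, `reduced`.
#' @return An object of class `embedding_matrix` (a numeric matrix).
#' @export
embedding_matrix <- function(mat, ids = rownames(mat), provenance = list()) {
  mat <- as.matrix(mat)
  if (is.null(ids)) stop_parameter("embedding matrix needs sequence ids")
  if (length(ids) != nrow(mat)) {
    stop_dimension("id count must equal the number of rows")
  }
  if (anyDuplicated(ids)) stop_duplicate_id("duplicate ids in embedding matrix")
  if (any(!is.finite(mat))) stop_parameter("non-finite embedding entries")
  rownames(mat) <- ids
  provenance <- provenance[!vapply(provenance, is.null, logical(1))]
  prov <- utils::modifyList(
    list(source = "file", model_name = NA_character_, pooling = "mean",
         reduced = FALSE, d = ncol(mat)),
    provenance
  )
  structure(mat, class = c("embedding_matrix", "matrix", "array"),
            provenance = prov)
}

#' @export
print.embedding_matrix <- function(x, ...) {
  p <- attr(x, "provenance")
  cat("<embedding_matrix> ", nrow(x), " sequences x ", ncol(x),
      " dims (source: ", p$source,
      if (isTRUE(p$reduced)) ", reduced" else "", ")\n", sep = "")
  invisible(x)
}

#' Mean-pool a per-residue embedding into a sequence vector
#'
#' Protein language models emit one state vector per residue (an L x d
#' matrix); mean-pooling averages over the sequence dimension so every
#' sequence gets the same fixed vector length regardless of L.
#'
#' @param per_residue Numeric L x d matrix, one row per residue.
#' @return Numeric vector of length d.
#' @export
mean_pool <- function(per_residue) {
  per_residue <- as.matrix(per_residue)
  if (nrow(per_residue) == 0) stop_empty_input("no residues to pool")
  colMeans(per_residue)
}

#' Fit a PCA reduction and project embeddings
#'
#' Centers the vectors and projects onto the top `d_out` principal
#' components (default 30, the working dimensionality for downstream
#' clustering). The sign of each component is fixed so its largest-magnitude
#' loading is positive, making the reduction deterministic for a given
#' input.
#'
#' @param embeddings An [embedding_matrix()].
#' @param d_out Output dimensionality; must be below the number of
#'   sequences.
#' @return List with `model` (class `reduction_model`: `center`, `rotation`,
#'   `explained`) and `reduced` (the projected `embedding_matrix`).
#' @export
fit_reduce <- function(embeddings, d_out = 30L) {
  n <- nrow(embeddings)
  if (d_out >= n) stop_dimension("d_out must be smaller than the number of sequences")
  d_out <- min(as.integer(d_out), ncol(embeddings))
  pc <- prcomp(unclass(embeddings), center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(d_out), drop = FALSE]
  flip <- vapply(seq_len(d_out), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(unclass(embeddings), 2, pc$center, `-`) %*% rot
  var_all <- pc$sdev^2
  model <- structure(
    list(center = pc$center, rotation = rot,
         explained = var_all[seq_len(d_out)] / sum(var_all)),
    class = "reduction_model"
  )
  prov <- attr(embeddings, "provenance")
  prov$reduced <- TRUE
  prov$d <- d_out
  list(model = model,
       reduced = embedding_matrix(scores, rownames(embeddings), prov))
}

#' Apply a fitted reduction to new vectors
#'
#' @param model A `reduction_model` from [fit_reduce()].
#' @param embeddings An [embedding_matrix()] with the model's input
#'   dimensionality.
#' @return The projected `embedding_matrix`.
#' @export
reduce_embeddings <- function(model, embeddings) {
  stopifnot(inherits(model, "reduction_model"))
  if (ncol(embeddings) != length(model$center)) {
    stop_dimension("embedding dimensionality does not match the model")
  }
  scores <- sweep(unclass(embeddings), 2, model$center, `-`) %*% model$rotation
  prov <- attr(embeddings, "provenance")
  prov$reduced <- TRUE
  prov$d <- ncol(scores)
  embedding_matrix(scores, rownames(embeddings), prov)
}

#' Synthetic hierarchical embeddings with planted labels
#'
#' Generates vectors with the two-level structure the clustering methods
#' assume: superfamily centers far apart, family centers scattered around
#' their superfamily center, members scattered around their family center.
#' Separations are expressed as expected Euclidean distances (superfamily
#' center to superfamily center, family center to its superfamily center,
#' member to its family center), so `sep_fam / noise_sd` is directly the
#' planted family separation-to-noise ratio.
#'
#' @param n_super Number of superfamilies.
#' @param fam_per_super Families per superfamily.
#' @param members_per_fam Members per family.
#' @param d Vector dimensionality.
#' @param sep_super Expected distance between superfamily centers.
#' @param sep_fam Expected distance from a family center to its superfamily
#'   center.
#' @param noise_sd Expected distance from a member to its family center.
#' @param seed Integer seed; the fixture is fully reproducible.
#' @return List with `embeddings` (an [embedding_matrix()]) and `truth`
#'   (tibble `id`, `superfamily`, `family`).
#' @export
synth_embeddings <- function(n_super = 8L, fam_per_super = 4L,
                             members_per_fam = 25L, d = 30L,
                             sep_super = 60, sep_fam = 10, noise_sd = 1,
                             seed = 1L) {
  stopifnot(sep_super > 0, sep_fam > 0, noise_sd >= 0)
  set.seed(seed)
  # iid N(0, s^2) coordinates give E||x - y||^2 = 2 d s^2 between two
  # centers and E||z||^2 = d s^2 around a center.
  super_means <- matrix(rnorm(n_super * d, sd = sep_super / sqrt(2 * d)),
                        nrow = n_super)
  rows <- list()
  truth <- list()
  for (s in seq_len(n_super)) {
    for (f in seq_len(fam_per_super)) {
      fam_mean <- super_means[s, ] + rnorm(d, sd = sep_fam / sqrt(d))
      noise <- matrix(rnorm(members_per_fam * d, sd = noise_sd / sqrt(d)),
                      nrow = members_per_fam)
      mem <- sweep(noise, 2, fam_mean, `+`)
      ids <- sprintf("S%02dF%02dM%03d", s, f, seq_len(members_per_fam))
      rows[[length(rows) + 1L]] <- mem
      truth[[length(truth) + 1L]] <-
        tibble(id = ids, superfamily = sprintf("S%02d", s),
               family = sprintf("S%02dF%02d", s, f))
    }
  }
  truth <- bind_rows(truth)
  mat <- do.call(rbind, rows)
  rownames(mat) <- truth$id
  list(
    embeddings = embedding_matrix(mat, provenance = list(
      source = "synthetic", pooling = "mean", reduced = FALSE)),
    truth = truth
  )
}

#' Write / read embedding vectors
#'
#' Vectors persist as a plain TSV (id + one column per dimension) with a
#' JSON sidecar (`<path>.json`) recording provenance, so files are portable
#' and diffable.
#'
#' @param embeddings An [embedding_matrix()].
#' @param path Output TSV path.
#' @return `write_embeddings()` returns `path` invisibly;
#'   `read_embeddings()` returns the `embedding_matrix`.
#' @export
write_embeddings <- function(embeddings, path) {
  tbl <- as_tibble(unclass(embeddings), .name_repair = ~ paste0("d", seq_along(.x)))
  tbl <- dplyr::bind_cols(tibble(id = rownames(embeddings)), tbl)
  readr::write_tsv(tbl, path)
  jsonlite::write_json(attr(embeddings, "provenance"),
                       paste0(path, ".json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    id = "c", .default = "d"), progress = FALSE)
  sidecar <- paste0(path, ".json")
  prov <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(source = "file")
  }
  m <- as.matrix(tbl[-1])
  dimnames(m) <- NULL
  embedding_matrix(m, ids = tbl$id, provenance = as.list(prov))
}
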