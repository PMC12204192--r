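default_config <- function() {
  list(
    out_dir = "seqspace_run",
    fasta = NULL, m8 = NULL, vectors = NULL,
    seed = 1L,
    evalue_max = 1e-3,
    chunk_edges = 1e6,
    percentiles = c(10, 25, 50, 75, 90),
    max_sample = 1e6,
    reduce_dims = 30L,
    k_max = NULL,            # default: number of homology clusters at the top cutoff
    flatten_k = NULL,        # default: cluster counts matching the homology levels
    layout_min_size = NULL,
    rep_method = "vector",
    run_sampling = FALSE,
    sampling = list()        # overrides for sampling_spec()
  )
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$fasta) || is.null(cfg$m8)) {
    stop_parameter("config needs at least `fasta` and `m8` paths")
  }
  for (p in c("fasta", "m8", "vectors")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop_parameter(paste0("config path does not exist: ", cfg[[p]]))
    }
  }
  cfg
}

hash_files <- function(paths) {
  paths <- paths[!vapply(paths, is.null, logical(1))]
  as.list(tools::md5sum(unlist(paths)))
}

manifest_path <- function(out_dir, stage) {
  file.path(out_dir, "manifests", paste0(stage, ".json"))
}

stage_cached <- function(out_dir, stage, inputs, params) {
  mp <- manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  man <- tryCatch(jsonlite::read_json(mp, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(man)) return(FALSE)
  if (!identical(man$inputs, hash_files(inputs))) return(FALSE)
  if (!identical(jsonlite::toJSON(man$params, auto_unbox = TRUE),
                 jsonlite::toJSON(params, auto_unbox = TRUE))) return(FALSE)
  outs <- unlist(man$outputs)
  if (length(outs) == 0) return(FALSE)
  files <- names(outs)
  all(file.exists(files)) &&
    identical(unname(tools::md5sum(files)), unname(outs))
}

write_manifest <- function(out_dir, stage, inputs, params, outputs) {
  mp <- manifest_path(out_dir, stage)
  dir.create(dirname(mp), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(stage = stage, inputs = hash_files(inputs), params = params,
         outputs = as.list(tools::md5sum(unlist(outputs)))),
    mp, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the sequence-space exploration pipeline
#'
#' Executes the standard workflow over one FASTA + m8 pair: edge
#' normalization, percentile cut-off selection, multi-cutoff homology
#' clustering, optional embedding reduction and hierarchy-consistent
#' K-means, layout construction, representative selection at the finest
#' homology level, and (optionally) even sampling for phylogenetics. Every
#' stage writes its outputs plus a manifest (input hashes, parameters,
#' output hashes) under `out_dir`; rerunning with unchanged inputs and
#' parameters skips completed stages, and corrupting an intermediate file
#' causes that stage and its dependents to run again.
#'
#' @param config A named list or path to a JSON file. Required: `fasta`,
#'   `m8`. Optional: `vectors` (embedding TSV), `out_dir`, `seed`,
#'   `percentiles`, `chunk_edges`, `reduce_dims`, `k_max`, `flatten_k`,
#'   `layout_min_size`, `rep_method` (`"vector"`/`"hmm"`), `run_sampling`,
#'   `sampling` (overrides for [sampling_spec()]).
#' @return Tibble with one row per stage (`stage`, `status`), invisibly the
#'   out directory as attribute `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- list()
  mark <- function(stage, st) status[[stage]] <<- st

  # -- network: normalize edges against the FASTA universe -----------------
  edges_file <- file.path(cfg$out_dir, "edges.tsv")
  nodes_file <- file.path(cfg$out_dir, "nodes.txt")
  net_params <- cfg[c("evalue_max")]
  if (stage_cached(cfg$out_dir, "network", list(cfg$fasta, cfg$m8),
                   net_params)) {
    mark("network", "cached")
  } else {
    nodes <- read_fasta(cfg$fasta)$id
    store <- edge_store(normalize_edges(read_m8(cfg$m8),
                                        evalue_max = cfg$evalue_max),
                        nodes = nodes)
    write_edge_store(store, edges_file)
    writeLines(store$ids, nodes_file)
    write_manifest(cfg$out_dir, "network", list(cfg$fasta, cfg$m8),
                   net_params, list(edges_file, nodes_file))
    mark("network", "completed")
  }
  store <- edge_store(edges_file, nodes = readLines(nodes_file))

  # -- cutoffs -------------------------------------------------------------
  cutoffs_file <- file.path(cfg$out_dir, "cutoffs.json")
  cut_params <- cfg[c("percentiles", "max_sample", "seed")]
  if (stage_cached(cfg$out_dir, "cutoffs", list(edges_file), cut_params)) {
    mark("cutoffs", "cached")
  } else {
    bits <- sample_bitscores(store, max_sample = cfg$max_sample,
                             seed = derive_seed(cfg$seed, "bitscores"),
                             chunk_edges = cfg$chunk_edges)
    cs <- percentile_cutoffs(bits, percentiles = cfg$percentiles)
    jsonlite::write_json(list(cutoffs = cs$cutoffs,
                              provenance = cs$provenance),
                         cutoffs_file, auto_unbox = TRUE, digits = NA)
    write_manifest(cfg$out_dir, "cutoffs", list(edges_file), cut_params,
                   list(cutoffs_file))
    mark("cutoffs", "completed")
  }
  cutoffs <- unlist(jsonlite::read_json(cutoffs_file,
                                        simplifyVector = TRUE)$cutoffs)

  # -- homology clustering -------------------------------------------------
  hmap_file <- file.path(cfg$out_dir, "homology_clusters.tsv")
  hier_params <- list(cutoffs = cutoffs, chunk_edges = cfg$chunk_edges)
  if (stage_cached(cfg$out_dir, "homology", list(edges_file), hier_params)) {
    mark("homology", "cached")
  } else {
    hier <- components_multi(store, cutoffs, chunk_edges = cfg$chunk_edges)
    write_cluster_map(tidy(hier), hmap_file)
    write_manifest(cfg$out_dir, "homology", list(edges_file), hier_params,
                   list(hmap_file))
    mark("homology", "completed")
  }
  assignment <- read_cluster_map(hmap_file)
  hier <- cluster_hierarchy(
    lapply(split(assignment, factor(assignment$level,
                                    levels = unique(assignment$level))),
           function(d) new_partition(d$id, d$cluster, level = d$level[1])))

  # -- vector clustering (optional) ----------------------------------------
  if (!is.null(cfg$vectors)) {
    vmap_file <- file.path(cfg$out_dir, "kmeans_clusters.tsv")
    n_top <- n_distinct(hier$levels[[length(hier$levels)]]$cluster)
    k_max <- cfg$k_max %||% max(2L, n_top)
    flatten_k <- cfg$flatten_k %||% unique(pmin(
      k_max, vapply(hier$levels, function(p) n_distinct(p$cluster),
                    integer(1))))
    vec_params <- list(reduce_dims = cfg$reduce_dims, k_max = k_max,
                       flatten_k = flatten_k, seed = cfg$seed)
    if (stage_cached(cfg$out_dir, "vector", list(cfg$vectors), vec_params)) {
      mark("vector", "cached")
    } else {
      emb <- read_embeddings(cfg$vectors)
      if (nrow(emb) > cfg$reduce_dims + 1) {
        emb <- fit_reduce(emb, d_out = min(cfg$reduce_dims,
                                           ncol(emb)))$reduced
      }
      bt <- bisecting_kmeans(emb, k_max = k_max,
                             seed = derive_seed(cfg$seed, "kmeans"))
      linkage <- tree_to_linkage(bt)
      membership <- leaf_membership(bt)
      parts <- lapply(sort(flatten_k), function(k) {
        project_labels(flatten_clusters(linkage, k), membership)
      })
      names(parts) <- paste0("K:", sort(flatten_k))
      vhier <- cluster_hierarchy(parts)
      write_cluster_map(tidy(vhier), vmap_file)
      write_manifest(cfg$out_dir, "vector", list(cfg$vectors), vec_params,
                     list(vmap_file))
      mark("vector", "completed")
    }
  }

  # -- layout --------------------------------------------------------------
  layout_file <- file.path(cfg$out_dir, "layout.tsv")
  lay_params <- list(min_size = cfg$layout_min_size, seed = cfg$seed)
  if (stage_cached(cfg$out_dir, "layout", list(hmap_file), lay_params)) {
    mark("layout", "cached")
  } else {
    layout <- build_layout(hier, min_size = cfg$layout_min_size,
                           seed = derive_seed(cfg$seed, "layout"))
    write_layout(layout, layout_file)
    write_manifest(cfg$out_dir, "layout", list(hmap_file), lay_params,
                   list(layout_file))
    mark("layout", "completed")
  }

  # -- representatives at the finest homology level ------------------------
  reps_file <- file.path(cfg$out_dir, "representatives.tsv")
  rep_inputs <- list(hmap_file, cfg$fasta, cfg$vectors)
  rep_params <- list(method = cfg$rep_method)
  if (stage_cached(cfg$out_dir, "representatives", rep_inputs, rep_params)) {
    mark("representatives", "cached")
  } else {
    seqs <- read_fasta(cfg$fasta)
    emb <- if (!is.null(cfg$vectors)) read_embeddings(cfg$vectors) else NULL
    finest <- hier$levels[[length(hier$levels)]]
    reps <- purrr::map_dfr(sort(unique(finest$cluster)), function(cl) {
      mem <- finest$id[finest$cluster == cl]
      choice <- if (cfg$rep_method == "vector" && !is.null(emb)) {
        vector_representative(mem, emb)
      } else {
        hmm_representative(seqs[seqs$id %in% mem, ], engine = "fallback")
      }
      mutate(choice, cluster = cl, .before = 1)
    })
    readr::write_tsv(reps, reps_file)
    write_manifest(cfg$out_dir, "representatives", rep_inputs, rep_params,
                   list(reps_file))
    mark("representatives", "completed")
  }

  # -- even sampling (optional) --------------------------------------------
  if (isTRUE(cfg$run_sampling)) {
    sample_file <- file.path(cfg$out_dir, "sample.tsv")
    spec <- do.call(sampling_spec, cfg$sampling)
    samp_params <- cfg$sampling
    if (stage_cached(cfg$out_dir, "sampling", list(edges_file, cfg$fasta),
                     samp_params)) {
      mark("sampling", "cached")
    } else {
      seqs <- read_fasta(cfg$fasta)
      emb <- if (!is.null(cfg$vectors)) read_embeddings(cfg$vectors) else NULL
      report <- even_sample(store, spec, seqs, embeddings = emb,
                            chunk_edges = cfg$chunk_edges)
      readr::write_tsv(report$chosen, sample_file)
      write_manifest(cfg$out_dir, "sampling", list(edges_file, cfg$fasta),
                     samp_params, list(sample_file))
      mark("sampling", "completed")
    }
  }

  out <- tibble(stage = names(status),
                status = unlist(status, use.names = FALSE))
  attr(out, "out_dir") <- cfg$out_dir
  out
}
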