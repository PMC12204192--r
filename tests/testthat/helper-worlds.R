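# Planted sampling world: a 2,500-member neighborhood that splits into
# 900/900/700 one step up, an undersized cluster, a cluster whose chosen
# representative is too long, and a cluster that never resolves below the
# size cap. Chains keep components exact without quadratic edge counts.
sampling_world <- function() {
  chain <- function(ids, bits) {
    tibble::tibble(id1 = pmin(head(ids, -1), ids[-1]),
                   id2 = pmax(head(ids, -1), ids[-1]),
                   bitscore = bits)
  }
  big_a <- sprintf("bigA%04d", 1:900)
  big_b <- sprintf("bigB%04d", 1:900)
  big_c <- sprintf("bigC%04d", 1:700)
  small <- sprintf("sml%04d", 1:50)
  longrep <- sprintf("lng%04d", 1:120)
  unres <- sprintf("unr%04d", 1:1200)
  edges <- dplyr::bind_rows(
    chain(big_a, 165), chain(big_b, 165), chain(big_c, 165),
    # links below 160 glue the three into one 2,500-member cluster at 150
    tibble::tibble(id1 = c(big_a[1], big_b[1]),
                   id2 = c(big_b[1], big_c[1]), bitscore = 155),
    chain(small, 200), chain(longrep, 200), chain(unres, 450))
  ids <- c(big_a, big_b, big_c, small, longrep, unres)
  store <- edge_store(dplyr::arrange(edges, id1, id2), nodes = ids)
  sequences <- tibble::tibble(
    id = ids,
    residues = vapply(ids, function(i) {
      strrep("A", if (startsWith(i, "lng")) 350L else 150L)
    }, character(1)))
  # one-column vectors; the "lng" cluster's lexicographically first member
  # sits exactly on the cluster mean so it is the deterministic pick
  vals <- seq_along(ids)
  names(vals) <- ids
  lng_rows <- which(startsWith(ids, "lng"))
  vals[lng_rows] <- c(0, rep(c(-1, 1), length.out = length(lng_rows) - 1))
  emb <- embedding_matrix(matrix(vals, ncol = 1, dimnames = list(ids, NULL)))
  list(store = store, sequences = sequences, embeddings = emb)
}

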