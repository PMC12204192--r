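test_that("read_fasta preserves order, concatenates lines, rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">B some description", "ACDE", "FGHI", ">A", "MKV"), f)
  recs <- read_fasta(f)
  expect_equal(recs$id, c("B", "A"))
  expect_equal(recs$residues, c("ACDEFGHI", "MKV"))
  expect_equal(recs$description, c("some description", ""))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "ACDE", ">A", "MKV"), dup)
  expect_error(read_fasta(dup), class = "seqspace_duplicate_id")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), class = "seqspace_empty_input")
})

test_that("fasta round-trips through write_fasta", {
  tbl <- tibble::tibble(id = c("s1", "s2"), description = c("d one", ""),
                        residues = c(rand_seq(150), rand_seq(90)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(tbl, f)
  expect_equal(read_fasta(f), tbl)
})

test_that("stream_m8 chunks, parses, and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".m8")
  rows <- sprintf("q%d\tt%d\t0.9\t100\t5\t1\t1\t100\t1\t100\t1e-%d\t%g",
                  1:10, 1:10, 1:10, 100 + 1:10)
  writeLines(rows, f)
  sizes <- integer(0)
  stream_m8(f, chunk_edges = 4, function(chunk) {
    sizes <<- c(sizes, nrow(chunk))
  })
  expect_equal(sizes, c(4L, 4L, 2L))

  edges <- read_m8(f)
  expect_equal(edges$query_id[1], "q1")
  expect_equal(edges$bitscore[3], 103)
  expect_equal(edges$evalue[3], 1e-3)

  bad <- withr::local_tempfile(fileext = ".m8")
  writeLines(c(rows[1:2], "a\tb\tc", rows[3]), bad)
  err <- expect_error(read_m8(bad), class = "seqspace_format")
  expect_match(conditionMessage(err), "line 3")

  # extra columns tolerated
  extra <- withr::local_tempfile(fileext = ".m8")
  writeLines(paste0(rows[1], "\textra\tcols"), extra)
  expect_equal(nrow(read_m8(extra)), 1L)
})

test_that("normalize_edges drops self-hits and weak hits, merges reciprocals", {
  edges <- tibble::tibble(
    query_id = c("A", "A", "B", "C"),
    target_id = c("A", "B", "A", "D"),
    bitscore = c(500, 100, 120, 80),
    evalue = c(1e-50, 1e-10, 1e-9, 1e-2)
  )
  out <- normalize_edges(edges)
  # self-hit A-A gone, C-D at evalue 1e-2 >= 1e-3 gone, reciprocal A-B max
  expect_equal(out, tibble::tibble(id1 = "A", id2 = "B", bitscore = 120))
  # idempotent and never grows
  expect_equal(normalize_edges(out), out)
  expect_lte(nrow(out), nrow(edges))
})

test_that("cluster maps round-trip and validate", {
  assign <- tibble::tibble(
    id = c("a", "b", "c", "a", "b", "c"),
    level = rep(c("bitscore:100", "bitscore:200"), each = 3),
    cluster = c("a", "a", "c", "a", "b", "c")
  )
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_map(assign, f)
  back <- read_cluster_map(f)
  expect_equal(dplyr::arrange(back, level, id),
               dplyr::arrange(assign, level, id))
  expect_error(read_cluster_map(f, levels = "bitscore:100"),
               class = "seqspace_format")

  # empty assignment -> header-only file
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_map(assign[0, ], f2)
  expect_equal(readLines(f2), "sequence_id\tlevel\tcluster_id")

  # duplicate (id, level) rows rejected
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tlevel\tcluster_id", "a\tL\tc1", "a\tL\tc2"), f3)
  expect_error(read_cluster_map(f3), class = "seqspace_duplicate_id")
})

test_that("newick round-trips preserve topology and path lengths", {
  t1 <- read_newick("(A:1,B:2);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  expect_equal(read_newick(write_newick(t1)), t1)

  leaf <- read_newick("A;")
  expect_equal(leaf$tip.label, "A")

  expect_error(read_newick("((A:1,B:2);"), class = "seqspace_format")

  set.seed(5)
  big <- ape::rtree(50)
  back <- read_newick(write_newick(big))
  expect_setequal(back$tip.label, big$tip.label)
  d1 <- ape::cophenetic.phylo(big)
  d2 <- ape::cophenetic.phylo(back)[rownames(d1), colnames(d1)]
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("iTOL annotation output is conformant and deterministic", {
  assign <- tibble::tibble(id = c("a", "b", "c"))
  ann <- tibble::tibble(id = c("a", "b", "c"),
                        fun = c("hydrolase", "oxidase", "hydrolase"))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_itol_annotations(assign, ann, f1, field = "fun")
  lines <- readLines(f1)
  expect_equal(lines[1], "DATASET_COLORSTRIP")
  expect_equal(sum(grepl("^[abc]\t#", lines)), 3L)
  write_itol_annotations(assign, ann, f2, field = "fun")
  expect_identical(readLines(f1), readLines(f2))

  # empty annotation -> header-only
  f3 <- withr::local_tempfile()
  write_itol_annotations(assign, ann[0, ], f3, field = "fun")
  expect_false(any(grepl("^[abc]\t", readLines(f3))))

  # unknown ids rejected
  expect_error(
    write_itol_annotations(assign, tibble::tibble(id = "z", fun = "x"),
                           withr::local_tempfile(), field = "fun"),
    class = "seqspace_universe")
})
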