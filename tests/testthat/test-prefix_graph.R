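test_that("automaton on singleton phasing paths is memory-1", {
  g <- chain_graph(c(50L, 50L))
  P <- build_phasing_set(g, point_fld(1L))  # singletons only
  aut <- build_automaton(g, P)
  expect_setequal(aut$keys, c("1", "2", "3", "4"))  # [S],[a],[b],[T]
  # every transition lands on a singleton state
  for (tr in aut$trans) {
    for (s in tr) expect_length(aut$states[[s]], 1L)
  }
})

test_that("automaton trie edge exists for a two-exon pattern", {
  g <- chain_graph(c(50L, 50L))
  P <- build_phasing_set(g, unif_fld(1L, 60L))  # includes [a,b]
  aut <- build_automaton(g, P)
  expect_true("2-3" %in% aut$keys)
  ia <- match("2", aut$keys)
  expect_equal(unname(aut$trans[[ia]][["3"]]), match("2-3", aut$keys))
})

test_that("transitions agree with brute-force longest-suffix search", {
  set.seed(41)
  for (i in 1:25) {
    fx <- small_fixture(6000L + i, short_exons = TRUE)
    P <- build_phasing_set(fx$graph, fx$fld)
    aut <- build_automaton(fx$graph, P)
    for (si in seq_along(aut$states)) {
      p <- aut$states[[si]]
      for (y in fx$graph$out[[p[length(p)]]]) {
        cand <- c(p, y)
        # brute force: longest suffix of cand among all state keys
        hits <- vapply(aut$states, function(s)
          length(s) <= length(cand) &&
            all(utils::tail(cand, length(s)) == s), logical(1))
        bl <- max(lengths(aut$states)[hits])
        best <- which(hits & lengths(aut$states) == bl)[1L]
        expect_equal(unname(aut$trans[[si]][[as.character(y)]]), best)
      }
    }
  }
})

test_that("automaton rejects phasing paths that are not graph paths", {
  g <- chain_graph(c(50L, 50L))
  P <- build_phasing_set(g, unif_fld(1L, 60L))
  P$paths[[length(P$paths) + 1L]] <- c(3L, 2L)
  P$keys <- c(P$keys, "3-2")
  expect_error(build_automaton(g, P), "not a splice-graph path")
  expect_error(build_compact_prefix_graph(g, P), "not a splice-graph path")
})

test_that("singleton phasing sets give graphs isomorphic to the splice graph", {
  for (mk in list(chain_graph, parallel_graph, chord_graph)) {
    g <- mk()
    P <- build_phasing_set(g, point_fld(1L))
    pg <- build_prefix_graph(build_automaton(g, P))
    cg <- build_compact_prefix_graph(g, P)
    for (x in list(pg, cg)) {
      expect_equal(n_pg_vertices(x), g$n)
      expect_equal(n_pg_edges(x), nrow(g$edges))
      # vertex labels are exactly the splice-graph vertices
      expect_setequal(vapply(x$vpaths, paste, character(1), collapse = "-"),
                      as.character(seq_len(g$n)))
    }
    # compact edge labels are the splice edges
    labs <- t(vapply(cg$elabels, identity, integer(2)))
    expect_equal(labs[order(labs[, 1], labs[, 2]), , drop = FALSE],
                 g$edges, ignore_attr = TRUE)
  }
})

test_that("chain with a two-exon pattern produces the expected compact graph", {
  g <- chain_graph(c(50L, 50L))
  P <- build_phasing_set(g, unif_fld(1L, 60L))  # P = {[a],[b],[a,b]}
  cg <- build_compact_prefix_graph(g, P)
  expect_setequal(vapply(cg$vpaths, paste, character(1), collapse = "-"),
                  c("1", "2", "3", "4"))
  ia <- match("2", cg$vkeys)
  eidx <- which(cg$edges[, "from"] == ia)
  expect_length(eidx, 1L)
  expect_equal(cg$elabels[[eidx]], c(2L, 3L))
  expect_equal(cg$AS[["2-3"]], eidx)
})

test_that("prefix-graph recognition sets match hand construction", {
  # chord graph: P includes [e1,e2] (prefix vertex appears in the rollout)
  g <- chord_graph(c(10L, 10L, 10L))
  P <- build_phasing_set(g, unif_fld(2L, 12L))
  expect_true("2-3" %in% P$keys)
  pg <- build_prefix_graph(build_automaton(g, P))
  expect_true("2-3" %in% pg$vkeys)
  # AS of a two-exon pattern: all vertices whose label ends with it
  as23 <- pg$AS[["2-3"]]
  expect_true(all(vapply(pg$vpaths[as23], function(v)
    paste(utils::tail(v, 2L), collapse = "-") == "2-3", logical(1))))
  expect_gte(length(as23), 1L)
  # recognition sets of distinct two-exon patterns are disjoint
  as24 <- pg$AS[["2-4"]]
  expect_length(intersect(as23, as24), 0L)
  expect_gte(length(as24), 1L)
})

test_that("compact graphs are never larger than prefix graphs", {
  set.seed(42)
  for (i in 1:100) {
    fx <- small_fixture(7000L + i)
    P <- build_phasing_set(fx$graph, fx$fld)
    m <- prefix_graph_size_metrics(fx$graph, P)
    expect_lte(m$n_vertices[m$graph == "compact"],
               m$n_vertices[m$graph == "prefix"])
    expect_lte(m$n_edges[m$graph == "compact"],
               m$n_edges[m$graph == "prefix"])
  }
})

test_that("S-T and [S]-[T] path counts agree and lifts round-trip", {
  set.seed(43)
  for (i in 1:100) {
    fx <- small_fixture(8000L + i)
    P <- build_phasing_set(fx$graph, fx$fld)
    pg <- build_prefix_graph(build_automaton(fx$graph, P))
    cg <- build_compact_prefix_graph(fx$graph, P)
    nst <- count_st_paths(fx$graph)
    expect_equal(count_pg_paths(pg), nst)
    expect_equal(count_pg_paths(cg), nst)
    paths <- enumerate_st_paths(fx$graph, 1024L)
    sel <- sample(length(paths), min(5L, length(paths)))
    for (tp in paths[sel]) {
      expect_equal(project_path(pg, lift_path(pg, tp)), tp)
      expect_equal(project_path(cg, lift_path(cg, tp)), tp)
    }
  }
})

test_that("recognition is exact: one hit per contained path, none otherwise", {
  set.seed(44)
  for (i in 1:40) {
    fx <- small_fixture(9000L + i, short_exons = TRUE)
    P <- build_phasing_set(fx$graph, fx$fld)
    pg <- build_prefix_graph(build_automaton(fx$graph, P))
    cg <- build_compact_prefix_graph(fx$graph, P)
    for (tp in enumerate_st_paths(fx$graph, 256L)) {
      ve <- lift_path(pg, tp)
      vset <- lifted_vertices(pg, ve)
      ce <- lift_path(cg, tp)
      for (j in seq_along(P$paths)) {
        contained <- spliceflow:::is_subpath(P$paths[[j]], tp)
        expect_equal(length(intersect(vset, pg$AS[[j]])),
                     as.integer(contained))
        expect_equal(length(intersect(ce, cg$AS[[j]])),
                     as.integer(contained))
      }
    }
  }
})

test_that("prefix graphs are DAGs with unique source and sink", {
  set.seed(45)
  for (i in 1:20) {
    fx <- small_fixture(10000L + i)
    P <- build_phasing_set(fx$graph, fx$fld)
    for (pg in list(build_prefix_graph(build_automaton(fx$graph, P)),
                    build_compact_prefix_graph(fx$graph, P))) {
      # topological order exists (construction would have failed otherwise)
      expect_length(pg$topo, n_pg_vertices(pg))
      expect_length(pg$in_e[[pg$source]], 0L)
      expect_length(pg$out_e[[pg$sink]], 0L)
      # every vertex on a source-sink path: in-degree > 0 except source
      degs_in <- lengths(pg$in_e)
      degs_out <- lengths(pg$out_e)
      expect_true(all(degs_in[-pg$source] > 0L))
      expect_true(all(degs_out[-pg$sink] > 0L))
    }
  }
})

test_that("DOT export writes a parseable digraph", {
  g <- chord_graph()
  P <- build_phasing_set(g, unif_fld(2L, 12L))
  cg <- build_compact_prefix_graph(g, P)
  f <- withr::local_tempfile(fileext = ".dot")
  write_dot(cg, f)
  lines <- readLines(f)
  expect_equal(lines[1L], "digraph prefix_graph {")
  expect_equal(sum(grepl("->", lines, fixed = TRUE)), n_pg_edges(cg))
})
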