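test_that("loglik matches the closed-form examples", {
  # one path, count n, lhat 1, c 1 -> 0
  expect_equal(loglik(c(p = 5), c(p = 1), c(p = 1)), 0)
  # two symmetric paths: optimum at c = (0.5, 0.5) has value 2 log 0.5
  expect_equal(loglik(c(a = 1, b = 1), c(a = .5, b = .5), c(a = 1, b = 1)),
               2 * log(0.5))
  # count on a zero-abundance path -> -Inf with a diagnostic
  expect_warning(v <- loglik(c(a = 1), c(a = 0, b = 1), c(a = 1, b = 1)),
                 "zero abundance")
  expect_equal(v, -Inf)
  expect_error(loglik(c(a = 1), c(a = 1), c(b = 0)), "positive")
})

test_that("single-gene solver matches two-branch closed forms", {
  # parallel exons with equal effective lengths: counts 10 vs 30 must give
  # branch abundances in ratio 1:3 (two-variable ML closed form)
  g <- parallel_graph(c(80L, 80L))
  D <- unif_fld(2L, 60L)
  P <- build_phasing_set(g, D)
  gene <- prepare_gene(g, P)
  fl <- solve_single_gene(gene, c("2" = 10, "3" = 30), mass = 1)
  sol <- attr(fl, "solution")
  expect_equal(sol$c[["3"]] / sol$c[["2"]], 3, tolerance = 1e-7)
  expect_equal(sum(sol$c[c("2", "3")] * gene$lhat[c("2", "3")]), 1,
               tolerance = 1e-12)
  expect_lte(sol$gap, 1e-8 * max(1, abs(sol$objective)))
  # chain graph: all counts on [a] force the single S-T path
  gc <- chain_graph(c(50L, 50L))
  Pc <- build_phasing_set(gc, D)
  genec <- prepare_gene(gc, Pc)
  flc <- solve_single_gene(genec, c("2" = 7), mass = 1)
  expect_true(all(flc$w > 0))
  expect_equal(sum(attr(flc, "solution")$c[Pc$keys] * Pc$eff_len), 1,
               tolerance = 1e-12)
})

test_that("solver rejects structurally impossible inputs", {
  g <- chain_graph(c(50L, 50L))
  P <- build_phasing_set(g, unif_fld(2L, 60L))
  gene <- prepare_gene(g, P)
  expect_error(solve_single_gene(gene, c("9-9" = 1)), "not in the phasing")
  expect_error(solve_single_gene(gene, c("2" = 1), mass = 0), "mass > 0")
})

test_that("solver objective matches the enumeration oracle on random data", {
  set.seed(61)
  for (i in 1:20) {
    cfg <- sim_config(n_internal_vertices = sample(3:7, 1L),
                      edge_density = stats::runif(1, .3, .6),
                      n_transcripts = sample(2:4, 1L),
                      n_fragments = 500L, multimap_rate = 0,
                      seed = 13000L + i)
    ds <- simulate_dataset(cfg)
    if (count_st_paths(ds$graph) > 64) next
    st <- run_em(list(g = ds$gene), ds$fragments)
    orc <- oracle_quantify(ds$graph, ds$fragments, ds$fld)
    ll <- st$loglik_trace[length(st$loglik_trace)]
    expect_lt(abs(ll - orc$loglik) / abs(orc$loglik), 1e-6)
  }
})

test_that("E-step responsibilities normalize and follow c * A ratios", {
  fr1 <- fragment_record("f1", list(
    list(path = 2L, start_offset = 1L, frag_len = 5L, affinity = 1)))
  fr2 <- fragment_record("f2", list(
    list(path = 2L, start_offset = 1L, frag_len = 5L, affinity = 1),
    list(path = 3L, start_offset = 1L, frag_len = 5L, affinity = 1.5)))
  cab <- c("2" = 1, "3" = 2)
  z <- e_step(cab, list(fr1, fr2))
  expect_equal(unname(z[[1L]]), 1)
  expect_equal(unname(z[[2L]]), c(1, 3) / 4)
  # uniform abundances, equal affinities, k mappings -> 1/k each
  frk <- fragment_record("f3", list(
    list(path = 2L, start_offset = 1L, frag_len = 5L, affinity = 2),
    list(path = 3L, start_offset = 1L, frag_len = 5L, affinity = 2)))
  zk <- e_step(c("2" = 1, "3" = 1), list(frk))
  expect_equal(unname(zk[[1L]]), c(0.5, 0.5))
  expect_error(e_step(c("2" = 0, "3" = 0), list(frk)), "all-zero")
})

test_that("gene abundances are proportional to expected read counts", {
  g1 <- chain_graph(c(60L, 60L)); g1$gene_id <- "g1"
  g2 <- parallel_graph(c(70L, 90L)); g2$gene_id <- "g2"
  D <- unif_fld(2L, 50L)
  genes <- list(g1 = prepare_gene(g1, build_phasing_set(g1, D)),
                g2 = prepare_gene(g2, build_phasing_set(g2, D)))
  counts <- list(g1 = c("2" = 20, "3" = 10),
                 g2 = c("2" = 30, "3" = 40))
  ms <- m_step(genes, counts, n_frags = 100L)
  expect_equal(unname(ms$c_gene), c(0.3, 0.7))
  expect_equal(ms$s_gene, c(g1 = 30, g2 = 70))
  # per-gene normalization: sum over paths of c_p lhat_p = c_g
  for (gn in names(genes)) {
    expect_equal(sum(ms$c[[gn]] * genes[[gn]]$lhat), ms$c_gene[[gn]],
                 tolerance = 1e-10)
  }
  # a zero-count gene is skipped with zero flow
  ms0 <- m_step(genes, list(g1 = c("2" = 10), g2 = c("2" = 0)), 10L)
  expect_null(ms0$flows$g2)
  expect_equal(sum(ms0$c$g2), 0)
})

test_that("decoupled gene-level M-step matches a joint two-gene solve", {
  set.seed(62)
  g1 <- chord_graph(c(60L, 40L, 80L)); g1$gene_id <- "g1"
  g2 <- parallel_graph(c(70L, 90L)); g2$gene_id <- "g2"
  D <- unif_fld(10L, 80L)
  genes <- list(g1 = prepare_gene(g1, build_phasing_set(g1, D)),
                g2 = prepare_gene(g2, build_phasing_set(g2, D)))
  # fixed responsibilities (counts); joint objective optimizes both genes
  # under one global normalization
  counts <- list(g1 = c("2" = 25, "3" = 10, "4" = 30, "3-4" = 5),
                 g2 = c("2" = 12, "3" = 18))
  nF <- sum(unlist(counts))
  ms <- m_step(genes, counts, nF)
  dec_obj <- sum(vapply(names(genes), function(gn) {
    cnt <- counts[[gn]]
    sum(cnt * log(ms$c[[gn]][names(cnt)]))
  }, numeric(1)))
  # joint solve via transcript enumeration over the union with the global
  # constraint sum c_i lhat_i = 1: pseudo-fragments with one unit per count
  pseudo <- list()
  for (gn in names(genes)) {
    for (k in names(counts[[gn]])) {
      p <- as.integer(strsplit(k, "-", fixed = TRUE)[[1L]])
      pseudo <- c(pseudo, replicate(counts[[gn]][[k]], fragment_record(
        paste0(gn, k, length(pseudo)), list(list(path = p, start_offset = 1L,
                                                 frag_len = 1L, affinity = 1,
                                                 gene = gn))), simplify = FALSE))
    }
  }
  orc <- oracle_quantify(list(g1 = g1, g2 = g2), pseudo, D)
  expect_lt(abs(dec_obj - orc$loglik) / abs(orc$loglik), 1e-6)
})

test_that("EM converges immediately without multimapping and stays
          monotone with it", {
  cfg <- sim_config(n_internal_vertices = 5L, edge_density = .5,
                    n_transcripts = 3L, n_fragments = 800L,
                    multimap_rate = 0, seed = 71L)
  ds <- simulate_dataset(cfg)
  st <- run_em(list(g = ds$gene), ds$fragments)
  expect_lte(st$n_iter, 2L)
  cfg2 <- sim_config(n_internal_vertices = 6L, edge_density = .5,
                     n_transcripts = 4L, n_fragments = 1500L,
                     multimap_rate = .4, seed = 72L)
  ds2 <- simulate_dataset(cfg2)
  st2 <- run_em(list(g = ds2$gene), ds2$fragments)
  tr <- st2$loglik_trace
  expect_true(all(diff(tr) >= -1e-9 * pmax(1, abs(tr[-length(tr)]))))
  expect_true(st2$converged)
  # responsibilities normalize per fragment class
  expect_true(all(abs(vapply(st2$z, sum, numeric(1)) - 1) < 1e-12))
  # gene abundances sum to one
  expect_equal(sum(st2$c_gene), 1)
})

test_that("flow objective is concave along random feasible segments", {
  set.seed(63)
  cfg <- sim_config(n_internal_vertices = 6L, edge_density = .5,
                    n_transcripts = 3L, n_fragments = 600L,
                    multimap_rate = 0, seed = 80L)
  ds <- simulate_dataset(cfg)
  gene <- ds$gene
  cnt <- stats::setNames(gene$P$counts, gene$P$keys)
  cnt <- cnt[cnt > 0]
  obj <- function(fl) {
    cp <- path_abundances(fl)
    sum(cnt * log(cp[names(cnt)]))
  }
  paths <- enumerate_st_paths(ds$graph, 1024L)
  pg <- gene$pg
  for (r in 1:20) {
    mk <- function() {
      k <- sample(seq_along(paths), min(4L, length(paths)))
      qts <- quantified_transcripts(ds$graph, paths[k],
                                    stats::rgamma(length(k), 1) + 1e-3)
      transcripts_to_flow(pg, qts)
    }
    f1 <- mk(); f2 <- mk()
    if (any(path_abundances(f1)[names(cnt)] == 0) ||
        any(path_abundances(f2)[names(cnt)] == 0)) next
    lam <- stats::runif(1)
    fm <- pg_flow(pg, lam * f1$w + (1 - lam) * f2$w)
    expect_gte(obj(fm) - (lam * obj(f1) + (1 - lam) * obj(f2)), -1e-9)
  }
})
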