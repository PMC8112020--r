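# Shared fixtures and brute-force oracles used across the suite.

# S -> e1 -> T
minimal_graph <- function(len = 10L) {
  build_splice_graph(len, NULL, "minimal")
}

# chain S -> e1 -> e2 -> ... -> T
chain_graph <- function(lens = c(100L, 100L)) {
  n <- length(lens)
  j <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else NULL
  build_splice_graph(lens, j, "chain")
}

# two parallel exons: S -> a -> T, S -> b -> T
parallel_graph <- function(lens = c(60L, 80L)) {
  build_splice_graph(lens, NULL, "parallel")
}

# diamond with chord: junctions (1,2), (1,3), (2,3)
chord_graph <- function(lens = c(100L, 80L, 120L)) {
  build_splice_graph(lens, rbind(c(1, 2), c(1, 3), c(2, 3)), "chord")
}

# uniform fragment-length distribution on lo..hi
unif_fld <- function(lo, hi) {
  pmf <- numeric(hi)
  pmf[lo:hi] <- 1 / (hi - lo + 1)
  frag_len_dist(pmf)
}

# point mass at one length
point_fld <- function(len) {
  pmf <- numeric(len)
  pmf[len] <- 1
  frag_len_dist(pmf)
}

# small random fixture (graph + fld suitable for exhaustive checks)
small_fixture <- function(seed, n_max = 6L, short_exons = FALSE) {
  cfg <- sim_config(
    n_internal_vertices = sample(2:n_max, 1L),
    edge_density = stats::runif(1, 0.3, 0.7),
    exon_length_range = if (short_exons) c(3L, 8L) else c(40L, 120L),
    fld_spec = if (short_exons) list(pmf = {
      p <- numeric(8); p[2:8] <- 1 / 7; p
    }) else list(mean = 80, sd = 30, lo = 20L, hi = 160L),
    seed = seed)
  g <- random_splice_graph(cfg)
  list(cfg = cfg, graph = g, fld = sim_fld(cfg))
}

# brute-force phasing-set oracle: enumerate every window of every S-T path
phasing_windows_oracle <- function(g, D, limit = 256L) {
  keys <- character(0)
  for (tp in enumerate_st_paths(g, limit)) {
    ex <- tp[-c(1L, length(tp))]
    lens <- g$exon_len[ex]
    cum <- cumsum(c(0L, lens))
    L <- sum(lens)
    for (j in seq_len(L)) {
      for (k in j:L) {
        if (fld_d_test(D, k - j + 1L) > 0) {
          fi <- findInterval(j, cum + 1L)
          li <- findInterval(k, cum + 1L)
          keys <- c(keys, paste(ex[fi:li], collapse = "-"))
        }
      }
    }
  }
  sort(unique(keys))
}

fld_d_test <- function(D, l) {
  if (l >= 1L && l <= D$max_len) D$pmf[l] else 0
}

# vertices visited by a lifted path (source plus edge heads)
lifted_vertices <- function(pg, eidx) {
  c(pg$source, pg$edges[eidx, "to"])
}

# ground-truth path abundances of a qts: c_p = sum over containing transcripts
true_path_abundances <- function(qts, P) {
  vapply(seq_along(P$paths), function(j) {
    p <- P$paths[[j]]
    sum(qts$abundances[vapply(qts$transcripts, function(tv)
      spliceflow:::is_subpath(p, tv), logical(1))])
  }, numeric(1))
}
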