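#' Simulation configuration
#'
#' Parameters of the synthetic-data generator.  Defaults emulate a typical
#' short-read paired-end library on a moderately complex gene: fragment
#' lengths from a discretized normal with mean 350 and sd 70 truncated to
#' `[50, 600]` bases, subexon lengths of 50-300 bases, and flat Dirichlet
#' ground-truth abundances.
#'
#' @param n_internal_vertices Number of exon vertices.
#' @param edge_density Probability of each forward junction; 0 falls back
#'   to a simple chain.
#' @param n_transcripts Number of expressed ground-truth transcripts
#'   (capped at the number of distinct `S`-`T` paths).
#' @param abundance_dirichlet_alpha Dirichlet concentration for abundances.
#' @param exon_length_range Inclusive integer range of exon lengths.
#' @param fld_spec Either `list(mean=, sd=, lo=, hi=)` for a discretized
#'   normal, or `list(pmf=)` for an explicit pmf.
#' @param n_fragments Number of fragments to simulate.
#' @param multimap_rate Probability that a fragment is reported through its
#'   paired-end anchor blocks only, exposing inner-gap chain ambiguity.
#' @param read_len Mate length used for the anchor blocks.
#' @param max_out_degree Optional cap on vertex out-degree (set to 2 for
#'   fixtures meeting the minimal-sufficiency conditions).
#' @param seed Integer seed fixing every random draw.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_internal_vertices = 6L, edge_density = 0.4,
                       n_transcripts = 3L, abundance_dirichlet_alpha = 1,
                       exon_length_range = c(50L, 300L),
                       fld_spec = list(mean = 350, sd = 70,
                                       lo = 50L, hi = 600L),
                       n_fragments = 2000L, multimap_rate = 0.2,
                       read_len = 100L, max_out_degree = NULL, seed = 1L) {
  stopifnot(n_internal_vertices >= 1L, edge_density >= 0, edge_density <= 1,
            n_transcripts >= 1L, abundance_dirichlet_alpha > 0,
            length(exon_length_range) == 2L,
            exon_length_range[1L] >= 1L,
            exon_length_range[2L] >= exon_length_range[1L],
            n_fragments >= 1L, multimap_rate >= 0, multimap_rate <= 1,
            read_len >= 1L)
  structure(list(n_internal_vertices = as.integer(n_internal_vertices),
                 edge_density = edge_density,
                 n_transcripts = as.integer(n_transcripts),
                 abundance_dirichlet_alpha = abundance_dirichlet_alpha,
                 exon_length_range = as.integer(exon_length_range),
                 fld_spec = fld_spec,
                 n_fragments = as.integer(n_fragments),
                 multimap_rate = multimap_rate,
                 read_len = as.integer(read_len),
                 max_out_degree = max_out_degree,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Fragment-length distribution from a simulation config
#'
#' @param cfg A [sim_config()].
#' @return A [frag_len_dist()].
#' @export
sim_fld <- function(cfg) {
  fs <- cfg$fld_spec
  if (!is.null(fs$pmf)) frag_len_dist(fs$pmf)
  else normal_fld(fs$mean, fs$sd, fs$lo, fs$hi)
}

#' Random splice graph
#'
#' Samples a forward DAG on ordered exon vertices: each forward pair is a
#' junction with probability `edge_density` (subject to the optional
#' out-degree cap); `S` is attached to all exons without incoming junctions
#' and `T` from all exons without outgoing ones, so every vertex lies on an
#' `S`-`T` path by construction.  An empty junction draw falls back to the
#' chain.
#'
#' @param cfg A [sim_config()].
#' @param gene_id Gene name for the graph.
#' @return A `splice_graph`.
#' @export
random_splice_graph <- function(cfg, gene_id = "sim_gene") {
  set.seed(cfg$seed)
  n <- cfg$n_internal_vertices
  lens <- sample(cfg$exon_length_range[1L]:cfg$exon_length_range[2L],
                 n, replace = TRUE)
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < cfg$edge_density
  junc <- pairs[keep, , drop = FALSE]
  if (!nrow(junc) && n > 1L) junc <- cbind(seq_len(n - 1L), 2:n)
  junc <- junc[order(junc[, 1L], junc[, 2L]), , drop = FALSE]
  if (!is.null(cfg$max_out_degree)) {
    keep <- unlist(lapply(split(seq_len(nrow(junc)), junc[, 1L]),
                          function(i) utils::head(i, cfg$max_out_degree)))
    junc <- junc[sort(keep), , drop = FALSE]
  }
  build_splice_graph(lens, junc, gene_id)
}

#' Random ground-truth quantified transcript set
#'
#' Samples `n_transcripts` distinct `S`-`T` paths and Dirichlet abundances.
#'
#' @param g A `splice_graph`.
#' @param cfg A [sim_config()].
#' @param limit Path-enumeration guard.
#' @return A [quantified_transcripts()].
#' @export
simulate_transcripts <- function(g, cfg, limit = 4096L) {
  set.seed(cfg$seed + 1L)
  paths <- enumerate_st_paths(g, limit)
  k <- min(cfg$n_transcripts, length(paths))
  sel <- sort(sample.int(length(paths), k))
  ab <- stats::rgamma(k, shape = cfg$abundance_dirichlet_alpha)
  quantified_transcripts(g, paths[sel], ab / sum(ab))
}

#' Simulate fragments from the generative model
#'
#' A transcript is drawn with probability proportional to `c_i * lhat_i`,
#' then a window `(j, k)` with probability proportional to `D(k - j + 1)`,
#' matching the sequencing model without bias.  Each fragment is mapped to
#' the phasing path its window spans.  With probability `multimap_rate`,
#' fragments whose mates leave an inner gap are reported through their
#' anchor blocks instead, and every exon chain consistent with the anchors
#' (and with positive fragment-length probability) becomes a candidate
#' mapping with affinity `D(implied length)` -- the multimapping that EM
#' resolves.
#'
#' @param g A `splice_graph`.
#' @param qts Ground-truth [quantified_transcripts()].
#' @param D A [frag_len_dist()].
#' @param n Number of fragments.
#' @param seed Integer seed.
#' @param read_len Mate length for anchor blocks.
#' @param multimap_rate See [sim_config()].
#' @param gene Optional gene name attached to each mapping.
#' @return List of [fragment_record()]s.
#' @export
simulate_fragments <- function(g, qts, D, n, seed = 1L, read_len = 100L,
                               multimap_rate = 0, gene = NULL) {
  set.seed(seed)
  stopifnot(length(qts$transcripts) >= 1L)
  lhat <- transcript_eff_len(D, qts$lengths)
  pr <- qts$abundances * lhat
  if (sum(pr) <= 0) stop("no transcript can generate fragments under D")
  ti <- sample.int(length(pr), n, replace = TRUE, prob = pr)
  frags <- vector("list", n)
  mm <- stats::runif(n) < multimap_rate
  # per-transcript window samplers
  percs <- lapply(seq_along(qts$transcripts), function(i) {
    l <- qts$lengths[i]
    t <- seq_len(min(l, D$max_len))
    wt <- D$pmf[t] * (l + 1 - t)
    list(t = t, wt = wt, l = l,
         ex = qts$transcripts[[i]][-c(1L, length(qts$transcripts[[i]]))])
  })
  for (i in seq_len(n)) {
    tr <- percs[[ti[i]]]
    t <- sample(tr$t, 1L, prob = tr$wt)
    j <- sample.int(tr$l + 1L - t, 1L)
    frags[[i]] <- make_fragment(g, tr$ex, j, t, D,
                                sprintf("frag%06d", i),
                                anchors_only = mm[i], read_len = read_len,
                                gene = gene)
  }
  frags
}

# build a fragment_record for window (j, j+t-1) on exon chain ex
make_fragment <- function(g, ex, j, t, D, id, anchors_only = FALSE,
                          read_len = 100L, gene = NULL) {
  lens <- g$exon_len[ex]
  cum <- cumsum(c(0L, lens))
  fi <- findInterval(j, cum + 1L)           # first exon (1-based in chain)
  li <- findInterval(j + t - 1L, cum + 1L)  # last exon
  p <- ex[fi:li]
  start_offset <- j - cum[fi]
  amap <- list(path = p, start_offset = as.integer(start_offset),
               frag_len = as.integer(t), affinity = fld_d(D, t))
  if (!is.null(gene)) amap$gene <- gene
  if (anchors_only && t > 2L * read_len) {
    # exon spans of the two mate blocks
    e1 <- findInterval(j + read_len - 1L, cum + 1L)
    s2 <- findInterval(j + t - read_len, cum + 1L)
    u <- ex[e1]; w <- ex[s2]
    if (u != w) {
      chains <- enumerate_chains(g, u, w)
      p1 <- ex[fi:e1]
      p2 <- ex[s2:li]
      lead <- lens[fi] - start_offset + 1L            # bases in first exon
      tail_off <- (j + t - 1L) - cum[li]              # bases in last exon
      maps <- lapply(chains, function(ch) {
        full <- c(p1, ch[-1L], if (length(p2) > 1L) p2[-1L] else NULL)
        if (ch[length(ch)] != p2[1L]) return(NULL)
        tl <- sum(g$exon_len[full]) - (start_offset - 1L) -
          (g$exon_len[full[length(full)]] - tail_off)
        a <- fld_d(D, as.integer(tl))
        if (a <= 0) return(NULL)
        m <- list(path = full, start_offset = as.integer(start_offset),
                  frag_len = as.integer(tl), affinity = a)
        if (!is.null(gene)) m$gene <- gene
        m
      })
      maps <- Filter(Negate(is.null), maps)
      if (length(maps) >= 1L) return(fragment_record(id, maps))
    }
  }
  fragment_record(id, list(amap))
}

#' Transcript-enumeration quantification oracle
#'
#' The brute-force reference quantifier: enumerates every `S`-`T` path of
#' each gene as a candidate transcript and runs the standard quantification
#' EM (`z` over compatible transcripts, `c_i = n_i / (W lhat_i)`) under the
#' normalization `sum_i c_i lhat_i = 1`, with transcript effective lengths
#' from the closed form.  Its maximized log-likelihood is the target the
#' prefix-graph flow EM must reproduce.
#'
#' @param genes A `splice_graph` or named list of them.
#' @param fragments List of [fragment_record()]s (mappings may carry
#'   `gene`).
#' @param D A [frag_len_dist()].
#' @param limit Per-gene `S`-`T` path enumeration guard.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List: `qts` (named list of per-gene [quantified_transcripts()]),
#'   `loglik`, `n_iter`, `trace`.
#' @export
oracle_quantify <- function(genes, fragments, D, limit = 1024L,
                            tol = 1e-11, max_iter = 50000L) {
  if (inherits(genes, "splice_graph")) genes <- list(gene = genes)
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
  gnames <- names(genes)
  trs <- lapply(genes, enumerate_st_paths, limit = limit)
  tr_gene <- rep(seq_along(genes), lengths(trs))
  tr_all <- unlist(trs, recursive = FALSE)
  tr_len <- vapply(seq_along(tr_all), function(i) {
    p <- tr_all[[i]]
    sum(genes[[tr_gene[i]]]$exon_len[p[c(-1L, -length(p))]])
  }, numeric(1))
  lhat <- transcript_eff_len(D, tr_len)
  nt <- length(tr_all)
  # Collapse fragments to equivalence classes.  Uniquely mapped fragments
  # collapse per path (their affinity is an additive log constant); the
  # path->transcript containment is computed once per distinct path.
  contain <- new.env(parent = emptyenv())
  contain_row <- function(gi, p, pk) {
    key <- paste0(gi, "|", pk)
    if (!exists(key, envir = contain)) {
      b <- numeric(nt)
      hit <- which(tr_gene == gi)
      hit <- hit[vapply(tr_all[hit], function(tv) is_subpath(p, tv),
                        logical(1))]
      b[hit] <- 1
      assign(key, b, envir = contain)
    }
    get(key, envir = contain)
  }
  sig <- character(length(fragments))
  specs <- vector("list", length(fragments))
  const_ll <- 0
  for (fi in seq_along(fragments)) {
    fr <- fragments[[fi]]
    gis <- vapply(fr$mappings, function(m) {
      gi <- if (is.null(m$gene)) 1L else match(m$gene, gnames)
      if (is.na(gi)) stop("mapping refers to unknown gene ", m$gene)
      gi
    }, integer(1))
    pks <- vapply(fr$mappings, function(m) path_key(m$path), character(1))
    affs <- vapply(fr$mappings, function(m) m$affinity, numeric(1))
    paths <- lapply(fr$mappings, `[[`, "path")
    if (length(gis) == 1L) {
      if (affs <= 0) stop("fragment with zero affinity")
      const_ll <- const_ll + log(affs)
      affs <- 1
      sig[fi] <- paste0("U:", gis, "|", pks)
    } else {
      o <- order(gis, pks, affs)
      gis <- gis[o]; pks <- pks[o]; affs <- affs[o]; paths <- paths[o]
      sig[fi] <- paste(gis, pks, sprintf("%.17g", affs), sep = ":",
                       collapse = ";")
    }
    specs[[fi]] <- list(gis = gis, pks = pks, paths = paths, affs = affs)
  }
  u <- which(!duplicated(sig))
  B <- do.call(rbind, lapply(u, function(fi) {
    sp <- specs[[fi]]
    b <- numeric(nt)
    for (j in seq_along(sp$gis))
      b <- b + sp$affs[j] * contain_row(sp$gis[j], sp$paths[[j]], sp$pks[j])
    b
  }))
  ncls <- as.numeric(table(factor(sig, levels = sig[u])))
  W <- sum(ncls)
  live <- lhat > 0
  if (!any(live)) stop("no transcript with positive effective length")
  cvec <- numeric(nt)
  cvec[live] <- (1 / sum(live)) / lhat[live]
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    den <- as.vector(B %*% cvec)
    if (any(den <= 0))
      stop("fragment class incompatible with every transcript")
    ll <- const_ll + sum(ncls * log(den))
    znum <- B * rep(cvec, each = nrow(B))
    nvec <- as.vector(crossprod(znum / den, ncls))
    cvec[live] <- nvec[live] / (W * lhat[live])
    if (length(trace) &&
        abs(ll - trace[length(trace)]) <=
          tol * max(1, abs(trace[length(trace)]))) {
      trace <- c(trace, ll)
      break
    }
    trace <- c(trace, ll)
  }
  qts <- stats::setNames(lapply(seq_along(genes), function(gi) {
    sel <- which(tr_gene == gi)
    quantified_transcripts(genes[[gi]], tr_all[sel], cvec[sel])
  }), gnames)
  list(qts = qts, loglik = trace[length(trace)], n_iter = length(trace),
       trace = trace, lhat = lhat)
}

#' Prefix-graph size metrics
#'
#' Vertex and edge counts of the prefix graph and the compact prefix graph
#' built from a phasing set; the edge count is the number of flow
#' parameters the inference must estimate.
#'
#' @param g A `splice_graph`.
#' @param P A `phasing_set`.
#' @return Data frame with columns `graph`, `n_vertices`, `n_edges`.
#' @export
prefix_graph_size_metrics <- function(g, P) {
  pg <- build_prefix_graph(build_automaton(g, P))
  cg <- build_compact_prefix_graph(g, P)
  data.frame(graph = c("prefix", "compact"),
             n_vertices = c(n_pg_vertices(pg), n_pg_vertices(cg)),
             n_edges = c(n_pg_edges(pg), n_pg_edges(cg)))
}

#' Simulate a complete single-gene dataset
#'
#' Convenience wrapper chaining [random_splice_graph()],
#' [simulate_transcripts()], [sim_fld()], [simulate_fragments()],
#' [build_phasing_set()] and [prepare_gene()].
#'
#' @param cfg A [sim_config()].
#' @param graph_type Passed to [prepare_gene()].
#' @param prefix_closed Passed to [build_phasing_set()].
#' @return List: `cfg`, `graph`, `truth` (qts), `fld`, `fragments`,
#'   `phasing`, `gene`.
#' @export
simulate_dataset <- function(cfg, graph_type = "compact",
                             prefix_closed = FALSE) {
  g <- random_splice_graph(cfg)
  qts <- simulate_transcripts(g, cfg)
  D <- sim_fld(cfg)
  frags <- simulate_fragments(g, qts, D, cfg$n_fragments,
                              seed = cfg$seed + 2L,
                              read_len = cfg$read_len,
                              multimap_rate = cfg$multimap_rate)
  P <- build_phasing_set(g, D, frags, prefix_closed = prefix_closed)
  gene <- prepare_gene(g, P, type = graph_type)
  list(cfg = cfg, graph = g, truth = qts, fld = D, fragments = frags,
       phasing = P, gene = gene)
}
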