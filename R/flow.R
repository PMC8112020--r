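#' Network flows on prefix graphs
#'
#' A flow assigns a nonnegative weight to every edge of a (compact) prefix
#' graph such that incoming and outgoing weight balance at every internal
#' vertex.  Flows are the inference variable of graph quantification: their
#' source-sink decompositions are quantified transcript sets, and the
#' recognition sets turn them into path abundances.
#'
#' @param pg A `prefix_graph` or `compact_prefix_graph`.
#' @param weights Numeric vector of edge weights (length `n` edges).
#' @param check Validate balance (default `TRUE`).
#' @return Object of class `pg_flow` with fields `pg`, `w`.
#' @export
pg_flow <- function(pg, weights, check = TRUE) {
  stopifnot(length(weights) == n_pg_edges(pg), all(weights >= 0))
  fl <- structure(list(pg = pg, w = as.numeric(weights)), class = "pg_flow")
  if (check) check_flow_balance(fl)
  fl
}

#' @rdname pg_flow
#' @param fl A `pg_flow`.
#' @param rtol,atol Relative (of total flow) and absolute tolerances.
#' @export
check_flow_balance <- function(fl, rtol = 1e-9, atol = 1e-15) {
  pg <- fl$pg
  tot <- sum(fl$w[pg$out_e[[pg$source]]])
  for (v in seq_len(n_pg_vertices(pg))) {
    if (v == pg$source || v == pg$sink) next
    r <- abs(sum(fl$w[pg$in_e[[v]]]) - sum(fl$w[pg$out_e[[v]]]))
    if (r > rtol * max(tot, 1e-300) + atol)
      stop(sprintf("flow imbalance %.3g at vertex %d", r, v))
  }
  invisible(fl)
}

#' Vertex throughput of a flow
#'
#' Incoming flow at each vertex (outgoing at the source); the quantity
#' `f_v` through which the non-compact prefix graph recognizes phasing
#' paths.
#'
#' @param fl A `pg_flow`.
#' @return Numeric vector over vertices.
#' @export
vertex_throughput <- function(fl) {
  pg <- fl$pg
  vapply(seq_len(n_pg_vertices(pg)), function(v) {
    if (v == pg$source) sum(fl$w[pg$out_e[[v]]]) else sum(fl$w[pg$in_e[[v]]])
  }, numeric(1))
}

#' Map a quantified transcript set onto a prefix-graph flow
#'
#' Each transcript's lifted `[S]`-`[T]` path carries its abundance; edge
#' weights add.  The inverse direction is [decompose_flow()]; path
#' abundances are preserved both ways.
#'
#' @param pg A `prefix_graph` or `compact_prefix_graph`.
#' @param qts A [quantified_transcripts()] on the same splice graph.
#' @return A [pg_flow()].
#' @export
transcripts_to_flow <- function(pg, qts) {
  w <- numeric(n_pg_edges(pg))
  for (i in seq_along(qts$transcripts)) {
    e <- lift_path(pg, qts$transcripts[[i]])
    w[e] <- w[e] + qts$abundances[i]
  }
  pg_flow(pg, w)
}

#' Path abundance from a flow
#'
#' `c_p`, the total abundance of transcripts containing phasing path `p`,
#' read off the flow through the recognition set: vertex throughputs for a
#' prefix graph, edge weights for a compact prefix graph.
#'
#' @param fl A [pg_flow()].
#' @param p Integer vertex path, or its key string; must belong to the
#'   phasing set the graph was built from.
#' @return Numeric abundance.
#' @export
path_abundance <- function(fl, p) {
  pg <- fl$pg
  k <- if (is.character(p)) p else path_key(p)
  j <- match(k, pg$P$keys)
  if (is.na(j))
    stop("path is not in the phasing set; its abundance is not representable")
  if (inherits(pg, "compact_prefix_graph")) {
    sum(fl$w[pg$AS[[j]]])
  } else {
    sum(vertex_throughput(fl)[pg$AS[[j]]])
  }
}

#' All path abundances of a flow
#'
#' @param fl A [pg_flow()].
#' @return Named numeric vector over the phasing set (names are path keys).
#' @export
path_abundances <- function(fl) {
  pg <- fl$pg
  src <- if (inherits(pg, "compact_prefix_graph")) fl$w
         else vertex_throughput(fl)
  out <- vapply(pg$AS, function(s) sum(src[s]), numeric(1))
  names(out) <- pg$P$keys
  out
}

#' Decompose a flow into weighted transcripts
#'
#' Iterative greedy widest-path decomposition: repeatedly extract the
#' `[S]`-`[T]` path with the largest bottleneck on the remaining flow
#' (ties broken by lexicographic vertex order), subtract it, and project it
#' back to a transcript.  Produces at most one path per edge; residual
#' below `1e-12` of the total is clipped.  Note that flow decomposition is
#' not unique; this is the package's canonical, reproducible choice.
#'
#' @param fl A [pg_flow()].
#' @return A [quantified_transcripts()] whose [transcripts_to_flow()] image
#'   reproduces the input flow edge-wise.
#' @export
decompose_flow <- function(fl) {
  pg <- fl$pg
  check_flow_balance(fl)
  w <- fl$w
  tot <- sum(w[pg$out_e[[pg$source]]])
  clip <- 1e-12 * max(tot, 1e-300)
  paths <- list(); wts <- numeric(0)
  while (TRUE) {
    w[w < clip] <- 0
    if (sum(w[pg$out_e[[pg$source]]]) <= 0) break
    wp <- widest_pg_path(pg, w)
    if (is.null(wp) || wp$width <= 0) break
    e <- wp$edges
    paths[[length(paths) + 1L]] <- project_path(pg, e)
    wts <- c(wts, wp$width)
    w[e] <- w[e] - wp$width
    if (length(paths) > n_pg_edges(pg))
      stop("internal error: decomposition exceeded edge count")
  }
  quantified_transcripts(pg$graph, paths, wts)
}

# widest [S]-[T] path on edge weights w (0-weight edges unusable);
# lexicographic tie-break via topological scan order and smallest edge index
widest_pg_path <- function(pg, w) {
  nv <- n_pg_vertices(pg)
  best <- rep(-Inf, nv); best[pg$source] <- Inf
  prev <- rep(NA_integer_, nv)
  for (v in pg$topo) {
    if (best[v] == -Inf) next
    for (e in pg$out_e[[v]]) {
      if (w[e] <= 0) next
      u <- pg$edges[e, "to"]
      cand <- min(best[v], w[e])
      if (cand > best[u]) { best[u] <- cand; prev[u] <- e }
    }
  }
  if (!is.finite(best[pg$sink]) || best[pg$sink] <= 0) return(NULL)
  e <- integer(0); v <- pg$sink
  while (v != pg$source) {
    e <- c(prev[v], e)
    v <- pg$edges[prev[v], "from"]
  }
  list(edges = e, width = best[pg$sink])
}

#' Percent spliced in (PSI) for an exon triple
#'
#' For exons `(e_first, e_mid, e_last)`, PSI is the total abundance of
#' transcripts containing all three exons divided by the total abundance of
#' transcripts containing the first and last (the middle being optional).
#' When called on a flow, the canonical greedy decomposition is used first;
#' since decompositions are not unique, different decompositions of the
#' same flow may give different PSI values unless the relevant phasing
#' paths are in the phasing set -- a warning notes this.
#'
#' @param x A [quantified_transcripts()] or [pg_flow()].
#' @param e_first,e_mid,e_last Exon indices (1-based over exons).
#' @param ... Unused.
#' @return PSI in `[0, 1]`, or `NaN` (with a warning) when no transcript
#'   contains the flanking pair.
#' @export
compute_psi <- function(x, e_first, e_mid, e_last, ...) {
  UseMethod("compute_psi")
}

#' @export
compute_psi.quantified_transcripts <- function(x, e_first, e_mid, e_last,
                                               ...) {
  g <- x$graph
  v3 <- c(e_first, e_mid, e_last) + 1L
  if (any(v3 < 2L) || any(v3 > g$n - 1L) || any(g$kind[v3] != "exon"))
    stop("exon index absent from graph")
  num <- 0; den <- 0
  for (i in seq_along(x$transcripts)) {
    tv <- x$transcripts[[i]]
    if (all(v3[c(1L, 3L)] %in% tv)) {
      den <- den + x$abundances[i]
      if (v3[2L] %in% tv) num <- num + x$abundances[i]
    }
  }
  if (den <= 0) {
    warning("no transcript contains the flanking exons; PSI undefined")
    return(NaN)
  }
  num / den
}

#' @export
compute_psi.pg_flow <- function(x, e_first, e_mid, e_last, ...) {
  warning(paste0(
    "PSI from a flow uses the canonical greedy decomposition; ",
    "alternative decompositions of the same flow may yield different PSI"))
  compute_psi(decompose_flow(x), e_first, e_mid, e_last)
}

#' Detect skipped-exon triples from graph topology
#'
#' Returns every exon triple `(u, m, w)` with edges `u->m`, `m->w` and the
#' bypass `u->w` all present -- the standard topological signature of a
#' skipped (cassette) exon event.
#'
#' @param g A `splice_graph`.
#' @return Data frame with columns `e_first`, `e_mid`, `e_last` (exon
#'   indices).
#' @export
find_skipped_exon_triples <- function(g) {
  ex <- which(g$kind == "exon")
  out <- list()
  for (u in ex) {
    for (m in intersect(g$out[[u]], ex)) {
      for (w in intersect(g$out[[m]], ex)) {
        if (w %in% g$out[[u]])
          out[[length(out) + 1L]] <- c(u, m, w) - 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(e_first = integer(0), e_mid = integer(0),
                      e_last = integer(0)))
  m <- do.call(rbind, out)
  data.frame(e_first = m[, 1L], e_mid = m[, 2L], e_last = m[, 3L])
}

#' Write a flow as TSV
#'
#' Columns: `from`, `to` (vertex labels as comma-joined exon names) and
#' `weight`.
#'
#' @param fl A [pg_flow()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_flow_tsv <- function(fl, path) {
  pg <- fl$pg; g <- pg$graph
  lab <- vapply(pg$vpaths, function(p)
    paste(vertex_label(g, p), collapse = ","), character(1))
  utils::write.table(
    data.frame(from = lab[pg$edges[, "from"]],
               to = lab[pg$edges[, "to"]],
               weight = fl$w),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
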