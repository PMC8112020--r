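#' Aho-Corasick automaton over phasing paths
#'
#' Multi-pattern matching automaton whose alphabet is the splice-graph
#' vertex set and whose patterns are the phasing paths.  States are the
#' prefix closure of the phasing set (plus the single-vertex states `[S]`
#' and `[T]`); a transition from state `p` on exon `y` leads to the longest
#' suffix of `p + y` that is itself a state.  Transitions are generated only
#' for `y` that are splice-graph successors of `p`'s last vertex, because
#' the text being scanned is always an `S`-`T` path.
#'
#' @param g A `splice_graph`.
#' @param P A `phasing_set` on `g` (singletons always present).
#' @return Object of class `ac_automaton`: `states` (list of vertex paths,
#'   sorted by depth then lexicographically), `keys`, `trans` (per-state
#'   named vector: successor vertex id -> state index), `suffix_link`
#'   (0 = the empty root).
#' @export
build_automaton <- function(g, P) {
  for (p in P$paths) {
    if (!is_graph_path(g, p))
      stop("phasing path is not a splice-graph path: ", path_key(p))
  }
  states <- list()
  seen <- new.env(parent = emptyenv())
  add_state <- function(p) {
    k <- path_key(p)
    if (!exists(k, envir = seen)) {
      assign(k, TRUE, envir = seen)
      states[[length(states) + 1L]] <<- p
    }
  }
  add_state(g$S)
  add_state(g$T)
  for (p in P$paths) for (m in seq_along(p)) add_state(p[seq_len(m)])
  states <- states[order_paths(states)]
  keys <- vapply(states, path_key, character(1))
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(keys)) assign(keys[i], i, envir = idx)
  lookup <- function(p) {
    k <- path_key(p)
    if (exists(k, envir = idx)) get(k, envir = idx) else NA_integer_
  }
  longest_suffix_state <- function(p) {
    for (drop in 0:(length(p) - 1L)) {
      i <- lookup(p[(1L + drop):length(p)])
      if (!is.na(i)) return(i)
    }
    NA_integer_  # unreachable: singleton states always exist
  }
  trans <- vector("list", length(states))
  for (i in seq_along(states)) {
    p <- states[[i]]
    succ <- g$out[[p[length(p)]]]
    if (!length(succ)) { trans[[i]] <- integer(0); next }
    tr <- vapply(succ, function(y) longest_suffix_state(c(p, y)), integer(1))
    names(tr) <- succ
    trans[[i]] <- tr
  }
  suffix_link <- vapply(seq_along(states), function(i) {
    p <- states[[i]]
    if (length(p) == 1L) return(0L)
    for (drop in 1:(length(p) - 1L)) {
      j <- lookup(p[(1L + drop):length(p)])
      if (!is.na(j)) return(j)
    }
    0L
  }, integer(1))
  structure(list(graph = g, P = P, states = states, keys = keys,
                 trans = trans, suffix_link = suffix_link),
            class = "ac_automaton")
}

# order paths by (depth, lexicographic vertex sequence)
order_paths <- function(paths) {
  key <- vapply(paths, function(p)
    sprintf("%03d|%s", length(p),
            paste(sprintf("%06d", p), collapse = ",")), character(1))
  order(key)
}

#' Prefix graph
#'
#' The prefix graph unrolls the splice graph along the Aho-Corasick
#' automaton of the phasing set: vertices are automaton states (labeled by
#' splice-graph paths), edges are the restricted transitions, and a phasing
#' path `p` is recognized at the vertex set `AS(p) = {v : p is a suffix of
#' t(v)}`.  Network flows on it carry all path abundances:
#' `c_p = sum of the throughput of AS(p)`.
#'
#' Vertices on no `[S]`-`[T]` path (states never realized by any transcript
#' because a longer suffix always matches first) are pruned; they can carry
#' no flow.
#'
#' @param aut An [build_automaton()] result.
#' @return Object of class `prefix_graph`: `vpaths`, `vkeys`, `source`,
#'   `sink`, `edges` (matrix `from`, `to`, `y` = appended splice vertex),
#'   `AS` (per phasing-path list of vertex indices), `topo` (topological
#'   vertex order), plus the underlying `graph` and `P`.
#' @export
build_prefix_graph <- function(aut) {
  g <- aut$graph
  nst <- length(aut$states)
  efrom <- integer(0); eto <- integer(0); ey <- integer(0)
  for (i in seq_len(nst)) {
    tr <- aut$trans[[i]]
    if (length(tr)) {
      efrom <- c(efrom, rep(i, length(tr)))
      eto <- c(eto, unname(tr))
      ey <- c(ey, as.integer(names(tr)))
    }
  }
  src <- match(path_key(g$S), aut$keys)
  snk <- match(path_key(g$T), aut$keys)
  pg <- finish_graph(
    list(graph = g, P = aut$P, vpaths = aut$states, vkeys = aut$keys,
         source = src, sink = snk,
         edges = cbind(from = efrom, to = eto, y = ey)),
    class = "prefix_graph")
  # recognition sets on vertices
  AS <- rep(list(integer(0)), length(pg$P$paths))
  names(AS) <- pg$P$keys
  for (v in seq_along(pg$vpaths)) {
    p <- pg$vpaths[[v]]
    for (drop in 0:(length(p) - 1L)) {
      k <- path_key(p[(1L + drop):length(p)])
      j <- match(k, pg$P$keys)
      if (!is.na(j)) AS[[j]] <- c(AS[[j]], v)
    }
  }
  pg$AS <- AS
  pg
}

#' Compact prefix graph
#'
#' Variant of the prefix graph that recognizes phasing paths on edges.
#' Vertices are all single-vertex paths plus the strict prefixes of phasing
#' paths; an edge from `p` on successor exon `y` carries the label `p + y`
#' and leads to the longest suffix of `p + y` in the vertex set.  The
#' recognition set is `AS(p) = {e : p is a suffix of t(e)}` and
#' `c_p = sum_{e in AS(p)} f_e`.
#'
#' @param g A `splice_graph`.
#' @param P A `phasing_set` on `g`.
#' @return Object of class `compact_prefix_graph` with fields as in
#'   [build_prefix_graph()] plus `elabels` (list of edge label paths); `AS`
#'   holds edge indices.
#' @export
build_compact_prefix_graph <- function(g, P) {
  for (p in P$paths) {
    if (!is_graph_path(g, p))
      stop("phasing path is not a splice-graph path: ", path_key(p))
  }
  verts <- list()
  seen <- new.env(parent = emptyenv())
  add_v <- function(p) {
    k <- path_key(p)
    if (!exists(k, envir = seen)) {
      assign(k, TRUE, envir = seen)
      verts[[length(verts) + 1L]] <<- p
    }
  }
  for (v in seq_len(g$n)) add_v(v)          # all single-vertex paths
  for (p in P$paths) {
    if (length(p) > 1L)
      for (m in seq_len(length(p) - 1L)) add_v(p[seq_len(m)])
  }
  verts <- verts[order_paths(verts)]
  vkeys <- vapply(verts, path_key, character(1))
  idx <- new.env(parent = emptyenv())
  for (i in seq_along(vkeys)) assign(vkeys[i], i, envir = idx)
  longest_suffix_vertex <- function(p) {
    for (drop in 0:(length(p) - 1L)) {
      k <- path_key(p[(1L + drop):length(p)])
      if (exists(k, envir = idx)) return(get(k, envir = idx))
    }
    NA_integer_
  }
  efrom <- integer(0); eto <- integer(0); ey <- integer(0)
  elabels <- list()
  for (i in seq_along(verts)) {
    p <- verts[[i]]
    for (y in g$out[[p[length(p)]]]) {
      lab <- c(p, y)
      efrom <- c(efrom, i)
      eto <- c(eto, longest_suffix_vertex(lab))
      ey <- c(ey, y)
      elabels[[length(elabels) + 1L]] <- lab
    }
  }
  pg <- finish_graph(
    list(graph = g, P = P, vpaths = verts, vkeys = vkeys,
         source = get(path_key(g$S), envir = idx),
         sink = get(path_key(g$T), envir = idx),
         edges = cbind(from = efrom, to = eto, y = ey),
         elabels = elabels),
    class = "compact_prefix_graph")
  AS <- rep(list(integer(0)), length(P$paths))
  names(AS) <- P$keys
  for (e in seq_along(pg$elabels)) {
    lab <- pg$elabels[[e]]
    for (drop in 0:(length(lab) - 1L)) {
      k <- path_key(lab[(1L + drop):length(lab)])
      j <- match(k, P$keys)
      if (!is.na(j)) AS[[j]] <- c(AS[[j]], e)
    }
  }
  pg$AS <- AS
  pg
}

# prune vertices on no source-sink path, build adjacency, topo order,
# edge lookup (from|y -> edge index); edges may carry labels.
finish_graph <- function(pg, class) {
  nv <- length(pg$vpaths)
  E <- pg$edges
  fwd <- logical(nv); fwd[pg$source] <- TRUE
  repeat {
    new <- fwd[E[, "from"]] & !fwd[E[, "to"]]
    if (!any(new)) break
    fwd[E[new, "to"]] <- TRUE
  }
  bwd <- logical(nv); bwd[pg$sink] <- TRUE
  repeat {
    new <- bwd[E[, "to"]] & !bwd[E[, "from"]]
    if (!any(new)) break
    bwd[E[new, "from"]] <- TRUE
  }
  keepv <- fwd & bwd
  if (!keepv[pg$source] || !keepv[pg$sink])
    stop("internal error: source/sink disconnected")
  vmap <- cumsum(keepv); vmap[!keepv] <- NA_integer_
  keepe <- keepv[E[, "from"]] & keepv[E[, "to"]]
  E <- E[keepe, , drop = FALSE]
  E[, "from"] <- vmap[E[, "from"]]
  E[, "to"] <- vmap[E[, "to"]]
  pg$vpaths <- pg$vpaths[keepv]
  pg$vkeys <- pg$vkeys[keepv]
  pg$source <- vmap[pg$source]
  pg$sink <- vmap[pg$sink]
  if (!is.null(pg$elabels)) pg$elabels <- pg$elabels[keepe]
  ord <- order(E[, "from"], E[, "to"], E[, "y"])
  E <- E[ord, , drop = FALSE]
  if (!is.null(pg$elabels)) pg$elabels <- pg$elabels[ord]
  pg$edges <- E
  nv <- length(pg$vpaths)
  pg$out_e <- lapply(seq_len(nv), function(v) which(E[, "from"] == v))
  pg$in_e <- lapply(seq_len(nv), function(v) which(E[, "to"] == v))
  # Kahn topological order (also certifies the DAG property)
  indeg <- vapply(pg$in_e, length, integer(1))
  topo <- integer(0)
  queue <- sort(which(indeg == 0L))
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    topo <- c(topo, v)
    for (e in pg$out_e[[v]]) {
      w <- E[e, "to"]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(topo) != nv)
    stop("cycle in prefix graph (an exon would appear twice on a transcript)")
  pg$topo <- topo
  ekey <- new.env(parent = emptyenv())
  for (e in seq_len(nrow(E)))
    assign(sprintf("%d|%d", E[e, "from"], E[e, "y"]), e, envir = ekey)
  pg$ekey <- ekey
  structure(pg, class = class)
}

n_pg_vertices <- function(pg) length(pg$vpaths)
n_pg_edges <- function(pg) nrow(pg$edges)

#' Lift an S-T path onto a (compact) prefix graph
#'
#' Feeds the transcript's vertices to the automaton walk and returns the
#' traversed edges; `project_path()` inverts it.  By the path bijection the
#' lifted `[S]`-`[T]` path exists and is unique.
#'
#' @param pg A `prefix_graph` or `compact_prefix_graph`.
#' @param st_path Integer `S`-`T` vertex path of the underlying splice
#'   graph.
#' @return Integer vector of `pg` edge indices.
#' @export
lift_path <- function(pg, st_path) {
  if (st_path[1L] != pg$graph$S || st_path[length(st_path)] != pg$graph$T)
    stop("not an S-T path")
  v <- pg$source
  eidx <- integer(length(st_path) - 1L)
  for (i in seq_len(length(st_path) - 1L)) {
    y <- st_path[i + 1L]
    k <- sprintf("%d|%d", v, y)
    if (!exists(k, envir = pg$ekey))
      stop("internal error: missing transition while lifting path")
    e <- get(k, envir = pg$ekey)
    eidx[i] <- e
    v <- pg$edges[e, "to"]
  }
  if (v != pg$sink) stop("internal error: lift did not end at sink")
  eidx
}

#' @rdname lift_path
#' @param pg_path Integer vector of `pg` edge indices forming an
#'   `[S]`-`[T]` path.
#' @return `project_path` returns the corresponding splice-graph `S`-`T`
#'   path.
#' @export
project_path <- function(pg, pg_path) {
  if (!length(pg_path)) stop("empty prefix-graph path")
  if (pg$edges[pg_path[1L], "from"] != pg$source)
    stop("path does not start at [S]")
  c(pg$graph$S, pg$edges[pg_path, "y"])
}

#' Count [S]-[T] paths of a prefix graph
#'
#' Topological-order DP; the counterpart of [count_st_paths()] for the path
#' bijection checks.
#'
#' @param pg A `prefix_graph` or `compact_prefix_graph`.
#' @return Numeric path count.
#' @export
count_pg_paths <- function(pg) {
  cnt <- numeric(n_pg_vertices(pg))
  cnt[pg$sink] <- 1
  for (v in rev(pg$topo)) {
    if (v != pg$sink)
      cnt[v] <- sum(cnt[pg$edges[pg$out_e[[v]], "to"]])
  }
  cnt[pg$source]
}

#' @export
print.prefix_graph <- function(x, ...) {
  cat(sprintf("prefix_graph on '%s': %d vertices, %d edges, |P| = %d\n",
              x$graph$gene_id, n_pg_vertices(x), n_pg_edges(x),
              length(x$P$paths)))
  invisible(x)
}

#' @export
print.compact_prefix_graph <- function(x, ...) {
  cat(sprintf(
    "compact_prefix_graph on '%s': %d vertices, %d edges, |P| = %d\n",
    x$graph$gene_id, n_pg_vertices(x), n_pg_edges(x), length(x$P$paths)))
  invisible(x)
}

#' Export a prefix graph as GraphViz DOT
#'
#' @param pg A `prefix_graph` or `compact_prefix_graph`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dot <- function(pg, path) {
  g <- pg$graph
  lab <- vapply(pg$vpaths, function(p)
    paste(vertex_label(g, p), collapse = ","), character(1))
  lines <- c("digraph prefix_graph {",
             sprintf('  v%d [label="[%s]"];', seq_along(lab), lab))
  for (e in seq_len(n_pg_edges(pg))) {
    el <- if (!is.null(pg$elabels))
      sprintf(' [label="%s"]',
              paste(vertex_label(g, pg$elabels[[e]]), collapse = ","))
    else ""
    lines <- c(lines, sprintf("  v%d -> v%d%s;",
                              pg$edges[e, "from"], pg$edges[e, "to"], el))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}
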