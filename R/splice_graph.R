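#' @keywords internal
"_PACKAGE"

#' Splice graphs
#'
#' A splice graph is a directed acyclic graph describing the alternative
#' splicing structure of one gene.  Two virtual vertices `S` (transcript
#' start) and `T` (transcript termination) bracket the exon vertices; every
#' transcript of the gene corresponds to a unique `S`-`T` path, and under the
#' graph-quantification model every `S`-`T` path is a potential transcript.
#'
#' Internally vertices are stored in topological order: `S` first, then the
#' exons, then `T`; every edge points forward in that order.  Genomic
#' coordinates, when present, are 0-based half-open.  Exon vertices always
#' carry a length (`end - start` for annotated exons), which is what fragment
#' arithmetic uses; coordinates themselves are optional so that purely
#' synthetic graphs can be built.
#'
#' @param gene_id Single string naming the gene.
#' @param exon_len Integer vector of exon lengths (one per exon vertex, in
#'   topological order).
#' @param edges Two-column integer matrix of directed edges between vertex
#'   indices (1 = `S`, `2 .. n+1` = exons, `n+2` = `T`).
#' @param chrom,start,end,strand Optional per-exon genomic annotation
#'   (0-based half-open coordinates, transcription order).
#' @return An object of class `splice_graph`: a list with elements
#'   `gene_id`, `n` (vertex count), `kind` (`"S"`, `"exon"`, `"T"`),
#'   `exon_len`, `chrom`, `start`, `end`, `strand`, `edges`, `S`, `T`,
#'   `out` and `inn` (adjacency lists).
#' @keywords internal
new_splice_graph <- function(gene_id, exon_len, edges,
                             chrom = NULL, start = NULL, end = NULL,
                             strand = NULL) {
  n_ex <- length(exon_len)
  n <- n_ex + 2L
  kind <- c("S", rep("exon", n_ex), "T")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) == 0L) edges <- matrix(integer(0), ncol = 2L)
  colnames(edges) <- c("from", "to")
  # forward orientation is the DAG certificate
  if (any(edges[, 1L] >= edges[, 2L]))
    stop("splice graph edges must point forward in topological order")
  if (any(edges < 1L) || any(edges > n))
    stop("edge endpoint outside vertex range")
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  edges <- unique(edges)
  out <- lapply(seq_len(n),
                function(v) sort(unname(edges[edges[, 1L] == v, 2L])))
  inn <- lapply(seq_len(n),
                function(v) sort(unname(edges[edges[, 2L] == v, 1L])))
  g <- structure(list(
    gene_id = gene_id,
    n = n,
    kind = kind,
    exon_len = c(NA_integer_, as.integer(exon_len), NA_integer_),
    chrom = chrom, start = start, end = end, strand = strand,
    edges = edges,
    S = 1L, T = n,
    out = out, inn = inn
  ), class = "splice_graph")
  validate_splice_graph(g)
}

#' Validate splice-graph invariants
#'
#' Checks that the graph is a forward DAG, that `S` has in-degree 0 and `T`
#' out-degree 0, that exon lengths are positive, and that every exon vertex
#' lies on at least one `S`-`T` path.
#'
#' @param g A `splice_graph`.
#' @return `g`, invisibly-checked (errors on violation).
#' @export
validate_splice_graph <- function(g) {
  stopifnot(inherits(g, "splice_graph"))
  if (length(g$inn[[g$S]]) > 0L) stop("S must have in-degree 0")
  if (length(g$out[[g$T]]) > 0L) stop("T must have out-degree 0")
  ex <- which(g$kind == "exon")
  if (any(g$exon_len[ex] <= 0L, na.rm = TRUE))
    stop("exon lengths must be positive")
  if (!is.null(g$start) && !is.null(g$end)) {
    bad <- which(!is.na(g$start[ex]) & !is.na(g$end[ex]) &
                   g$start[ex] >= g$end[ex])
    if (length(bad)) stop("degenerate exon interval (start >= end)")
  }
  acc <- vertices_on_st_paths(g)
  stray <- setdiff(ex, acc)
  if (length(stray))
    stop("exon vertex not on any S-T path: ",
         paste(stray, collapse = ", "))
  g
}

# vertices reachable from S and co-reachable from T
vertices_on_st_paths <- function(g) {
  n <- g$n
  fwd <- logical(n); fwd[g$S] <- TRUE
  for (v in seq_len(n)) if (fwd[v]) fwd[g$out[[v]]] <- TRUE
  bwd <- logical(n); bwd[g$T] <- TRUE
  for (v in rev(seq_len(n))) if (bwd[v]) bwd[g$inn[[v]]] <- TRUE
  which(fwd & bwd)
}

#' Build a splice graph from exons and junctions
#'
#' Constructs the gene's splice graph from a table of exon intervals and a
#' list of junctions (exon-index pairs).  The virtual source `S` is connected
#' to each transcript's first exon and the sink `T` from each transcript's
#' last exon when `transcripts` are supplied; for junction-only input, `S`
#' connects to all exons without an incoming junction and `T` from all exons
#' without an outgoing one (the permissive closure).
#'
#' Exons must be supplied disjoint and in transcription order (minus-strand
#' genes are reversed into transcription order by [read_gtf()]); overlapping
#' exons are not split into partial exons here -- that is annotation
#' preprocessing.
#'
#' @param exons Data frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open) or a plain integer vector of exon lengths for
#'   coordinate-free graphs.
#' @param junctions Two-column matrix (or list of pairs) of exon indices,
#'   each pair `(i, j)` meaning exon `i` can be followed by exon `j`.
#' @param gene_id Gene identifier string.
#' @param transcripts Optional list of integer exon-index chains; used to
#'   place the `S`/`T` edges at annotated transcript ends.
#' @return A [new_splice_graph()] object.
#' @examples
#' g <- build_splice_graph(c(100L, 80L, 120L),
#'                         junctions = rbind(c(1, 2), c(1, 3), c(2, 3)),
#'                         gene_id = "toy")
#' enumerate_st_paths(g, limit = 10)
#' @export
build_splice_graph <- function(exons, junctions, gene_id,
                               transcripts = NULL) {
  if (is.data.frame(exons)) {
    exon_len <- as.integer(exons$end - exons$start)
    chrom  <- c(NA, as.character(exons$chrom), NA)
    start  <- c(NA_integer_, as.integer(exons$start), NA_integer_)
    end    <- c(NA_integer_, as.integer(exons$end), NA_integer_)
    strand <- c(NA, as.character(exons$strand), NA)
  } else {
    exon_len <- as.integer(exons)
    chrom <- start <- end <- strand <- NULL
  }
  n_ex <- length(exon_len)
  if (n_ex < 1L) stop("need at least one exon")
  if (any(exon_len <= 0L)) stop("degenerate exon interval")
  if (is.list(junctions) && !is.data.frame(junctions))
    junctions <- do.call(rbind, junctions)
  if (is.null(junctions) || length(junctions) == 0L)
    junctions <- matrix(integer(0), ncol = 2L)
  junctions <- matrix(as.integer(junctions), ncol = 2L)
  if (any(junctions < 1L) || any(junctions > n_ex))
    stop("dangling junction index (no such exon)")
  # cycle check on the exon order: junctions must be consistent with some
  # topological order; we require the supplied exon order to be one, and
  # report a back edge otherwise.
  back <- junctions[, 1L] >= junctions[, 2L]
  if (any(back)) {
    b <- junctions[which(back)[1L], ]
    stop(sprintf(
      "cycle detected: junction (%d -> %d) is a back edge in exon order",
      b[1L], b[2L]))
  }
  if (!is.null(transcripts) && length(transcripts)) {
    firsts <- unique(vapply(transcripts, function(ch) as.integer(ch[[1L]]),
                            integer(1)))
    lasts  <- unique(vapply(transcripts,
                            function(ch) as.integer(ch[[length(ch)]]),
                            integer(1)))
  } else {
    firsts <- setdiff(seq_len(n_ex), junctions[, 2L])
    lasts  <- setdiff(seq_len(n_ex), junctions[, 1L])
  }
  edges <- rbind(
    cbind(1L, firsts + 1L),
    cbind(junctions + 1L),
    cbind(lasts + 1L, n_ex + 2L)
  )
  new_splice_graph(gene_id, exon_len, edges,
                   chrom = chrom, start = start, end = end, strand = strand)
}

#' Map a transcript exon chain to its S-T path
#'
#' Each transcript corresponds to a unique `S`-`T` path of its gene's splice
#' graph; this prepends `S` and appends `T` to the exon chain after checking
#' every consecutive pair is an edge.
#'
#' @param g A `splice_graph`.
#' @param exon_chain Integer vector of exon indices (1-based over exons, in
#'   transcription order) or of vertex indices (then they must already
#'   exclude `S`/`T`).
#' @return Integer vector of vertex indices `c(S, chain, T)`.
#' @export
transcript_to_path <- function(g, exon_chain) {
  if (length(exon_chain) < 1L) stop("empty exon chain")
  v <- as.integer(exon_chain) + 1L  # exon i -> vertex i+1
  if (any(g$kind[v] != "exon")) stop("chain refers to non-exon vertex")
  p <- c(g$S, v, g$T)
  check_graph_path(g, p)
  p
}

# assert p is a path of g (every adjacent pair an edge)
check_graph_path <- function(g, p) {
  if (length(p) < 1L) stop("empty path")
  if (length(p) >= 2L) {
    for (i in seq_len(length(p) - 1L)) {
      if (!(p[i + 1L] %in% g$out[[p[i]]]))
        stop(sprintf("missing edge (%d -> %d)", p[i], p[i + 1L]))
    }
  }
  invisible(p)
}

is_graph_path <- function(g, p) {
  length(p) >= 1L &&
    all(vapply(seq_len(max(length(p) - 1L, 0L)),
               function(i) p[i + 1L] %in% g$out[[p[i]]], logical(1)))
}

#' Enumerate all S-T paths of a splice graph
#'
#' Exhaustive DFS enumeration in lexicographic (topological) vertex order,
#' guarded by `limit` because the number of `S`-`T` paths can be exponential
#' in graph size.  Used by the transcript-enumeration oracle.
#'
#' @param g A `splice_graph`.
#' @param limit Maximum number of paths before an overflow error.
#' @return List of integer vertex vectors, each starting at `S` and ending
#'   at `T`, in lexicographic order.
#' @export
enumerate_st_paths <- function(g, limit = 1024L) {
  stopifnot(limit >= 1L)
  paths <- vector("list", 0L)
  stack <- list(g$S)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- p[length(p)]
    if (v == g$T) {
      paths[[length(paths) + 1L]] <- p
      if (length(paths) > limit)
        stop(sprintf("S-T path count exceeds limit (%d); shrink the instance",
                     limit))
      next
    }
    succ <- g$out[[v]]
    # push in reverse so lexicographically smallest is expanded first
    for (y in rev(succ)) stack[[length(stack) + 1L]] <- c(p, y)
  }
  paths
}

#' Count S-T paths by dynamic programming
#'
#' Number of `S`-`T` paths via the standard topological-order recursion;
#' the independent cross-check for [enumerate_st_paths()].
#'
#' @param g A `splice_graph`.
#' @return Numeric path count.
#' @export
count_st_paths <- function(g) {
  cnt <- numeric(g$n)
  cnt[g$T] <- 1
  for (v in rev(seq_len(g$n))) {
    if (v != g$T) cnt[v] <- sum(cnt[g$out[[v]]])
  }
  cnt[g$S]
}

#' Quantified transcript sets
#'
#' A quantified transcript set pairs `S`-`T` paths with nonnegative
#' abundances; it is the object a conventional quantifier estimates, and what
#' flow decomposition produces.
#'
#' @param g A `splice_graph`.
#' @param transcripts List of `S`-`T` vertex paths.
#' @param abundances Nonnegative numeric vector, one per transcript.
#' @return Object of class `quantified_transcripts` with elements `graph`,
#'   `transcripts`, `abundances` and `lengths` (sums of exon lengths).
#' @export
quantified_transcripts <- function(g, transcripts, abundances) {
  stopifnot(length(transcripts) == length(abundances),
            all(abundances >= 0))
  for (p in transcripts) {
    if (p[1L] != g$S || p[length(p)] != g$T)
      stop("transcript is not an S-T path")
    check_graph_path(g, p)
  }
  lengths <- vapply(transcripts,
                    function(p) sum(g$exon_len[p[c(-1L, -length(p))]]),
                    numeric(1))
  structure(list(graph = g, transcripts = transcripts,
                 abundances = as.numeric(abundances),
                 lengths = as.integer(lengths)),
            class = "quantified_transcripts")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph '%s': %d exons, %d edges\n",
              x$gene_id, sum(x$kind == "exon"), nrow(x$edges)))
  invisible(x)
}

#' @export
print.quantified_transcripts <- function(x, ...) {
  cat(sprintf("quantified_transcripts: %d transcripts on '%s'\n",
              length(x$transcripts), x$graph$gene_id))
  invisible(x)
}

path_key <- function(p) paste(p, collapse = "-")

# human-readable vertex labels ("S", "e1".., "T")
vertex_label <- function(g, v) {
  ifelse(g$kind[v] == "S", "S",
         ifelse(g$kind[v] == "T", "T", paste0("e", v - 1L)))
}
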