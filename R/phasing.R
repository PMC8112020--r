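#' Fragment records
#'
#' A fragment (mapped read pair) together with its candidate phasing-path
#' mappings.  Each mapping carries the exon-vertex path, the fragment start
#' offset within the path's first exon, the (implied) fragment length, and
#' the mapping affinity `A(f|p)` used by the likelihood.
#'
#' @param fragment_id String id.
#' @param mappings List of lists with fields `path` (integer vertex vector),
#'   `start_offset`, `frag_len`, `affinity`.
#' @return Object of class `fragment_record`.
#' @export
fragment_record <- function(fragment_id, mappings) {
  if (!length(mappings)) stop("fragment needs at least one mapping")
  for (m in mappings) {
    stopifnot(length(m$path) >= 1L, m$frag_len >= 1L, m$affinity >= 0)
  }
  structure(list(fragment_id = fragment_id, mappings = mappings),
            class = "fragment_record")
}

#' Flatten fragment records to a mapping table
#'
#' One row per candidate mapping: `fragment_id`, `path` (dash-joined vertex
#' ids), `start_offset`, `frag_len`, `affinity`.
#'
#' @param fragments List of [fragment_record()]s.
#' @return A data frame.
#' @export
fragments_to_table <- function(fragments) {
  rows <- lapply(fragments, function(fr) {
    do.call(rbind, lapply(fr$mappings, function(m) {
      data.frame(fragment_id = fr$fragment_id,
                 path = path_key(m$path),
                 start_offset = m$start_offset,
                 frag_len = m$frag_len,
                 affinity = m$affinity)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname fragments_to_table
#' @param tab A mapping table as produced by `fragments_to_table`.
#' @export
table_to_fragments <- function(tab) {
  sp <- split(tab, tab$fragment_id)
  out <- lapply(sp, function(d) {
    fragment_record(d$fragment_id[1L], lapply(seq_len(nrow(d)), function(i) {
      list(path = as.integer(strsplit(d$path[i], "-", fixed = TRUE)[[1L]]),
           start_offset = d$start_offset[i],
           frag_len = d$frag_len[i],
           affinity = d$affinity[i])
    }))
  })
  names(out) <- NULL
  out
}

#' Read / write fragment mapping TSV
#'
#' Tab-separated file with columns `fragment_id`, `path`, `start_offset`,
#' `frag_len`, `affinity`; one row per candidate mapping.
#'
#' @param fragments List of [fragment_record()]s.
#' @param path File path.
#' @return `read_fragments_tsv` returns a list of [fragment_record()]s.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments_to_table(fragments), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(
    fragment_id = "character", path = "character"))
  table_to_fragments(tab)
}

#' Map aligned fragment blocks to candidate phasing paths
#'
#' Given the aligned blocks of a fragment (genomic intervals, 0-based
#' half-open, in transcription order; paired-end mates simply contribute
#' separate blocks), returns the candidate phasing-path mappings.  Blocks
#' must land inside exon vertices; when the inner gap between consecutive
#' blocks is consistent with several exon chains, one mapping per consistent
#' chain is emitted (to be resolved by EM as a multimapping); a unique chain
#' yields a single mapping including any unsequenced spanned exons.
#'
#' @param g A `splice_graph` with exon coordinates.
#' @param blocks Two-column matrix of `(start, end)` intervals.
#' @param D Optional [frag_len_dist()]; when given, chains whose implied
#'   fragment length has zero probability are dropped and mapping affinities
#'   are set to `D(implied length)`.
#' @param max_chains Guard on the number of candidate chains per gap.
#' @return List of mappings, each `list(path, start_offset, frag_len,
#'   affinity)`.
#' @export
fragment_to_path <- function(g, blocks, D = NULL, max_chains = 64L) {
  if (is.null(g$start) || is.null(g$end))
    stop("fragment_to_path needs exon coordinates on the graph")
  blocks <- matrix(as.numeric(blocks), ncol = 2L)
  if (!nrow(blocks)) stop("no blocks")
  spans <- lapply(seq_len(nrow(blocks)),
                  function(i) block_to_span(g, blocks[i, 1L], blocks[i, 2L]))
  # combine consecutive block spans, branching over gap chains
  paths <- list(spans[[1L]]$chain)
  for (i in seq_len(length(spans) - 1L)) {
    nxt <- spans[[i + 1L]]$chain
    paths <- unlist(lapply(paths, function(pth) {
      u <- pth[length(pth)]; w <- nxt[1L]
      if (u == w) {
        list(c(pth, nxt[-1L]))
      } else {
        chains <- enumerate_chains(g, u, w, max_chains)
        if (!length(chains))
          stop("unmappable fragment: blocks touch exons with no connecting path")
        lapply(chains, function(ch) c(pth, ch[-1L], nxt[-1L]))
      }
    }), recursive = FALSE)
    if (!length(paths))
      stop("unmappable fragment: blocks touch exons with no connecting path")
  }
  first_ex <- spans[[1L]]$chain[1L]
  start_offset <- spans[[1L]]$start_off
  last_sp <- spans[[length(spans)]]
  end_off <- last_sp$end_off     # bases into the final exon
  maps <- lapply(paths, function(pth) {
    lens <- g$exon_len[pth]
    frag_len <- sum(lens) - (start_offset - 1L) - (lens[length(lens)] - end_off)
    list(path = pth, start_offset = start_offset,
         frag_len = as.integer(frag_len),
         affinity = if (is.null(D)) 1 else fld_d(D, as.integer(frag_len)))
  })
  if (!is.null(D)) maps <- Filter(function(m) m$affinity > 0, maps)
  if (!length(maps))
    stop("unmappable fragment: no chain consistent with the fragment-length distribution")
  maps
}

# map one contiguous block to the exon chain it covers
block_to_span <- function(g, s, e) {
  ex <- which(g$kind == "exon")
  hit <- ex[!is.na(g$start[ex]) & g$start[ex] < e & g$end[ex] > s]
  if (!length(hit)) stop("unmappable fragment: block outside all exons")
  hit <- sort(hit)
  if (s < g$start[hit[1L]] || e > g$end[hit[length(hit)]])
    stop("unmappable fragment: block extends outside exon boundaries")
  if (length(hit) > 1L) {
    for (i in seq_len(length(hit) - 1L)) {
      if (!(hit[i + 1L] %in% g$out[[hit[i]]]))
        stop("unmappable fragment: block spans non-adjacent exons")
    }
  }
  list(chain = hit,
       start_off = as.integer(s - g$start[hit[1L]] + 1L),
       end_off = as.integer(e - g$start[hit[length(hit)]]))
}

# all u -> w chains (inclusive); error when more than max_chains
enumerate_chains <- function(g, u, w, max_chains = 64L) {
  res <- list()
  stack <- list(u)
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- p[length(p)]
    if (v == w) { res[[length(res) + 1L]] <- p; next }
    if (v > w) next  # forward order: overshot
    for (y in rev(g$out[[v]])) {
      if (y <= w && g$kind[y] == "exon") stack[[length(stack) + 1L]] <- c(p, y)
    }
    if (length(res) > max_chains)
      stop("too many candidate chains between fragment anchors")
  }
  res
}

#' Phasing sets
#'
#' The set `P` of phasing paths of a gene: all splice-graph paths with
#' positive effective length under the fragment-length distribution (capped
#' by its maximum length `M`), always including every singleton exon path.
#' Per-path expected fragment counts are aggregated from the fragment
#' mappings (multimapped fragments contribute affinity-normalized
#' fractions; EM later refines these).
#'
#' @param g A `splice_graph`.
#' @param D A [frag_len_dist()].
#' @param fragments List of [fragment_record()]s (may be empty).
#' @param aff Optional [affinity_model()] used for effective lengths
#'   (default: `no_bias` on `D`).
#' @param prefix_closed If `TRUE`, close the set under path prefixes (the
#'   precondition of the compact prefix graph's minimal-sufficiency
#'   guarantee).
#' @return Object of class `phasing_set` with `paths`, `keys`, `counts`,
#'   `eff_len`, `graph`, `fld`.
#' @export
build_phasing_set <- function(g, D, fragments = list(), aff = NULL,
                              prefix_closed = FALSE) {
  if (is.null(aff)) aff <- affinity_model(D)
  cand <- enumerate_phasing_candidates(g, D$max_len)
  keys <- vapply(cand, path_key, character(1))
  lhat <- vapply(cand, function(p) path_eff_len(g, p, aff), numeric(1))
  singleton <- lengths(cand) == 1L
  keep <- lhat > 0 | singleton
  cand <- cand[keep]; keys <- keys[keep]; lhat <- lhat[keep]
  # aggregate counts from fragment mappings
  counts <- numeric(length(cand))
  names(counts) <- keys
  for (fr in fragments) {
    aw <- vapply(fr$mappings, function(m) m$affinity, numeric(1))
    if (sum(aw) <= 0) aw <- rep(1, length(aw))
    aw <- aw / sum(aw)
    for (i in seq_along(fr$mappings)) {
      k <- path_key(fr$mappings[[i]]$path)
      j <- match(k, keys)
      if (is.na(k) || is.na(j)) {
        # mapped path outside the structural candidate set: add it
        p <- fr$mappings[[i]]$path
        cand <- c(cand, list(p))
        keys <- c(keys, k)
        lhat <- c(lhat, path_eff_len(g, p, aff))
        counts <- c(counts, 0)
        names(counts) <- keys
        j <- length(cand)
      }
      counts[j] <- counts[j] + aw[i]
    }
  }
  ps <- structure(list(graph = g, fld = D, paths = cand, keys = keys,
                       counts = unname(counts), eff_len = lhat),
                  class = "phasing_set")
  if (prefix_closed) ps <- prefix_close_phasing_set(ps, aff) else ps
}

# all paths whose minimal exactly-mapping fragment length is <= M
enumerate_phasing_candidates <- function(g, M) {
  ex <- which(g$kind == "exon")
  out <- list()
  for (u in ex) {
    stack <- list(u)
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      out[[length(out) + 1L]] <- p
      lead <- g$exon_len[p[1L]]
      cum <- sum(g$exon_len[p])
      for (y in g$out[[p[length(p)]]]) {
        if (g$kind[y] != "exon") next
        # extending p by y: interior becomes cum - lead
        if (cum - lead + 2L <= M) stack[[length(stack) + 1L]] <- c(p, y)
      }
    }
  }
  out
}

#' Close a phasing set under prefixes
#'
#' Adds every strict prefix of each path (with zero count) so that the
#' compact prefix graph built from the set satisfies the prefix-closure
#' condition of the minimal-sufficiency theorem.
#'
#' @param P A `phasing_set`.
#' @param aff Optional [affinity_model()] for the added paths' effective
#'   lengths.
#' @return A `phasing_set`.
#' @export
prefix_close_phasing_set <- function(P, aff = NULL) {
  if (is.null(aff)) aff <- affinity_model(P$fld)
  have <- new.env(parent = emptyenv())
  for (k in P$keys) assign(k, TRUE, envir = have)
  add <- list()
  for (p in P$paths) {
    if (length(p) > 1L) {
      for (m in seq_len(length(p) - 1L)) {
        q <- p[seq_len(m)]
        k <- path_key(q)
        if (!exists(k, envir = have)) {
          assign(k, TRUE, envir = have)
          add[[length(add) + 1L]] <- q
        }
      }
    }
  }
  if (!length(add)) return(P)
  P$paths <- c(P$paths, add)
  P$keys <- c(P$keys, vapply(add, path_key, character(1)))
  P$counts <- c(P$counts, numeric(length(add)))
  P$eff_len <- c(P$eff_len,
                 vapply(add, function(p) path_eff_len(P$graph, p, aff),
                        numeric(1)))
  P
}

#' Trim a phasing set
#'
#' Removes phasing paths that have no mapped fragments and an effective
#' length below `min_eff_len`.  Singletons and any path with a positive
#' count are never removed.  The likelihood simply omits trimmed paths from
#' its normalization; no renormalization is applied (the induced
#' overestimation is argued to be negligible precisely because the removed
#' paths have tiny effective length).
#'
#' Default threshold: the effective-length mass contributed by a single
#' window at the 99.5th percentile of the fragment-length distribution --
#' the regime of "extra-long phasing paths only reachable through the long
#' tail".
#'
#' @param P A `phasing_set`.
#' @param min_eff_len Numeric threshold; paths with `count == 0` and
#'   `eff_len < min_eff_len` are dropped.
#' @return A trimmed `phasing_set`.
#' @export
trim_phasing_set <- function(P, min_eff_len = NULL) {
  if (is.null(min_eff_len)) {
    cdf <- cumsum(P$fld$pmf)
    q <- which(cdf >= 0.995)[1L]
    min_eff_len <- P$fld$pmf[q]
  }
  singleton <- lengths(P$paths) == 1L
  drop <- !singleton & P$counts == 0 & P$eff_len < min_eff_len
  P$paths <- P$paths[!drop]
  P$keys <- P$keys[!drop]
  P$counts <- P$counts[!drop]
  P$eff_len <- P$eff_len[!drop]
  P
}

#' @export
print.phasing_set <- function(x, ...) {
  cat(sprintf("phasing_set on '%s': %d paths (%d singletons), %g fragments\n",
              x$graph$gene_id, length(x$paths), sum(lengths(x$paths) == 1L),
              sum(x$counts)))
  invisible(x)
}
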