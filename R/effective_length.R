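#' Fragment-length distributions
#'
#' A discrete probability mass function `D(l)` over fragment lengths
#' `1..max_len`.  `D` drives every effective-length computation and, in the
#' bias-free affinity model, equals the affinity of any fragment window of
#' that length.
#'
#' @param pmf Numeric vector of probabilities; `pmf[l]` is `D(l)`.
#' @return Object of class `frag_len_dist` with fields `pmf` and `max_len`.
#' @export
frag_len_dist <- function(pmf) {
  pmf <- as.numeric(pmf)
  if (any(pmf < 0)) stop("negative probability in fragment-length pmf")
  s <- sum(pmf)
  if (abs(s - 1) > 1e-12)
    stop(sprintf("fragment-length pmf sums to %.15g, not 1", s))
  max_len <- max(c(0L, which(pmf > 0)))
  if (max_len == 0L) stop("fragment-length pmf is all zero")
  structure(list(pmf = pmf[seq_len(max_len)], max_len = max_len),
            class = "frag_len_dist")
}

# D(l), vectorized, zero outside support
fld_d <- function(D, l) {
  out <- numeric(length(l))
  ok <- l >= 1L & l <= D$max_len
  out[ok] <- D$pmf[l[ok]]
  out
}

#' Empirical fragment-length distribution
#'
#' Normalized histogram of observed fragment lengths, with optional
#' rectangular kernel smoothing (half-width `smooth`) to fill sampling gaps.
#'
#' @param lengths Positive integer vector of observed fragment lengths.
#' @param smooth Non-negative integer half-width; 0 disables smoothing.
#' @return A [frag_len_dist()].
#' @export
empirical_fld <- function(lengths, smooth = 0L) {
  lengths <- as.integer(lengths)
  if (!length(lengths) || any(lengths < 1L))
    stop("need a nonempty vector of positive fragment lengths")
  M <- max(lengths)
  h <- tabulate(lengths, nbins = M)
  if (smooth > 0L) {
    k <- rep(1, 2L * smooth + 1L)
    h <- as.numeric(stats::filter(c(rep(0, smooth), h, rep(0, smooth)), k,
                                  sides = 2L))[smooth + seq_len(M)]
  }
  frag_len_dist(h / sum(h))
}

#' Discretized normal fragment-length distribution
#'
#' Gaussian pmf discretized on `lo..hi` and renormalized; the stock
#' parametric model for paired-end libraries.
#'
#' @param mean,sd Normal parameters in bases.
#' @param lo,hi Truncation range (inclusive).
#' @return A [frag_len_dist()].
#' @export
normal_fld <- function(mean = 350, sd = 70, lo = 50L, hi = 600L) {
  stopifnot(lo >= 1L, hi >= lo)
  l <- lo:hi
  w <- stats::dnorm(l, mean, sd)
  pmf <- numeric(hi)
  pmf[l] <- w / sum(w)
  frag_len_dist(pmf)
}

#' Transcript effective length
#'
#' The effective length of a transcript of length `l` is the total
#' probability mass of fragment windows it can generate,
#' `sum_{j<=k<=l} D(k-j+1) = sum_t D(t) (l+1-t)`.  The classical form used
#' by conventional quantifiers, `(sum_{t<=l} D(t)) * (l+1-mu)` with `mu` the
#' truncated mean of `D`, is algebraically identical; both are exposed and
#' agree to machine precision.
#'
#' @param D A [frag_len_dist()].
#' @param l Transcript length (bases), `l >= 1`.
#' @param form `"window"` (the window-sum definition) or `"classical"`.
#' @return Effective length (numeric scalar; vectorized over `l`).
#' @export
transcript_eff_len <- function(D, l, form = c("window", "classical")) {
  form <- match.arg(form)
  vapply(as.integer(l), function(li) {
    stopifnot(li >= 1L)
    t <- seq_len(min(li, D$max_len))
    dt <- D$pmf[t]
    if (form == "window") {
      sum(dt * (li + 1 - t))
    } else {
      s <- sum(dt)
      if (s == 0) return(0)
      mu <- sum(t * dt) / s
      s * (li + 1 - mu)
    }
  }, numeric(1))
}

#' Affinity models
#'
#' The affinity `A_p(j, k)` is the unnormalized likelihood of generating a
#' fragment occupying positions `j..k` (1-based inclusive) of the
#' concatenated sequence of path `p`.  Without bias correction it is exactly
#' `D(k - j + 1)`; with positional bias it is the reference-weighted mean of
#' per-transcript bias affinities (see [positional_affinity()]).
#'
#' @param D A [frag_len_dist()].
#' @param mode `"no_bias"` or `"positional"`.
#' @param bias A [reference_bias()] object (required for positional mode).
#' @return Object of class `affinity_model` with an `evaluate(g, p, j, k)`
#'   function.
#' @export
affinity_model <- function(D, mode = c("no_bias", "positional"),
                           bias = NULL) {
  mode <- match.arg(mode)
  if (mode == "positional" && is.null(bias))
    stop("positional mode needs a reference_bias object")
  ev <- if (mode == "no_bias") {
    function(g, p, j, k) fld_d(D, k - j + 1L)
  } else {
    function(g, p, j, k) positional_affinity(bias, g, p, j, k)
  }
  structure(list(D = D, mode = mode, bias = bias, evaluate = ev),
            class = "affinity_model")
}

#' Reference-transcript positional bias
#'
#' Transcript-specific positional bias cannot enter the path model directly
#' (it depends on the full transcript, not just the phasing path), so it is
#' approximated by the abundance-weighted empirical positional bias over a
#' reference transcriptome: `A_p(j,k) = sum_i r_i B_i(j',k') / sum_i r_i`,
#' the sums running over reference transcripts containing `p`, with `(j',k')`
#' the window translated into transcript coordinates.
#'
#' `B_i(j,k)` is modeled as a piecewise-constant function of the fragment
#' midpoint's relative position in the transcript (`n_bins` equal bins)
#' multiplied by `D(k-j+1)`.
#'
#' @param g A `splice_graph`.
#' @param transcripts List of `S`-`T` vertex paths (reference transcripts).
#' @param abundances Reference abundances `r_i` (nonnegative).
#' @param D A [frag_len_dist()].
#' @param bin_weights Numeric vector of per-bin multipliers (default 5 flat
#'   bins, i.e. no positional preference).
#' @return Object of class `reference_bias`.
#' @export
reference_bias <- function(g, transcripts, abundances, D,
                           bin_weights = rep(1, 5)) {
  stopifnot(length(transcripts) == length(abundances),
            all(abundances >= 0), all(bin_weights >= 0))
  structure(list(graph = g, transcripts = transcripts,
                 abundances = as.numeric(abundances), D = D,
                 bin_weights = as.numeric(bin_weights)),
            class = "reference_bias")
}

# B_i(j,k) on transcript coordinates: positional bin weight times D(length)
bias_B <- function(bias, tr_len, j, k) {
  nb <- length(bias$bin_weights)
  mid <- (j + k) / 2
  bin <- pmin(nb, pmax(1L, ceiling(mid / tr_len * nb)))
  bias$bin_weights[bin] * fld_d(bias$D, k - j + 1L)
}

#' Positional-bias affinity of a path window
#'
#' Evaluates the abundance-weighted mean of reference-transcript bias values
#' at the window translated into each containing transcript's coordinates.
#' Errors if no reference transcript contains `p` (fall back to the
#' `no_bias` model in that case).
#'
#' @param bias A [reference_bias()].
#' @param g A `splice_graph` (must match `bias$graph`).
#' @param p Integer vertex path (exon vertices only).
#' @param j,k Window on the concatenated path sequence, 1-based inclusive.
#' @return Affinity value (numeric scalar).
#' @export
positional_affinity <- function(bias, g, p, j, k) {
  hit <- vapply(bias$transcripts, function(tr) is_subpath(p, tr), logical(1))
  hit <- hit & bias$abundances > 0
  if (!any(hit))
    stop("no reference transcript contains the path; use no_bias affinity")
  num <- 0; den <- 0
  for (i in which(hit)) {
    tr <- bias$transcripts[[i]]
    ex <- tr[c(-1L, -length(tr))]
    tr_len <- sum(g$exon_len[ex])
    # offset of p's first exon within the transcript sequence
    pos <- match(p[1L], ex)
    off <- if (pos > 1L) sum(g$exon_len[ex[seq_len(pos - 1L)]]) else 0L
    b <- bias_B(bias, tr_len, j + off, k + off)
    num <- num + bias$abundances[i] * b
    den <- den + bias$abundances[i]
  }
  num / den
}

# is p a contiguous subpath of q?
is_subpath <- function(p, q) {
  np <- length(p); nq <- length(q)
  if (np > nq) return(FALSE)
  for (s in seq_len(nq - np + 1L)) {
    if (all(q[s:(s + np - 1L)] == p)) return(TRUE)
  }
  FALSE
}

#' Path effective length
#'
#' The effective length of a phasing path `p` is the total affinity mass of
#' fragment windows whose exon span is exactly `p`: windows starting inside
#' `p`'s first exon and ending inside its last exon (covering the interior
#' entirely).  It generalizes transcript effective length and is independent
#' of any embedding transcript in the `no_bias` model.
#'
#' For the `no_bias` model a closed form is used: with first/last exon
#' lengths `L1`, `Lm` and interior length `I`, the number of windows of
#' total length `t` is `#\{(x,b) : x+b = t-I, 1<=x<=L1, 1<=b<=Lm\}`, so
#' `lhat_p = sum_t D(t) N(t-I)`.  For general affinities the windows are
#' enumerated.
#'
#' @param g A `splice_graph`.
#' @param p Integer vertex path over exon vertices (no `S`/`T`).
#' @param aff An [affinity_model()] (or a [frag_len_dist()], promoted to the
#'   `no_bias` model).
#' @return Effective length (numeric scalar).
#' @export
path_eff_len <- function(g, p, aff) {
  if (inherits(aff, "frag_len_dist")) aff <- affinity_model(aff)
  p <- as.integer(p)
  if (!length(p)) stop("empty path")
  if (any(g$kind[p] != "exon")) stop("path must consist of exon vertices")
  check_graph_path(g, p)
  if (!path_has_embedding(g, p))
    stop("path cannot be extended to an S-T path")
  L <- g$exon_len[p]
  m <- length(p)
  if (aff$mode == "no_bias") {
    D <- aff$D
    if (m == 1L) {
      l <- L[1L]
      t <- seq_len(min(l, D$max_len))
      return(sum(D$pmf[t] * (l + 1 - t)))
    }
    L1 <- L[1L]; Lm <- L[m]; I <- if (m > 2L) sum(L[2:(m - 1L)]) else 0L
    thi <- min(I + L1 + Lm, D$max_len)
    if (I + 2L > thi) return(0)
    t <- (I + 2L):thi
    s <- t - I
    nwin <- pmin(s - 1L, L1, Lm, L1 + Lm - s + 1L)
    return(sum(D$pmf[t] * pmax(nwin, 0L)))
  }
  # generic affinity: enumerate windows with exon span exactly p
  tot <- sum(L)
  if (m == 1L) {
    acc <- 0
    for (j in seq_len(L[1L])) {
      ks <- j:L[1L]
      acc <- acc + sum(aff$evaluate(g, p, rep(j, length(ks)), ks))
    }
    return(acc)
  }
  acc <- 0
  kmin <- tot - L[m] + 1L
  for (j in seq_len(L[1L])) {
    ks <- kmin:tot
    acc <- acc + sum(aff$evaluate(g, p, rep(j, length(ks)), ks))
  }
  acc
}

# can p be extended left to S and right to T?
path_has_embedding <- function(g, p) {
  acc <- vertices_on_st_paths(g)
  all(p %in% acc)
}

# minimal fragment length that maps exactly to p (touch first & last exon)
path_min_frag_len <- function(g, p) {
  m <- length(p)
  if (m == 1L) return(1L)
  if (m == 2L) return(2L)
  sum(g$exon_len[p[2:(m - 1L)]]) + 2L
}

#' Extend a path to an embedding S-T path
#'
#' Returns one (lexicographically smallest) `S`-`T` path containing `p` as a
#' contiguous subpath, used to realize fragment windows on a concrete
#' transcript.
#'
#' @param g A `splice_graph`.
#' @param p Integer exon-vertex path.
#' @return Integer `S`-`T` vertex path.
#' @export
embed_path <- function(g, p) {
  pre <- shortest_chain(g, g$S, p[1L])
  suf <- shortest_chain(g, p[length(p)], g$T)
  if (is.null(pre) || is.null(suf))
    stop("path cannot be extended to an S-T path")
  c(pre, p[-1L], suf[-1L])[!duplicated(c(pre, p[-1L], suf[-1L]))]
}

# BFS shortest chain u -> v (inclusive); NULL if none
shortest_chain <- function(g, u, v) {
  if (u == v) return(u)
  prev <- rep(NA_integer_, g$n)
  frontier <- u
  seen <- logical(g$n); seen[u] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (w in frontier) {
      for (y in g$out[[w]]) {
        if (!seen[y]) {
          seen[y] <- TRUE; prev[y] <- w
          if (y == v) {
            path <- v
            while (path[1L] != u) path <- c(prev[path[1L]], path)
            return(path)
          }
          nxt <- c(nxt, y)
        }
      }
    }
    frontier <- nxt
  }
  NULL
}

#' Write / read a fragment-length distribution as TSV
#'
#' Two-column TSV `length`, `probability`.
#'
#' @param D A [frag_len_dist()].
#' @param path File path.
#' @return `read_fld_tsv` returns a [frag_len_dist()].
#' @export
write_fld_tsv <- function(D, path) {
  keep <- which(D$pmf > 0)
  utils::write.table(
    data.frame(length = keep, probability = D$pmf[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fld_tsv
#' @export
read_fld_tsv <- function(path) {
  df <- utils::read.delim(path)
  pmf <- numeric(max(df$length))
  pmf[df$length] <- df$probability
  frag_len_dist(pmf / sum(pmf))
}
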