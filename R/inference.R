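#' Prepare a gene for flow inference
#'
#' Bundles a splice graph and its phasing set with the (compact) prefix
#' graph and the quantities the solver needs: per-path effective lengths,
#' edge-level recognition sets, and the edge weights
#' `omega_e = sum of eff_len over paths recognized at e`.  Because every
#' fragment window of a transcript is recognized exactly once along its
#' lifted path, a transcript's effective length is the sum of `omega` over
#' its lifted edges -- effective length is edge-additive on prefix graphs,
#' which is what makes the normalization constraint linear in the flow.
#'
#' @param g A `splice_graph`.
#' @param P A `phasing_set` on `g` (effective lengths populated).
#' @param type `"compact"` (default) or `"prefix"`.
#' @return Object of class `gene_model`: `graph`, `P`, `pg`, `lhat` (named
#'   by path key), `ASe` (per-path edge recognition sets), `edge_paths`
#'   (per-edge path indices), `omega`.
#' @export
prepare_gene <- function(g, P, type = c("compact", "prefix")) {
  type <- match.arg(type)
  pg <- if (type == "compact") build_compact_prefix_graph(g, P)
        else build_prefix_graph(build_automaton(g, P))
  ASe <- if (type == "compact") {
    pg$AS
  } else {
    # vertex recognition -> incoming-edge recognition (AS never holds [S])
    lapply(pg$AS, function(vs) sort(unlist(pg$in_e[vs])))
  }
  ne <- n_pg_edges(pg)
  edge_paths <- rep(list(integer(0)), ne)
  for (j in seq_along(ASe)) {
    for (e in ASe[[j]]) edge_paths[[e]] <- c(edge_paths[[e]], j)
  }
  lhat <- P$eff_len
  names(lhat) <- P$keys
  omega <- vapply(edge_paths, function(js) sum(P$eff_len[js]), numeric(1))
  structure(list(graph = g, P = P, pg = pg, lhat = lhat, ASe = ASe,
                 edge_paths = edge_paths, omega = omega),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model '%s': %s with %d edges, |P| = %d\n",
              x$graph$gene_id, class(x$pg)[1L], n_pg_edges(x$pg),
              length(x$P$paths)))
  invisible(x)
}

#' Reparameterized log-likelihood
#'
#' `sum_p counts_p log c_p - (sum counts) log(sum_p c_p lhat_p)`: the path
#' log-likelihood of uniquely mapped fragments.  (With multimapping the
#' fragment term becomes `log sum_{p in M(f)} c_p A(f|p)`; that form is what
#' [run_em()] traces.)
#'
#' @param counts Named nonnegative weights per path key.
#' @param c Named path abundances (must cover `names(counts)` and
#'   `names(lhat)`).
#' @param lhat Named path effective lengths defining the normalization.
#' @return Log-likelihood value; `-Inf` (with a warning naming the path) if
#'   a counted path has zero abundance.
#' @export
loglik <- function(counts, c, lhat) {
  stopifnot(all(c >= 0))
  cl <- c[names(lhat)]
  if (any(is.na(cl)))
    stop("abundance vector does not cover the normalization paths; ",
         "sum(c * lhat) must be positive")
  norm <- sum(cl * lhat)
  if (norm <= 0) stop("normalization sum(c * lhat) must be positive")
  counts <- counts[counts > 0]
  cc <- c[names(counts)]
  if (any(is.na(cc))) stop("counted path missing from abundance vector")
  if (any(cc == 0)) {
    warning("counted path has zero abundance: ",
            names(counts)[which(cc == 0)[1L]])
    return(-Inf)
  }
  sum(counts * log(cc)) - sum(counts) * log(norm)
}

#' Solver control settings
#'
#' @param gap_tol Relative duality-gap tolerance certifying the M-step
#'   optimum (Frank-Wolfe gap against `max(1, |objective|)`).
#' @param inner_tol,inner_max Convergence of the restricted-master EM
#'   (with extrapolation acceleration).
#' @param outer_max Maximum number of generated columns.
#' @param dink_tol Dinkelbach fixed-point tolerance in the max-ratio path
#'   pricing.
#' @param quiet Suppress the stall warning (used for intermediate EM
#'   iterations whose M-steps need not be certified).
#' @return List of settings.
#' @export
sg_control <- function(gap_tol = 1e-8, inner_tol = 1e-13, inner_max = 20000L,
                       outer_max = 1000L, dink_tol = 1e-13, quiet = FALSE) {
  list(gap_tol = gap_tol, inner_tol = inner_tol, inner_max = inner_max,
       outer_max = outer_max, dink_tol = dink_tol, quiet = quiet)
}

#' Single-gene convex flow optimization (M-step)
#'
#' Maximizes `sum_p counts_p log c_p` over prefix-graph flows subject to
#' flow balance, nonnegativity and the normalization
#' `sum_p c_p lhat_p = mass`, where `c_p` is the recognition-set flow.
#' The problem is concave with linear constraints.
#'
#' The solver is fully-corrective column generation: a restricted master
#' problem over the currently active source-sink columns is solved by EM,
#' and the pricing step searches the prefix graph for the maximum-ratio
#' `[S]`-`[T]` path (recognition-gradient over effective-length mass) with
#' Dinkelbach iterations on a longest-path DP.  The Frank-Wolfe duality gap
#' `mass * r_max - sum(counts)` certifies the returned objective; the
#' solver stops when it falls below `gap_tol` relative to the objective.
#'
#' @param gene A [prepare_gene()] model.
#' @param counts Named nonnegative path weights (names are path keys of the
#'   gene's phasing set).
#' @param mass Right-hand side of the normalization (1 for a single gene,
#'   `s_g / |F|` inside the gene-level M-step).
#' @param control A [sg_control()] list.
#' @param warm Optional warm-start state (the `warm` element of a previous
#'   solution's attribute), reused by [run_em()] across EM iterations.
#' @return A [pg_flow()] with attribute `solution`: list with `c` (named
#'   abundances for the whole phasing set), `objective`, `gap`, `columns`
#'   (transcripts and weights of the support found), `warm`.
#' @export
solve_single_gene <- function(gene, counts, mass = 1,
                              control = sg_control(), warm = NULL) {
  stopifnot(mass > 0)
  pg <- gene$pg
  ne <- n_pg_edges(pg)
  keys <- gene$P$keys
  counts <- counts[counts > 0]
  # paths with negligible expected counts stay in the normalization but are
  # treated as uncounted: their objective contribution is below float noise
  # while their gradient (w/c with c free to approach 0) is unbounded and
  # would poison the pricing certificate
  counts <- counts[counts > 1e-12 * sum(counts)]
  q <- match(names(counts), keys)
  if (any(is.na(q)))
    stop("counted path not in the phasing set: ",
         names(counts)[which(is.na(q))[1L]])
  if (any(lengths(gene$ASe[q]) == 0L))
    stop("counted path has an empty recognition set (structural error)")
  if (any(gene$lhat[q] <= 0))
    stop("counted path has zero effective length; the model cannot explain it")
  w <- as.numeric(counts)
  W <- sum(w)
  if (W == 0) {
    # no data: any feasible flow maximizes; return the max-mass path
    bp <- longest_pg_path(pg, gene$omega)
    if (bp$value <= 0) stop("no S-T path with positive effective length")
    f <- numeric(ne); f[bp$edges] <- mass / bp$value
    fl <- pg_flow(pg, f)
    attr(fl, "solution") <- list(
      c = stats::setNames(vapply(gene$ASe, function(es) sum(f[es]),
                                 numeric(1)), keys),
      objective = 0, gap = 0,
      columns = list(transcripts = list(project_path(pg, bp$edges)),
                     weights = mass / bp$value))
    return(fl)
  }

  # initial columns: warm-start support plus one embedding per counted
  # path not yet covered
  cols <- list(); colkeys <- character(0)
  add_col <- function(eidx) {
    k <- path_key(eidx)
    if (k %in% colkeys) return(FALSE)
    cols[[length(cols) + 1L]] <<- eidx
    colkeys <<- c(colkeys, k)
    TRUE
  }
  x <- NULL
  if (!is.null(warm) && length(warm$cols)) {
    cols <- warm$cols
    colkeys <- warm$colkeys
    x <- warm$x
  }
  nq <- length(q)
  qpos <- integer(length(keys)); qpos[q] <- seq_len(nq)
  col_members <- function(eidx) {
    js <- qpos[unique(unlist(gene$edge_paths[eidx]))]
    sort(js[js > 0L])
  }
  covered <- logical(nq)
  for (eidx in cols) covered[col_members(eidx)] <- TRUE
  for (j in which(!covered))
    add_col(lift_path(pg, embed_path(gene$graph, gene$P$paths[[q[j]]])))
  for (outer in seq_len(control$outer_max)) {
    k <- length(cols)
    Mc <- matrix(0, nq, k)
    for (j in seq_len(k)) Mc[col_members(cols[[j]]), j] <- 1
    L <- vapply(cols, function(eidx) sum(gene$omega[eidx]), numeric(1))
    if (any(L <= 0)) stop("column with zero effective length (degenerate)")
    # restricted master: EM over column weights (warm-started)
    xk <- if (is.null(x) || !length(x)) {
      mass / (k * L)
    } else if (length(x) < k) {
      nnew <- k - length(x)
      xs <- x * mass / sum(x * L[seq_along(x)])  # rescale to current mass
      c(xs * 0.99, 0.01 * mass / (nnew * L[(length(x) + 1L):k]))
    } else {
      x * mass / sum(x * L)
    }
    em_update <- function(xv) {
      r <- w / as.vector(Mc %*% xv)
      mass * (xv * as.vector(crossprod(Mc, r))) / (W * L)
    }
    obj_of <- function(xv) sum(w * log(as.vector(Mc %*% xv)))
    # EM fixed-point iteration with SQUAREM-style extrapolation to tame
    # the sublinear EM tail on near-collinear column sets
    obj_prev <- -Inf
    for (it in seq_len(control$inner_max)) {
      x1 <- em_update(xk)
      x2 <- em_update(x1)
      r <- x1 - xk
      v <- x2 - x1 - r
      nv <- sqrt(sum(v * v))
      if (nv > 0) {
        alpha <- min(-1, -sqrt(sum(r * r)) / nv)
        xe <- xk - 2 * alpha * r + alpha^2 * v
        xe <- pmax(xe, 1e-300)
        xe <- xe * mass / sum(L * xe)
        xk2 <- if (obj_of(xe) >= obj_of(x2)) xe else x2
      } else {
        xk2 <- x2
      }
      obj <- obj_of(xk2)
      xk <- xk2
      if (is.finite(obj_prev) &&
          obj - obj_prev <= control$inner_tol * max(1, abs(obj))) break
      obj_prev <- obj
    }
    x <- xk
    # pricing: maximum-ratio path (Dinkelbach on longest-path DP)
    f <- numeric(ne)
    for (j in seq_len(k)) f[cols[[j]]] <- f[cols[[j]]] + x[j]
    cq <- as.vector(Mc %*% x)
    rfull <- numeric(length(keys)); rfull[q] <- w / cq
    gamma <- vapply(gene$edge_paths, function(js) sum(rfull[js]), numeric(1))
    lambda <- W / mass
    best <- NULL
    for (dk in seq_len(100L)) {
      bp <- longest_pg_path(pg, gamma - lambda * gene$omega)
      if (bp$value <= control$dink_tol * max(W / mass, 1)) break
      gs <- sum(gamma[bp$edges]); os <- sum(gene$omega[bp$edges])
      if (os <= 0) stop("improving path with zero effective length (degenerate)")
      lambda <- gs / os
      best <- bp
    }
    gap <- mass * lambda - W
    if (gap <= control$gap_tol * max(1, abs(obj_prev))) break
    if (is.null(best) || !add_col(best$edges)) {
      # master not tight enough to expose the gap; tighten and retry
      control$inner_tol <- control$inner_tol / 100
      if (control$inner_tol < 1e-17) {
        if (!isTRUE(control$quiet))
          warning(sprintf("column generation stalled with relative gap %.3g",
                          gap / max(1, abs(obj_prev))))
        break
      }
    }
  }
  if (length(cols) > length(x)) cols <- cols[seq_along(x)]
  f <- numeric(ne)
  for (j in seq_along(cols)) f[cols[[j]]] <- f[cols[[j]]] + x[j]
  sc <- mass / sum(gene$omega * f)
  f <- f * sc; x <- x * sc
  fl <- pg_flow(pg, f)
  call <- vapply(gene$ASe, function(es) sum(f[es]), numeric(1))
  names(call) <- keys
  keep <- x * vapply(cols, function(eidx) sum(gene$omega[eidx]),
                     numeric(1)) > 1e-12 * mass
  attr(fl, "solution") <- list(
    c = call,
    objective = sum(w * log(call[q])),
    gap = gap,
    columns = list(
      transcripts = lapply(cols, function(e) project_path(pg, e)),
      weights = x),
    warm = list(cols = cols[keep], colkeys = colkeys[keep], x = x[keep]))
  fl
}

# longest [S]-[T] path under additive edge scores; returns edges and value
longest_pg_path <- function(pg, score) {
  nv <- n_pg_vertices(pg)
  best <- rep(-Inf, nv); best[pg$source] <- 0
  prev <- rep(NA_integer_, nv)
  for (v in pg$topo) {
    if (best[v] == -Inf) next
    for (e in pg$out_e[[v]]) {
      u <- pg$edges[e, "to"]
      cand <- best[v] + score[e]
      if (cand > best[u]) { best[u] <- cand; prev[u] <- e }
    }
  }
  e <- integer(0); v <- pg$sink
  while (v != pg$source) {
    e <- c(prev[v], e)
    v <- pg$edges[prev[v], "from"]
  }
  list(edges = e, value = best[pg$sink])
}

#' E-step: fragment-to-path responsibilities
#'
#' `z_{f,p} = c_p A(f|p) / sum_{p' in M(f)} c_{p'} A(f|p')`, normalized per
#' fragment.
#'
#' @param c Named abundance vector.  Names are path keys, or
#'   `"gene|path-key"` for mappings carrying a `gene` field.
#' @param fragments List of [fragment_record()]s.
#' @return List (one element per fragment) of numeric responsibility
#'   vectors named by mapping key.
#' @export
e_step <- function(c, fragments) {
  lapply(fragments, function(fr) {
    ks <- vapply(fr$mappings, mapping_key, character(1))
    a <- vapply(fr$mappings, function(m) m$affinity, numeric(1))
    cp <- c[ks]
    if (any(is.na(cp)))
      stop("abundance missing for mapping ", ks[which(is.na(cp))[1L]])
    den <- sum(cp * a)
    if (den <= 0)
      stop("all-zero responsibility denominator for fragment ",
           fr$fragment_id)
    stats::setNames(cp * a / den, ks)
  })
}

mapping_key <- function(m) {
  k <- path_key(m$path)
  if (is.null(m$gene)) k else paste0(m$gene, "|", k)
}

#' Gene-level M-step
#'
#' Given per-gene expected path counts (`sum_f z_{f,p}`), solves each
#' gene's flow program with normalization mass `s_g / n_frags` and sets the
#' gene abundance `c_g = s_g / n_frags` (gene abundance is proportional to
#' its expected read count).  Genes are solved independently.
#'
#' @param genes Named list of [prepare_gene()] models.
#' @param counts Named list (same names) of named path-count vectors.
#' @param n_frags Total fragment count `|F|`.
#' @param control A [sg_control()].
#' @param warm Optional named list of per-gene warm-start states.
#' @return List with `flows` (per gene, `NULL` for zero-count genes), `c`
#'   (per-gene named absolute abundances), `c_gene`, `c_rel` (relative
#'   abundances `c_p / c_g`), `s_gene`, `warm`.
#' @export
m_step <- function(genes, counts, n_frags, control = sg_control(),
                   warm = NULL) {
  stopifnot(length(genes) >= 1L, !is.null(names(genes)))
  s_gene <- vapply(names(genes), function(gn) sum(counts[[gn]]), numeric(1))
  flows <- stats::setNames(vector("list", length(genes)), names(genes))
  cabs <- stats::setNames(vector("list", length(genes)), names(genes))
  crel <- stats::setNames(vector("list", length(genes)), names(genes))
  for (gn in names(genes)) {
    if (s_gene[[gn]] <= 0) {
      cabs[[gn]] <- stats::setNames(numeric(length(genes[[gn]]$P$keys)),
                                    genes[[gn]]$P$keys)
      crel[[gn]] <- cabs[[gn]]
      next
    }
    cnt <- counts[[gn]]
    fl <- solve_single_gene(genes[[gn]], cnt[cnt > 0],
                            mass = s_gene[[gn]] / n_frags,
                            control = control, warm = warm[[gn]])
    flows[[gn]] <- fl
    sol <- attr(fl, "solution")
    cabs[[gn]] <- sol$c
    crel[[gn]] <- sol$c / (s_gene[[gn]] / n_frags)
  }
  wout <- lapply(flows, function(fl)
    if (is.null(fl)) NULL else attr(fl, "solution")$warm)
  list(flows = flows, c = cabs, c_gene = s_gene / n_frags, c_rel = crel,
       s_gene = s_gene, warm = wout)
}

# Collapse fragments into equivalence classes of identical mapping sets.
# Uniquely mapped fragments have affinity-independent responsibilities, so
# their affinity is factored into an additive log-likelihood constant
# (attribute "const") and they collapse into one class per path.
build_em_classes <- function(genes, fragments) {
  gnames <- names(genes)
  sigs <- character(length(fragments))
  members <- vector("list", length(fragments))
  const <- 0
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    gm <- vapply(fr$mappings, function(m) {
      gn <- if (is.null(m$gene)) gnames[1L] else m$gene
      gi <- match(gn, gnames)
      if (is.na(gi)) stop("mapping refers to unknown gene ", gn)
      gi
    }, integer(1))
    pk <- vapply(fr$mappings, function(m) path_key(m$path), character(1))
    pi <- vapply(seq_along(pk), function(j) {
      jj <- match(pk[j], genes[[gm[j]]]$P$keys)
      if (is.na(jj))
        stop("fragment ", fr$fragment_id, " maps to path ", pk[j],
             " absent from the phasing set of gene ", gnames[gm[j]])
      jj
    }, integer(1))
    a <- vapply(fr$mappings, function(m) m$affinity, numeric(1))
    o <- order(gm, pi, a)
    gm <- gm[o]; pi <- pi[o]; a <- a[o]
    # merge duplicate (gene, path) mappings by summing affinity
    dkey <- paste(gm, pi, sep = ",")
    if (anyDuplicated(dkey)) {
      keep <- !duplicated(dkey)
      a <- as.numeric(tapply(a, factor(dkey, levels = dkey[keep]), sum))
      gm <- gm[keep]; pi <- pi[keep]
    }
    if (length(gm) == 1L) {
      if (a <= 0) stop("fragment ", fr$fragment_id, " has zero affinity")
      const <- const + log(a)
      a <- 1
      sigs[i] <- paste0("U:", gm, ":", pi)
    } else {
      sigs[i] <- paste(gm, pi, sprintf("%.17g", a), sep = ":",
                       collapse = ";")
    }
    members[[i]] <- list(gene = gm, pidx = pi, aff = a)
  }
  u <- !duplicated(sigs)
  cls <- members[u]
  n <- as.numeric(table(factor(sigs, levels = sigs[u])))
  for (i in seq_along(cls)) cls[[i]]$n <- n[i]
  attr(cls, "const") <- const
  cls
}

#' Run the full EM over genes and fragments
#'
#' Alternates the global E-step (fragment responsibilities over candidate
#' mappings) with the gene-level M-step (independent per-gene flow solves
#' with masses `s_g / |F|`) until the relative log-likelihood change falls
#' below `tol`.  Fragments with identical mapping sets are collapsed into
#' equivalence classes first.  The traced objective is
#' `sum_f log sum_{p in M(f)} c_p A(f|p)` under the global normalization
#' `sum_g c_g = 1`; it is non-decreasing by EM construction, and a decrease
#' beyond `1e-9` relative aborts with an internal error (it would indicate
#' an M-step solver failure).
#'
#' @param genes Named list of [prepare_gene()] models (a single
#'   `gene_model` is promoted).
#' @param fragments List of [fragment_record()]s; mappings may carry a
#'   `gene` field (defaulting to the first gene).
#' @param config List: `tol` (default `1e-9`), `max_iter` (default 1000),
#'   `control` ([sg_control()] passthrough).
#' @return Object of class `em_state`: `c` (per-gene named abundances),
#'   `c_gene`, `c_rel`, `s_gene`, `z` (per-class responsibilities),
#'   `classes`, `flows`, `loglik_trace`, `n_iter`, `converged`.
#' @export
run_em <- function(genes, fragments, config = list()) {
  if (inherits(genes, "gene_model")) genes <- list(gene = genes)
  if (is.null(names(genes)))
    names(genes) <- paste0("gene", seq_along(genes))
  tol <- config$tol %||% 1e-9
  max_iter <- config$max_iter %||% 1000L
  control <- config$control %||% sg_control()
  if (!length(fragments)) stop("need at least one fragment")
  cls <- build_em_classes(genes, fragments)
  const_ll <- attr(cls, "const")
  nF <- sum(vapply(cls, function(cl) cl$n, numeric(1)))
  gnames <- names(genes)
  ccur <- lapply(genes, function(ge)
    stats::setNames(rep(1, length(ge$P$keys)), ge$P$keys))
  trace <- numeric(0)
  ms <- NULL
  zlist <- NULL
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step on classes
    counts <- lapply(genes, function(ge)
      stats::setNames(numeric(length(ge$P$keys)), ge$P$keys))
    zlist <- vector("list", length(cls))
    for (ci in seq_along(cls)) {
      cl <- cls[[ci]]
      cp <- vapply(seq_along(cl$gene), function(j)
        ccur[[cl$gene[j]]][cl$pidx[j]], numeric(1))
      den <- sum(cp * cl$aff)
      if (den <= 0)
        stop("all-zero responsibility denominator in fragment class ", ci)
      z <- cp * cl$aff / den
      zlist[[ci]] <- z
      for (j in seq_along(z)) {
        gi <- cl$gene[j]
        counts[[gi]][cl$pidx[j]] <- counts[[gi]][cl$pidx[j]] + cl$n * z[j]
      }
    }
    # M-step (warm-started with the previous iteration's columns; stall
    # warnings are deferred to the final certificate check below)
    ctrl_i <- control
    ctrl_i$quiet <- TRUE
    ms <- m_step(genes, counts, nF, control = ctrl_i,
                 warm = if (is.null(ms)) NULL else ms$warm)
    ccur <- ms$c
    # objective at the new point
    ll <- const_ll
    for (cl in cls) {
      cp <- vapply(seq_along(cl$gene), function(j)
        ccur[[cl$gene[j]]][cl$pidx[j]], numeric(1))
      ll <- ll + cl$n * log(sum(cp * cl$aff))
    }
    if (length(trace)) {
      prev <- trace[length(trace)]
      if (ll < prev - 1e-9 * max(1, abs(prev)))
        stop(sprintf(
          "EM log-likelihood decreased (%.12g -> %.12g): solver failure",
          prev, ll))
      if (abs(ll - prev) <= tol * max(1, abs(prev))) {
        trace <- c(trace, ll)
        converged <- TRUE
        break
      }
    }
    trace <- c(trace, ll)
  }
  # certificate check on the final M-step solves
  for (gn in names(ms$flows)) {
    fl <- ms$flows[[gn]]
    if (is.null(fl)) next
    sol <- attr(fl, "solution")
    if (sol$gap > (control$gap_tol %||% 1e-8) * max(1, abs(sol$objective)))
      warning(sprintf(
        "final M-step for gene '%s' certified only to relative gap %.3g",
        gn, sol$gap / max(1, abs(sol$objective))))
  }
  structure(list(c = ccur, c_gene = ms$c_gene, c_rel = ms$c_rel,
                 s_gene = ms$s_gene, z = zlist, classes = cls,
                 flows = ms$flows, loglik_trace = trace,
                 n_iter = length(trace), converged = converged),
            class = "em_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.em_state <- function(x, ...) {
  cat(sprintf("em_state: %d genes, %d iterations, loglik %.6f%s\n",
              length(x$c), x$n_iter, x$loglik_trace[length(x$loglik_trace)],
              if (x$converged) " (converged)" else ""))
  invisible(x)
}
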