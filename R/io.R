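#' Read / write the JSON splice-graph dialect
#'
#' Fixture format:
#' `{"gene_id": ..., "vertices": [{"id", "kind", "len", "chrom", "start",
#' "end", "strand"}, ...], "edges": [[u, v], ...]}` with vertex ids in
#' topological order (`S` first, `T` last) and 0-based half-open
#' coordinates.
#'
#' @param g A `splice_graph`.
#' @param path File path.
#' @return `read_graph_json` returns a `splice_graph`.
#' @export
write_graph_json <- function(g, path) {
  verts <- lapply(seq_len(g$n), function(v) {
    out <- list(id = v, kind = g$kind[v])
    if (g$kind[v] == "exon") {
      out$len <- g$exon_len[v]
      if (!is.null(g$start) && !is.na(g$start[v])) {
        out$chrom <- g$chrom[v]; out$start <- g$start[v]
        out$end <- g$end[v]; out$strand <- g$strand[v]
      }
    }
    out
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(e)
    c(g$edges[e, "from"], g$edges[e, "to"]))
  jsonlite::write_json(list(gene_id = g$gene_id, vertices = verts,
                            edges = edges),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  js <- jsonlite::read_json(path)
  verts <- js$vertices
  ids <- vapply(verts, function(v) v$id, numeric(1))
  o <- order(ids)
  verts <- verts[o]
  kind <- vapply(verts, function(v) v$kind, character(1))
  if (kind[1L] != "S" || kind[length(kind)] != "T")
    stop("JSON graph must list S first and T last")
  ex <- which(kind == "exon")
  exon_len <- vapply(verts[ex], function(v) {
    if (!is.null(v$len)) as.integer(v$len)
    else as.integer(v$end - v$start)
  }, integer(1))
  getf <- function(f, default) {
    vapply(verts, function(v) {
      x <- v[[f]]
      if (is.null(x)) default else x
    }, default)
  }
  has_coord <- any(vapply(verts[ex], function(v) !is.null(v$start),
                          logical(1)))
  edges <- do.call(rbind, lapply(js$edges, function(e)
    c(as.integer(e[[1L]]), as.integer(e[[2L]]))))
  if (has_coord) {
    new_splice_graph(js$gene_id, exon_len, edges,
                     chrom = getf("chrom", NA_character_),
                     start = as.integer(getf("start", NA_real_)),
                     end = as.integer(getf("end", NA_real_)),
                     strand = getf("strand", NA_character_))
  } else {
    new_splice_graph(js$gene_id, exon_len, edges)
  }
}

#' Read exon / junction / transcript tables from a GTF
#'
#' Parses `exon` features (attributes `gene_id`, `transcript_id`) with
#' `rtracklayer` and groups them per gene.  GTF coordinates (1-based
#' inclusive) are converted to 0-based half-open; minus-strand genes are
#' reversed into transcription order, so exon 1 is always the 5' end of the
#' transcript.
#'
#' @param path GTF file.
#' @return Named list (per gene) of lists with `exons` (data frame
#'   `chrom`, `start`, `end`, `strand`), `junctions` (two-column exon-index
#'   matrix), `transcripts` (named list of exon-index chains).
#' @export
read_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gtf requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  gr <- gr[gr$type == "exon", , drop = FALSE]
  if (!nrow(gr)) stop("no exon features in GTF")
  df <- data.frame(chrom = as.character(gr$seqnames),
                   start = gr$start - 1L,  # to 0-based half-open
                   end = gr$end,
                   strand = as.character(gr$strand),
                   gene_id = gr$gene_id,
                   transcript_id = gr$transcript_id)
  lapply(split(df, df$gene_id), function(gd) {
    minus <- gd$strand[1L] == "-"
    ex <- unique(gd[, c("chrom", "start", "end", "strand")])
    ex <- ex[order(ex$start * ifelse(minus, -1L, 1L)), , drop = FALSE]
    rownames(ex) <- NULL
    exkey <- paste(ex$start, ex$end)
    transcripts <- lapply(split(gd, gd$transcript_id), function(td) {
      td <- td[order(td$start * ifelse(minus, -1L, 1L)), , drop = FALSE]
      match(paste(td$start, td$end), exkey)
    })
    jns <- unique(do.call(rbind, lapply(transcripts, function(ch) {
      if (length(ch) < 2L) return(NULL)
      cbind(ch[-length(ch)], ch[-1L])
    })))
    if (is.null(jns)) jns <- matrix(integer(0), ncol = 2L)
    list(exons = ex, junctions = jns, transcripts = transcripts)
  })
}

#' Build a splice graph from one gene of a GTF
#'
#' @param gtf_gene One element of [read_gtf()]'s result.
#' @param gene_id Gene name.
#' @param use_transcript_ends Place `S`/`T` edges at annotated transcript
#'   ends (default) rather than the permissive in/out-degree-0 closure.
#' @return A `splice_graph`.
#' @export
splice_graph_from_annotation <- function(gtf_gene, gene_id,
                                         use_transcript_ends = TRUE) {
  build_splice_graph(
    gtf_gene$exons, gtf_gene$junctions, gene_id,
    transcripts = if (use_transcript_ends) gtf_gene$transcripts else NULL)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a CLI run bit-for-bit: tool version,
#' command, full configuration and seed.  Deliberately contains no
#' timestamp so identical configs produce identical outputs.
#'
#' @param out_dir Output directory.
#' @param command Subcommand name.
#' @param config Configuration list.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(out_dir, command, config) {
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(tool = "spliceflow",
         version = as.character(utils::packageVersion("spliceflow")),
         command = command, config = config),
    p, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(p)
}

check_config <- function(config, allowed, required) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config fields: ", paste(missing, collapse = ", "))
  config
}

#' Quantification workflow
#'
#' Loads a JSON splice graph, a fragment TSV and a fragment-length
#' distribution TSV, builds (and optionally trims) the phasing set, runs
#' the flow EM and writes `flow.tsv`, `path_abundance.tsv`,
#' `loglik_trace.tsv`, `transcripts.tsv` (greedy decomposition) and
#' `manifest.json` into `out_dir`.
#'
#' @param config List with keys `graph`, `fragments`, `fld`, `out_dir` and
#'   optional `graph_type` (`"compact"`), `trim` (logical, default TRUE),
#'   `trim_min_eff_len`, `prefix_closed`, `tol`, `max_iter`, `seed`.
#' @return Invisibly, the [run_em()] state.
#' @export
cli_quantify <- function(config) {
  config <- check_config(config,
    allowed = c("graph", "fragments", "fld", "out_dir", "graph_type",
                "trim", "trim_min_eff_len", "prefix_closed", "tol",
                "max_iter", "seed"),
    required = c("graph", "fragments", "fld", "out_dir"))
  for (f in c("graph", "fragments", "fld")) {
    if (!file.exists(config[[f]]))
      stop(sprintf("input '%s' does not exist: %s", f, config[[f]]))
  }
  g <- read_graph_json(config$graph)
  D <- read_fld_tsv(config$fld)
  frags <- read_fragments_tsv(config$fragments)
  P <- build_phasing_set(g, D, frags,
                         prefix_closed = isTRUE(config$prefix_closed))
  if (config$trim %||% TRUE) {
    mel <- config$trim_min_eff_len
    P <- if (is.null(mel)) trim_phasing_set(P) else trim_phasing_set(P, mel)
  }
  gene <- prepare_gene(g, P, type = config$graph_type %||% "compact")
  st <- run_em(stats::setNames(list(gene), g$gene_id), frags,
               config = list(tol = config$tol %||% 1e-9,
                             max_iter = config$max_iter %||% 1000L))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  fl <- st$flows[[1L]]
  write_flow_tsv(fl, file.path(config$out_dir, "flow.tsv"))
  utils::write.table(
    data.frame(gene = g$gene_id, path = names(st$c[[1L]]),
               eff_len = gene$lhat, abundance = unname(st$c[[1L]])),
    file.path(config$out_dir, "path_abundance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(iteration = seq_along(st$loglik_trace),
               loglik = st$loglik_trace),
    file.path(config$out_dir, "loglik_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  dec <- decompose_flow(fl)
  utils::write.table(
    data.frame(gene = g$gene_id,
               transcript = vapply(dec$transcripts, path_key, character(1)),
               abundance = dec$abundances),
    file.path(config$out_dir, "transcripts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config$out_dir, "quantify", config)
  invisible(st)
}

#' PSI workflow
#'
#' Computes percent-spliced-in values for skipped-exon triples from a
#' quantified transcript table (`transcripts` TSV with columns
#' `transcript`, `abundance`, e.g. the decomposition written by
#' [cli_quantify()]).  Event triples come from an `events` TSV
#' (`e_first`, `e_mid`, `e_last`) or are auto-detected from the graph
#' topology.  Events whose flanking abundance is zero get `NaN`.
#'
#' @param config List with keys `graph`, `transcripts`, `out_dir`, optional
#'   `events`.
#' @return Invisibly, the PSI data frame (also written to `psi.tsv`).
#' @export
cli_psi <- function(config) {
  config <- check_config(config,
    allowed = c("graph", "transcripts", "events", "out_dir"),
    required = c("graph", "transcripts", "out_dir"))
  g <- read_graph_json(config$graph)
  tt <- utils::read.delim(config$transcripts,
                          colClasses = c(transcript = "character"))
  qts <- quantified_transcripts(
    g, lapply(strsplit(tt$transcript, "-", fixed = TRUE), as.integer),
    tt$abundance)
  ev <- if (!is.null(config$events)) utils::read.delim(config$events)
        else find_skipped_exon_triples(g)
  psi <- if (nrow(ev)) {
    vapply(seq_len(nrow(ev)), function(i)
      suppressWarnings(
        compute_psi(qts, ev$e_first[i], ev$e_mid[i], ev$e_last[i])),
      numeric(1))
  } else numeric(0)
  out <- data.frame(gene = rep(g$gene_id, nrow(ev)), ev, psi = psi)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(out, file.path(config$out_dir, "psi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config$out_dir, "psi", config)
  invisible(out)
}

#' Simulation workflow
#'
#' Generates a synthetic gene (graph, ground-truth transcripts, fragment
#' length distribution, fragments) and writes `graph.json`,
#' `fragments.tsv`, `truth.tsv`, `fld.tsv` and `manifest.json`.
#'
#' @param config List of [sim_config()] fields plus `out_dir`.
#' @return Invisibly, the [simulate_dataset()] bundle.
#' @export
cli_simulate <- function(config) {
  config <- check_config(config,
    allowed = c(names(formals(sim_config)), "out_dir"),
    required = "out_dir")
  cfgargs <- config[setdiff(names(config), "out_dir")]
  if (!is.null(cfgargs$exon_length_range))
    cfgargs$exon_length_range <- unlist(cfgargs$exon_length_range)
  cfg <- do.call(sim_config, cfgargs)
  ds <- simulate_dataset(cfg)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_graph_json(ds$graph, file.path(config$out_dir, "graph.json"))
  write_fragments_tsv(ds$fragments,
                      file.path(config$out_dir, "fragments.tsv"))
  write_fld_tsv(ds$fld, file.path(config$out_dir, "fld.tsv"))
  utils::write.table(
    data.frame(
      transcript = vapply(ds$truth$transcripts, path_key, character(1)),
      length = ds$truth$lengths,
      abundance = ds$truth$abundances),
    file.path(config$out_dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_manifest(config$out_dir, "simulate", config)
  invisible(ds)
}

#' Graph-construction workflow
#'
#' Converts a GTF annotation into per-gene JSON splice graphs.
#'
#' @param config List with keys `gtf`, `out_dir`, optional
#'   `use_transcript_ends` (default TRUE).
#' @return Invisibly, the named list of graphs.
#' @export
cli_build_graph <- function(config) {
  config <- check_config(config,
    allowed = c("gtf", "out_dir", "use_transcript_ends"),
    required = c("gtf", "out_dir"))
  genes <- read_gtf(config$gtf)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- lapply(names(genes), function(gn) {
    g <- splice_graph_from_annotation(
      genes[[gn]], gn,
      use_transcript_ends = config$use_transcript_ends %||% TRUE)
    write_graph_json(g, file.path(config$out_dir,
                                  paste0(gn, ".graph.json")))
    g
  })
  names(gs) <- names(genes)
  write_manifest(config$out_dir, "build-graph", config)
  invisible(gs)
}
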