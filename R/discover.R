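#' Discover motifs in a set of accessible-chromatin sequences
#'
#' Runs the full pipeline: Markov background estimation, Poisson k-mer
#' scoring and tiering, Hamming-graph construction over the significant
#' tier, greedy independent-set seeding and cluster growth, de Bruijn graph
#' construction over all observed k-mers, cluster-digraph reconstruction,
#' greedy path extension, and occurrence-overlap motif refinement.
#'
#' @param seqs A `DNAStringSet` (e.g. from [read_fasta()]).
#' @param k Word length (default 6).
#' @param markov_order Background Markov order, 0-2 (default 2).
#' @param top_k1 Size cap of the highly significant seed tier (default 100).
#' @param max_len Maximum motif length in nt (default 18).
#' @param bg_pseudocount Pseudocount per background-matrix cell
#'   (default 0.5).
#' @param pwm_pseudocount Pseudocount per PWM cell (default 0.25).
#' @return An object of class `cemig_result`: list with `motifs` (list of
#'   `motif_result`, each named `motif_<path>_<source>`), `kmer_table`,
#'   `background`, `clusters`, `cluster_digraph`, `paths`, and the
#'   parameters used.
#' @export
discover_motifs <- function(seqs, k = 6, markov_order = 2, top_k1 = 100,
                            max_len = 18, bg_pseudocount = 0.5,
                            pwm_pseudocount = 0.25) {
  stopifnot(k >= 2, max_len > k)
  model <- estimate_background(seqs, order = markov_order,
                               pseudocount = bg_pseudocount)
  tab <- build_kmer_table(seqs, model, k = k, top_k1 = top_k1)
  k2 <- tier_kmers(tab, "K2")
  g <- build_hamming_graph(k2)
  pvalues <- stats::setNames(tab$pvalue, tab$kmer)
  k1 <- tier_kmers(tab, "K1")
  is_set <- greedy_independent_set(g, k1)
  clusters <- cluster_all(g, is_set, pvalues)
  dbg <- build_debruijn_graph(seqs, tab$kmer, k)
  gc_graph <- build_cluster_digraph(dbg, clusters)
  paths <- extend_paths(gc_graph, k, max_len = max_len)

  strands <- sequence_strands(seqs)
  motifs <- list()
  for (pi in seq_along(paths)) {
    p <- paths[[pi]]
    o1 <- collect_occurrences(p$upstream, gc_graph, strands, k)
    o2 <- collect_occurrences(p$downstream, gc_graph, strands, k)
    full <- if (length(p$vertices) > 1L)
      collect_occurrences(p$vertices, gc_graph, strands, k) else o1
    refined <- refine_motifs(p, o1, o2, full, pseudocount = pwm_pseudocount)
    for (mot in refined) {
      motifs[[sprintf("motif_%03d_%s", pi, mot$source)]] <- mot
    }
  }
  structure(
    list(motifs = motifs, kmer_table = tab, background = model,
         clusters = clusters, cluster_digraph = gc_graph, paths = paths,
         params = list(k = k, markov_order = markov_order, top_k1 = top_k1,
                       max_len = max_len, bg_pseudocount = bg_pseudocount,
                       pwm_pseudocount = pwm_pseudocount)),
    class = "cemig_result"
  )
}

#' @export
print.cemig_result <- function(x, ...) {
  cat("cemig result: ", length(x$motifs), " motifs from ",
      length(x$paths), " paths (k = ", x$params$k, ")\n", sep = "")
  for (nm in names(x$motifs)) {
    m <- x$motifs[[nm]]
    cat("  ", nm, ": ", m$consensus, " (", m$nsites, " sites)\n", sep = "")
  }
  invisible(x)
}

#' Write motifs in MEME minimal motif format
#'
#' @param motifs Named list of `motif_result` objects (or a `cemig_result`).
#' @param path Output path.
#' @param background Optional `markov_background`; its `M1` becomes the
#'   background letter frequency line (uniform if omitted).
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  if (inherits(motifs, "cemig_result")) {
    if (is.null(background)) background <- motifs$background
    motifs <- motifs$motifs
  }
  bg <- if (is.null(background)) rep(0.25, 4) else background$M1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", BASES, bg), collapse = " "),
    ""
  ), con)
  nms <- if (is.null(names(motifs))) sprintf("motif_%03d", seq_along(motifs))
         else names(motifs)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF %s %s", nms[i], m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(m$pwm), m$nsites), con)
    for (j in seq_len(ncol(m$pwm))) {
      writeLines(paste(sprintf("%.6f", m$pwm[, j]), collapse = "  "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# total information content of a PWM in bits (sum over columns of
# 2 + sum_b p log2 p)
pwm_information_content <- function(pwm) {
  sum(apply(pwm, 2, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0))))
}

#' Write motif sites as BED6
#'
#' One line per occurrence: `seqname, start, end, motif id, score, strand`,
#' the score being the motif's per-column mean information content scaled
#' to 0-1000.
#'
#' @param motifs Named list of `motif_result` objects (or a `cemig_result`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(motifs, path) {
  if (inherits(motifs, "cemig_result")) motifs <- motifs$motifs
  nms <- if (is.null(names(motifs))) sprintf("motif_%03d", seq_along(motifs))
         else names(motifs)
  rows <- list()
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    occ <- m$occurrences
    if (nrow(occ) == 0L) next
    score <- round(1000 * pwm_information_content(m$pwm) / (2 * ncol(m$pwm)))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = occ$seqname, start = occ$start, end = occ$end,
      name = nms[i], score = as.integer(score), strand = occ$strand,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(rows) > 0) do.call(rbind, rows)
        else data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = integer(), strand = character())
  df <- df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
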