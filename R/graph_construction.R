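#' Hamming distance between equal-length words
#'
#' @param u,v Character strings of equal length.
#' @return Number of mismatching positions.
#' @export
hamming_distance <- function(u, v) {
  if (nchar(u) != nchar(v)) stop("hamming_distance requires equal lengths")
  sum(strsplit(u, "", fixed = TRUE)[[1]] != strsplit(v, "", fixed = TRUE)[[1]])
}

# all 3k single-substitution neighbours of each word, as a long data.frame
substitution_neighbors <- function(kmers) {
  k <- nchar(kmers[1])
  res <- vector("list", k * 3L)
  idx <- 0L
  for (pos in seq_len(k)) {
    cur <- substr(kmers, pos, pos)
    for (b in BASES) {
      idx <- idx + 1L
      nb <- kmers
      substr(nb, pos, pos) <- b
      keep <- cur != b
      res[[idx]] <- data.frame(u = kmers[keep], v = nb[keep],
                               stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Build the Hamming-distance graph over the significant k-mer set
#'
#' Vertices are the supplied k-mers; an undirected edge joins every pair at
#' Hamming distance exactly 1 (distance < 2 with distinct vertices), with
#' the distance stored as the edge weight. Edges are found by enumerating
#' each k-mer's `3k` single-substitution neighbours and intersecting with
#' the vertex set, avoiding the all-pairs scan.
#'
#' @param k2 Character vector of k-mers (typically `tier_kmers(tab, "K2")`).
#' @return An object of class `hamming_graph` with elements `vertices`,
#'   `edges` (`data.frame` with `u < v` and `w = 1`), and `adj` (named list
#'   of neighbour vectors).
#' @export
build_hamming_graph <- function(k2) {
  k2 <- unique(k2)
  if (length(k2) == 0L) {
    warning("empty k-mer set; Hamming graph has no vertices")
    return(structure(list(vertices = character(), edges = empty_edges(),
                          adj = list(), wmap = numeric()),
                     class = "hamming_graph"))
  }
  if (length(unique(nchar(k2))) != 1L) stop("all k-mers must have equal length")
  nb <- substitution_neighbors(k2)
  nb <- nb[nb$v %in% k2 & nb$u < nb$v, , drop = FALSE]  # each pair once
  if (nrow(nb) > 0) {
    edges <- unique(data.frame(u = nb$u, v = nb$v, w = 1,
                               stringsAsFactors = FALSE))
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- empty_edges()
  }
  adj <- make_adjacency(k2, edges)
  wmap <- edge_weight_map(edges, directed = FALSE)
  structure(list(vertices = sort(k2), edges = edges, adj = adj, wmap = wmap),
            class = "hamming_graph")
}

empty_edges <- function() {
  data.frame(u = character(), v = character(), w = numeric(),
             stringsAsFactors = FALSE)
}

# named weight lookup keyed "u>v" (and "v>u" for undirected graphs);
# zero-row inputs need the guard because paste0() recycles empty vectors
edge_weight_map <- function(edges, directed = TRUE) {
  if (nrow(edges) == 0L) return(stats::setNames(numeric(), character()))
  if (directed) {
    stats::setNames(edges$w, paste0(edges$u, ">", edges$v))
  } else {
    stats::setNames(c(edges$w, edges$w),
                    c(paste0(edges$u, ">", edges$v),
                      paste0(edges$v, ">", edges$u)))
  }
}

make_adjacency <- function(vertices, edges) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (v in vertices) adj[[v]] <- character()
  if (nrow(edges) > 0) {
    fw <- split(edges$v, edges$u)
    bw <- split(edges$u, edges$v)
    for (u in names(fw)) adj[[u]] <- c(adj[[u]], fw[[u]])
    for (v in names(bw)) adj[[v]] <- c(adj[[v]], bw[[v]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

#' @export
print.hamming_graph <- function(x, ...) {
  cat("Hamming-distance graph: ", length(x$vertices), " vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build the de Bruijn graph with (k+1)-mer frequency edge weights
#'
#' Vertices are the supplied k-mers (typically the union of the K2 and K3
#' tiers, i.e. all observed k-mers). A directed edge `u -> v` exists when
#' the last `k - 1` characters of `u` equal the first `k - 1` of `v` and
#' the concatenated `(k+1)`-mer occurs in the input; its weight is that
#' `(k+1)`-mer's occurrence count over the forward sequences and their
#' reverse complements. Zero-weight edges are omitted; homopolymer
#' self-loops are retained.
#'
#' @param seqs A `DNAStringSet`.
#' @param vertices Character vector of k-mers forming the vertex set.
#' @param k Word length.
#' @return An object of class `debruijn_graph` with elements `vertices`,
#'   `edges` (`data.frame` columns `u`, `v`, `w`), and a named weight
#'   lookup `wmap` keyed `"u>v"`.
#' @export
build_debruijn_graph <- function(seqs, vertices, k) {
  stopifnot(k >= 2)
  vertices <- unique(vertices)
  cnt <- count_words(seqs, as.integer(k) + 1L) +
    count_words(Biostrings::reverseComplement(seqs), as.integer(k) + 1L)
  cnt <- cnt[cnt > 0]
  words <- names(cnt)
  u <- substr(words, 1L, k)
  v <- substr(words, 2L, k + 1L)
  keep <- u %in% vertices & v %in% vertices
  edges <- data.frame(u = u[keep], v = v[keep], w = as.numeric(cnt[keep]),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  wmap <- edge_weight_map(edges, directed = TRUE)
  structure(list(vertices = sort(vertices), edges = edges, wmap = wmap,
                 k = as.integer(k)),
            class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat("de Bruijn graph: ", length(x$vertices), " vertices, ",
      nrow(x$edges), " weighted edges\n", sep = "")
  invisible(x)
}

#' Dump graph edges as TSV
#'
#' @param graph A `hamming_graph` or `debruijn_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph_edges <- function(graph, path) {
  type <- if (inherits(graph, "hamming_graph")) "hamming" else "debruijn"
  df <- cbind(graph$edges, graph = type)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
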