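#' Collapse k-mer clusters into a cluster-vertex digraph
#'
#' Each cluster becomes one vertex. K3 ("insignificant") k-mers and K2
#' k-mers belonging to no cluster are excised; a k-mer claimed by several
#' clusters is assigned to the one with the higher `f` (ties by seed
#' lexicographic order) before edges are aggregated. The weight of edge
#' `c1 -> c2` is the sum of de Bruijn edge weights from members of `c1` to
#' members of `c2`; zero-weight edges are omitted. Within-cluster
#' (self-loop) weights are recorded but never traversed during path
#' extension.
#'
#' @param dbg A `debruijn_graph`.
#' @param clusters List of `kmer_cluster` objects, sorted by decreasing `f`
#'   (as returned by [cluster_all()]).
#' @return An object of class `cluster_digraph` with elements `vertices`
#'   (`data.frame`: `id`, `seed`, `f`, `n_members`), `members` (named list
#'   id -> member k-mers after exclusive assignment), `edges` (`data.frame`:
#'   `from`, `to`, `w`, including self-loops), `k`.
#' @export
build_cluster_digraph <- function(dbg, clusters) {
  if (length(clusters) == 0L) stop("no clusters supplied")
  scores <- vapply(clusters, `[[`, numeric(1), "score")
  seeds <- vapply(clusters, `[[`, character(1), "seed")
  ord <- order(-scores, seeds)     # defensive: normally already sorted
  clusters <- clusters[ord]
  scores <- scores[ord]
  seeds <- seeds[ord]
  ids <- sprintf("C%03d", seq_along(clusters))

  # exclusive assignment: first cluster in (f desc, seed lex) order wins
  assign_map <- new.env(parent = emptyenv())
  members <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(clusters)) {
    mine <- character()
    for (km in clusters[[i]]$members) {
      if (!exists(km, envir = assign_map, inherits = FALSE)) {
        assign(km, ids[i], envir = assign_map)
        mine <- c(mine, km)
      }
    }
    members[[ids[i]]] <- sort(mine)
  }

  e <- dbg$edges
  from_id <- vapply(e$u, function(x)
    if (exists(x, envir = assign_map, inherits = FALSE))
      get(x, envir = assign_map) else NA_character_, character(1))
  to_id <- vapply(e$v, function(x)
    if (exists(x, envir = assign_map, inherits = FALSE))
      get(x, envir = assign_map) else NA_character_, character(1))
  keep <- !is.na(from_id) & !is.na(to_id)
  if (any(keep)) {
    agg <- stats::aggregate(w ~ from + to,
                            data = data.frame(from = from_id[keep],
                                              to = to_id[keep],
                                              w = e$w[keep],
                                              stringsAsFactors = FALSE),
                            FUN = sum)
    agg <- agg[agg$w > 0, , drop = FALSE]
    agg <- agg[order(agg$from, agg$to), , drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(from = character(), to = character(), w = numeric(),
                      stringsAsFactors = FALSE)
  }

  vertices <- data.frame(
    id = ids, seed = seeds, f = scores,
    n_members = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE
  )
  structure(list(vertices = vertices, members = members, edges = agg,
                 k = dbg$k),
            class = "cluster_digraph")
}

#' @export
print.cluster_digraph <- function(x, ...) {
  cat("cluster digraph: ", nrow(x$vertices), " cluster vertices, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Assemble motif paths by greedy extension on the cluster digraph
#'
#' Repeatedly starts from the uncovered cluster vertex with the highest `f`
#' and extends the path one vertex at a time: among the heaviest usable
#' outgoing edge from the downstream end and the heaviest usable incoming
#' edge into the upstream end, the heavier edge is taken (downstream
#' preferred on a tie). An edge is unusable when its weight is 0, its
#' candidate vertex is already on the path, its direction has already
#' received 3 vertices, or the total number of path edges would exceed
#' `18 - k` (so spelled motifs never exceed 18 nt). When both directions
#' are blocked the path is emitted and all its vertices become covered;
#' extension repeats until every cluster vertex is covered.
#'
#' @param gc A `cluster_digraph`.
#' @param k Word length used to build the graphs.
#' @param max_len Maximum motif length in nt (default 18).
#' @return List of `motif_path` objects: `vertices` (ordered ids),
#'   `start` (id), `upstream` / `downstream` (sub-paths including the
#'   start), in emission order.
#' @export
extend_paths <- function(gc, k, max_len = 18) {
  stopifnot(k >= 2)
  max_edges <- max_len - k
  v <- gc$vertices
  e <- gc$edges[gc$edges$from != gc$edges$to, , drop = FALSE]  # no self-loops
  out_e <- split(e[, c("to", "w")], e$from)
  in_e <- split(e[, c("from", "w")], e$to)
  covered <- stats::setNames(rep(FALSE, nrow(v)), v$id)
  paths <- list()

  # heaviest candidate not yet on the path; ties by candidate id
  best_candidate <- function(tbl, col, on_path) {
    if (is.null(tbl)) return(NULL)
    tbl <- tbl[!(tbl[[col]] %in% on_path) & tbl$w > 0, , drop = FALSE]
    if (nrow(tbl) == 0L) return(NULL)
    tbl <- tbl[order(-tbl$w, tbl[[col]]), , drop = FALSE]
    list(vertex = tbl[[col]][1L], w = tbl$w[1L])
  }

  while (any(!covered)) {
    start <- v$id[!covered[v$id]][1L]   # v is sorted by f desc, seed lex
    path <- start
    up_added <- 0L
    down_added <- 0L
    repeat {
      n_edges <- length(path) - 1L
      down <- if (down_added < 3L && n_edges < max_edges)
        best_candidate(out_e[[path[length(path)]]], "to", path) else NULL
      up <- if (up_added < 3L && n_edges < max_edges)
        best_candidate(in_e[[path[1L]]], "from", path) else NULL
      if (is.null(down) && is.null(up)) break
      take_down <- !is.null(down) && (is.null(up) || down$w >= up$w)
      if (take_down) {
        path <- c(path, down$vertex)
        down_added <- down_added + 1L
      } else {
        path <- c(up$vertex, path)
        up_added <- up_added + 1L
      }
    }
    covered[path] <- TRUE
    covered[start] <- TRUE
    si <- match(start, path)
    paths[[length(paths) + 1L]] <- structure(
      list(vertices = path, start = start,
           upstream = path[seq_len(si)],            # head .. start
           downstream = path[si:length(path)]),     # start .. tail
      class = "motif_path"
    )
  }
  paths
}

#' @export
print.motif_path <- function(x, ...) {
  cat("motif path: ", paste(x$vertices, collapse = " -> "),
      " (start ", x$start, ")\n", sep = "")
  invisible(x)
}

# per-sequence forward/reverse character strings, cached once
sequence_strands <- function(seqs) {
  list(fwd = as.character(seqs),
       rev = as.character(Biostrings::reverseComplement(seqs)),
       len = Biostrings::width(seqs),
       ids = if (is.null(names(seqs))) as.character(seq_along(seqs))
             else names(seqs))
}

#' Locate occurrences of a cluster-path segment in the input sequences
#'
#' A window of length `k + (#edges in segment)` matches when each of its
#' length-`k` sub-windows, in order, is a member k-mer of the corresponding
#' cluster of the segment. Both strands are scanned; all (possibly
#' overlapping) matches are kept. Coordinates are 0-based half-open on the
#' forward strand.
#'
#' @param segment Ordered cluster ids, contiguous in some path.
#' @param gc A `cluster_digraph`.
#' @param seqs A `DNAStringSet` (or a cached [sequence_strands()] list).
#' @param k Word length.
#' @return `data.frame` with columns `seqname`, `start`, `end`, `strand`,
#'   `word`.
#' @export
collect_occurrences <- function(segment, gc, seqs, k) {
  strands <- if (is.list(seqs) && !is.null(seqs$fwd)) seqs
             else sequence_strands(seqs)
  member_sets <- gc$members[segment]
  m <- length(segment)
  L <- k + (m - 1L)
  hits <- list()
  scan_one <- function(s, l, seqname, strand) {
    if (l < L) return(NULL)
    starts <- seq_len(l - k + 1L)
    kv <- substring(s, starts, starts + k - 1L)
    ok <- lapply(member_sets, function(set) kv %in% set)
    n_off <- l - L + 1L
    match_at <- ok[[1L]][seq_len(n_off)]
    if (m > 1L) {
      for (j in 2:m) {
        match_at <- match_at & ok[[j]][seq_len(n_off) + (j - 1L)]
      }
    }
    off <- which(match_at)   # 1-based on the scanned strand string
    if (length(off) == 0L) return(NULL)
    word <- substring(s, off, off + L - 1L)
    if (strand == "+") {
      start0 <- off - 1L
    } else {
      start0 <- l - (off - 1L) - L   # map back to forward coordinates
    }
    data.frame(seqname = seqname, start = start0, end = start0 + L,
               strand = strand, word = word, stringsAsFactors = FALSE)
  }
  for (i in seq_along(strands$fwd)) {
    hits[[length(hits) + 1L]] <-
      scan_one(strands$fwd[i], strands$len[i], strands$ids[i], "+")
    hits[[length(hits) + 1L]] <-
      scan_one(strands$rev[i], strands$len[i], strands$ids[i], "-")
  }
  res <- do.call(rbind, hits)
  if (is.null(res)) {
    res <- data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      word = character(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

# rows of o1 that overlap (same seqname & strand, intervals intersect)
# at least one row of o2
intersect_occurrences <- function(o1, o2) {
  if (nrow(o1) == 0L || nrow(o2) == 0L) return(o1[0, , drop = FALSE])
  key1 <- paste(o1$seqname, o1$strand)
  key2 <- paste(o2$seqname, o2$strand)
  hit <- logical(nrow(o1))
  idx2 <- split(seq_len(nrow(o2)), key2)
  for (i in seq_len(nrow(o1))) {
    js <- idx2[[key1[i]]]
    if (is.null(js)) next
    hit[i] <- any(o1$start[i] < o2$end[js] & o2$start[js] < o1$end[i])
  }
  o1[hit, , drop = FALSE]
}

#' Refine a path into one, two, or three motif occurrence sets
#'
#' Given the occurrence sets of the upstream sub-path (`o1`, including the
#' start cluster), the downstream sub-path (`o2`, including the start), and
#' the full path (`full`), computes the overlap ratio
#' `r = |O1 intersect O2| / min(|O1|, |O2|)` (occurrences overlap when they
#' share sequence and strand and their intervals intersect; empty `O1` or
#' `O2` gives `r = 0`) and branches:
#' * `r > 1/2`: one motif from the full path's occurrences;
#' * `1/4 < r <= 1/2`: three motifs, from `O1`, `O2` and their intersection;
#' * `r <= 1/4`: two motifs, from `O1` and `O2`.
#' Empty occurrence sets are dropped from the result.
#'
#' @param path A `motif_path` (used for labelling).
#' @param o1,o2,full Occurrence `data.frame`s from [collect_occurrences()].
#' @param pseudocount PWM pseudocount passed to [build_pwm()].
#' @return List of `motif_result` objects.
#' @export
refine_motifs <- function(path, o1, o2, full, pseudocount = 0.25) {
  n1 <- nrow(o1)
  n2 <- nrow(o2)
  if (n1 == 0L || n2 == 0L) {
    r <- 0
  } else {
    inter <- intersect_occurrences(o1, o2)
    r <- nrow(inter) / min(n1, n2)
  }
  pick <- if (r > 1 / 2) {
    list(full_path = full)
  } else if (r > 1 / 4) {
    list(upstream = o1, downstream = o2, intersection = inter)
  } else {
    list(upstream = o1, downstream = o2)
  }
  pick <- pick[vapply(pick, nrow, integer(1)) > 0]
  lapply(names(pick), function(src) {
    mot <- build_pwm(pick[[src]], pseudocount = pseudocount)
    mot$source <- src
    mot$path <- path$vertices
    mot
  })
}

#' Build a position weight matrix from an occurrence set
#'
#' Column probabilities are `(base count + pseudocount) /
#' (nsites + 4 * pseudocount)`; the consensus takes each column's most
#' probable base with ties resolved in `A < C < G < T` order.
#'
#' @param occurrences Occurrence `data.frame` with equal-length `word`s.
#' @param pseudocount Per-cell pseudocount (default 0.25).
#' @return An object of class `motif_result`: `consensus`, `pwm` (4 x L,
#'   rows `A,C,G,T`, columns sum to 1), `occurrences`, `nsites`, `source`.
#' @export
build_pwm <- function(occurrences, pseudocount = 0.25) {
  if (nrow(occurrences) == 0L) stop("cannot build a PWM from zero occurrences")
  words <- occurrences$word
  L <- unique(nchar(words))
  if (length(L) != 1L) stop("occurrence words must share one length")
  chars <- matrix(unlist(strsplit(words, "", fixed = TRUE), use.names = FALSE),
                  ncol = L, byrow = TRUE)
  counts <- vapply(seq_len(L), function(j)
    tabulate(factor(chars[, j], levels = BASES), nbins = 4L),
    integer(4))
  pwm <- (counts + pseudocount) / (length(words) + 4 * pseudocount)
  rownames(pwm) <- BASES
  consensus <- paste(BASES[apply(pwm, 2, which.max)], collapse = "")
  structure(
    list(consensus = consensus, pwm = pwm, occurrences = occurrences,
         nsites = length(words), source = "occurrences", path = NULL),
    class = "motif_result"
  )
}

#' @export
print.motif_result <- function(x, ...) {
  cat("motif ", x$consensus, " (", ncol(x$pwm), " nt, ", x$nsites,
      " sites, source ", x$source, ")\n", sep = "")
  invisible(x)
}
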