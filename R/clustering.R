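#' Greedy maximal independent set over the Hamming graph
#'
#' Scans the supplied k-mers (already ranked by decreasing significance) in
#' order and inserts each one that has no neighbour already in the set.
#' The result is independent and maximal with respect to the scanned
#' vertices; it approximates, but need not equal, a maximum independent set.
#'
#' @param g A `hamming_graph`.
#' @param k1 Ordered character vector of seed candidates (must be vertices
#'   of `g`).
#' @return Character vector of selected seeds, in insertion order.
#' @export
greedy_independent_set <- function(g, k1) {
  missing <- setdiff(k1, g$vertices)
  if (length(missing) > 0) {
    stop("seed k-mer(s) absent from the Hamming graph: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  chosen <- character()
  in_set <- new.env(parent = emptyenv())
  for (v in k1) {
    if (!any(vapply(g$adj[[v]], exists, logical(1), envir = in_set,
                    inherits = FALSE))) {
      chosen <- c(chosen, v)
      assign(v, TRUE, envir = in_set)
    }
  }
  chosen
}

#' Cluster objective f(C)
#'
#' For a vertex set `C` on the Hamming graph with per-vertex p-values
#' `p(u)`, computes
#' `f(C) = [-sum_{(u,v) in E(C)} w(u,v)^{-1} log(p(u) p(v))] / (|C| (|C|-1)) * log(|C|)`
#' where the sum runs over unordered member pairs joined by an edge of the
#' graph and logs are natural. A singleton has `f = 0`.
#'
#' @param members Character vector of member k-mers.
#' @param g A `hamming_graph`.
#' @param pvalues Named numeric vector of p-values covering `members`.
#' @return The objective value.
#' @export
eval_f <- function(members, g, pvalues) {
  m <- length(members)
  if (m < 1L) stop("cluster must have at least one member")
  if (any(pvalues[members] <= 0)) stop("p-values must be strictly positive")
  if (m == 1L) return(0)
  s <- internal_edge_sum(members, g, log(pvalues[members]))
  (-s) / (m * (m - 1)) * log(m)
}

# sum over internal edges of w(u,v)^{-1} (log p(u) + log p(v))
internal_edge_sum <- function(members, g, logp) {
  s <- 0
  for (u in members) {
    for (v in g$adj[[u]]) {
      if (u < v && v %in% members) {
        s <- s + (1 / g$wmap[[paste0(u, ">", v)]]) * (logp[[u]] + logp[[v]])
      }
    }
  }
  s
}

f_from_sum <- function(s, m) {
  if (m <= 1L) return(0)
  (-s) / (m * (m - 1)) * log(m)
}

# connectivity of `members` within g, required to contain `anchor`
is_connected_with <- function(members, g, anchor) {
  if (!(anchor %in% members)) return(FALSE)
  seen <- new.env(parent = emptyenv())
  memb <- new.env(parent = emptyenv())
  for (x in members) assign(x, TRUE, envir = memb)
  queue <- anchor
  assign(anchor, TRUE, envir = seen)
  n_seen <- 1L
  while (length(queue) > 0) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (nb in g$adj[[cur]]) {
      if (exists(nb, envir = memb, inherits = FALSE) &&
          !exists(nb, envir = seen, inherits = FALSE)) {
        assign(nb, TRUE, envir = seen)
        n_seen <- n_seen + 1L
        queue <- c(queue, nb)
      }
    }
  }
  n_seen == length(members)
}

#' Grow one k-mer cluster from a seed by hill-climbing f(C)
#'
#' Initialises the cluster with the seed plus the pair of its neighbours
#' maximising `f` (all available neighbours when fewer than two exist).
#' Then alternates: an add phase that admits the single boundary neighbour
#' giving the largest strict increase of `f`, and a remove phase that
#' evicts the single non-seed member giving the largest strict increase
#' while keeping the cluster connected and seed-containing. Terminates when
#' neither phase improves; `f` strictly increases at every accepted move,
#' so termination is guaranteed. Ties are broken lexicographically.
#'
#' @param seed A vertex of `g`.
#' @param g A `hamming_graph`.
#' @param pvalues Named p-value vector covering the vertices of `g`.
#' @return An object of class `kmer_cluster`: list with `seed`, `members`
#'   (sorted), `score`.
#' @export
grow_cluster <- function(seed, g, pvalues) {
  if (!(seed %in% g$vertices)) stop("seed '", seed, "' is not a graph vertex")
  nb <- g$adj[[seed]]
  if (length(nb) >= 2L) {
    best <- NULL
    best_f <- -Inf
    pairs <- utils::combn(sort(nb), 2L)
    for (j in seq_len(ncol(pairs))) {
      cand <- c(seed, pairs[, j])
      fj <- eval_f(cand, g, pvalues)
      if (fj > best_f) {
        best_f <- fj
        best <- cand
      }
    }
    members <- best
  } else {
    members <- c(seed, nb)
  }
  logp <- log(pvalues)
  s_cur <- internal_edge_sum(members, g, logp)
  f_cur <- f_from_sum(s_cur, length(members))

  # incident-edge contribution of x against the current members
  delta_of <- function(x, members) {
    d <- 0
    for (v in g$adj[[x]]) {
      if (v %in% members && v != x) {
        d <- d + (1 / g$wmap[[paste0(x, ">", v)]]) * (logp[[x]] + logp[[v]])
      }
    }
    d
  }

  repeat {
    changed <- FALSE
    m <- length(members)
    # add phase: best boundary neighbour with a strict improvement
    boundary <- sort(setdiff(unique(unlist(g$adj[members], use.names = FALSE)),
                             members))
    if (length(boundary) > 0) {
      fs <- vapply(boundary, function(b)
        f_from_sum(s_cur + delta_of(b, members), m + 1L), numeric(1))
      i <- which.max(fs)
      if (fs[i] > f_cur) {
        b <- boundary[i]
        s_cur <- s_cur + delta_of(b, members)
        members <- c(members, b)
        f_cur <- fs[i]
        changed <- TRUE
      }
    }
    # remove phase: best eviction keeping seed and connectivity
    m <- length(members)
    removable <- sort(setdiff(members, seed))
    if (length(removable) > 0 && m > 1L) {
      fs <- vapply(removable, function(r) {
        if (!is_connected_with(setdiff(members, r), g, seed)) return(-Inf)
        f_from_sum(s_cur - delta_of(r, setdiff(members, r)), m - 1L)
      }, numeric(1))
      i <- which.max(fs)
      if (is.finite(fs[i]) && fs[i] > f_cur) {
        r <- removable[i]
        s_cur <- s_cur - delta_of(r, setdiff(members, r))
        members <- setdiff(members, r)
        f_cur <- fs[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  structure(list(seed = seed, members = sort(members), score = unname(f_cur)),
            class = "kmer_cluster")
}

#' Grow clusters from every independent-set seed
#'
#' Seeds are processed in the order given (descending significance);
#' clusters are grown independently, so a k-mer may belong to several
#' clusters. Output is sorted by decreasing `f`, ties broken by seed
#' lexicographic order.
#'
#' @param g A `hamming_graph`.
#' @param is_set Character vector of seeds from [greedy_independent_set()].
#' @param pvalues Named p-value vector covering the vertices of `g`.
#' @return List of `kmer_cluster` objects in score order.
#' @export
cluster_all <- function(g, is_set, pvalues) {
  clusters <- lapply(is_set, grow_cluster, g = g, pvalues = pvalues)
  scores <- vapply(clusters, `[[`, numeric(1), "score")
  seeds <- vapply(clusters, `[[`, character(1), "seed")
  clusters[order(-scores, seeds)]
}

#' @export
print.kmer_cluster <- function(x, ...) {
  cat("k-mer cluster: seed ", x$seed, ", ", length(x$members),
      " members, f = ", format(x$score, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write a cluster report as TSV
#'
#' @param clusters List of `kmer_cluster` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(clusters, path) {
  df <- data.frame(
    cluster = sprintf("C%03d", seq_along(clusters)),
    seed = vapply(clusters, `[[`, character(1), "seed"),
    f = vapply(clusters, `[[`, numeric(1), "score"),
    n_members = vapply(clusters, function(cl) length(cl$members), integer(1)),
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
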