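# Independent oracles used across the suite. Each deliberately takes the
# naive route (term-by-term sums, all-pairs scans, exhaustive window
# enumeration) so it shares no code path with the package implementation.

ORACLE_BASES <- c("A", "C", "G", "T")

random_kmer_sample <- function(n, k) {
  universe <- apply(do.call(expand.grid, rep(list(ORACLE_BASES), k)),
                    1, paste, collapse = "")
  sample(universe, min(n, length(universe)))
}

random_dna <- function(len) {
  paste(sample(ORACLE_BASES, len, replace = TRUE), collapse = "")
}

# Poisson upper tail by explicit term summation: 1 - sum_{x<n} e^-lam lam^x/x!
oracle_poisson_tail <- function(n_t, lam) {
  if (n_t == 0) return(1)
  x <- 0:(n_t - 1)
  1 - sum(exp(-lam + x * log(lam) - lfactorial(x)))
}

# hand-rolled Markov chain product for one k-mer
oracle_chain_lambda <- function(model, t, tp) {
  a <- strsplit(t, "")[[1]]
  p <- model$M1[[a[1]]] * model$M2[a[1], a[2]]
  if (length(a) >= 3) {
    for (j in 3:length(a)) {
      p <- p * model$M3[paste0(a[j - 2], a[j - 1]), a[j]]
    }
  }
  p * tp
}

# all-pairs Hamming-1 edge set, vectorised by position
oracle_hamming_edges <- function(kmers) {
  n <- length(kmers)
  if (n < 2) return(data.frame(u = character(), v = character()))
  k <- nchar(kmers[1])
  mat <- matrix(unlist(strsplit(kmers, "")), ncol = k, byrow = TRUE)
  d <- matrix(0L, n, n)
  for (j in seq_len(k)) {
    d <- d + outer(mat[, j], mat[, j], "!=")
  }
  idx <- which(d == 1L & upper.tri(d), arr.ind = TRUE)
  u <- pmin(kmers[idx[, 1]], kmers[idx[, 2]])
  v <- pmax(kmers[idx[, 1]], kmers[idx[, 2]])
  df <- data.frame(u = u, v = v, stringsAsFactors = FALSE)
  df[order(df$u, df$v), , drop = FALSE]
}

# direct substring count of `word` over sequences and reverse complements
oracle_substring_count <- function(word, seq_strings) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  count_in <- function(s) {
    l <- nchar(s)
    w <- nchar(word)
    if (l < w) return(0L)
    starts <- seq_len(l - w + 1L)
    sum(substring(s, starts, starts + w - 1L) == word)
  }
  sum(vapply(seq_strings, count_in, integer(1))) +
    sum(vapply(vapply(seq_strings, revcomp, character(1)), count_in, integer(1)))
}

# Eq.-style cluster objective from first principles, scanning all pairs
oracle_eval_f <- function(members, edges_df, pvalues) {
  m <- length(members)
  if (m <= 1) return(0)
  s <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      a <- min(members[i], members[j])
      b <- max(members[i], members[j])
      hit <- which(edges_df$u == a & edges_df$v == b)
      if (length(hit) == 1) {
        s <- s + (1 / edges_df$w[hit]) *
          log(pvalues[[members[i]]] * pvalues[[members[j]]])
      }
    }
  }
  (-s) / (m * (m - 1)) * log(m)
}

# build a hamming_graph-shaped object from an arbitrary edge list, for
# exercising the clustering operations on graphs that need not arise from
# k-mer neighbourhoods
make_test_graph <- function(vertices, edges_df) {
  if (nrow(edges_df) > 0) {
    u <- pmin(edges_df$u, edges_df$v)
    v <- pmax(edges_df$u, edges_df$v)
    edges_df <- unique(data.frame(u = u, v = v,
                                  w = if ("w" %in% names(edges_df))
                                        edges_df$w else 1,
                                  stringsAsFactors = FALSE))
    edges_df <- edges_df[order(edges_df$u, edges_df$v), , drop = FALSE]
  } else {
    edges_df <- data.frame(u = character(), v = character(), w = numeric())
  }
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (x in vertices) adj[[x]] <- character()
  for (i in seq_len(nrow(edges_df))) {
    adj[[edges_df$u[i]]] <- sort(c(adj[[edges_df$u[i]]], edges_df$v[i]))
    adj[[edges_df$v[i]]] <- sort(c(adj[[edges_df$v[i]]], edges_df$u[i]))
  }
  wmap <- if (nrow(edges_df) == 0L) {
    stats::setNames(numeric(), character())
  } else {
    stats::setNames(c(edges_df$w, edges_df$w),
                    c(paste0(edges_df$u, ">", edges_df$v),
                      paste0(edges_df$v, ">", edges_df$u)))
  }
  structure(list(vertices = sort(vertices), edges = edges_df, adj = adj,
                 wmap = wmap),
            class = "hamming_graph")
}

random_test_graph <- function(n_vertices, edge_prob) {
  vertices <- sprintf("V%02d", seq_len(n_vertices))
  pairs <- t(utils::combn(vertices, 2))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  make_test_graph(vertices,
                  data.frame(u = pairs[keep, 1], v = pairs[keep, 2],
                             stringsAsFactors = FALSE))
}

# independence + maximality, checked directly against the edge list
oracle_is_independent_maximal <- function(set, graph) {
  for (i in seq_len(nrow(graph$edges))) {
    if (graph$edges$u[i] %in% set && graph$edges$v[i] %in% set) {
      return(list(independent = FALSE, maximal = NA))
    }
  }
  for (v in setdiff(graph$vertices, set)) {
    if (!any(graph$adj[[v]] %in% set)) {
      return(list(independent = TRUE, maximal = FALSE))
    }
  }
  list(independent = TRUE, maximal = TRUE)
}

# exhaustive segment-occurrence scan over all windows of all sequences
oracle_occurrences <- function(member_sets, seq_strings, k) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  m <- length(member_sets)
  L <- k + m - 1L
  rows <- list()
  for (nm in names(seq_strings)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq_strings[[nm]] else revcomp(seq_strings[[nm]])
      l <- nchar(s)
      if (l < L) next
      for (off in 0:(l - L)) {
        ok <- TRUE
        for (j in seq_len(m)) {
          sub <- substr(s, off + j, off + j + k - 1L)
          if (!(sub %in% member_sets[[j]])) { ok <- FALSE; break }
        }
        if (ok) {
          start0 <- if (strand == "+") off else l - off - L
          rows[[length(rows) + 1L]] <- data.frame(
            seqname = nm, start = start0, end = start0 + L, strand = strand,
            word = substr(s, off + 1L, off + L), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(seqname = character(), start = integer(),
                      end = integer(), strand = character(),
                      word = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# AUPRC by explicit enumeration of every distinct threshold
oracle_auprc <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  prec <- numeric(length(ths))
  rec <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pred <- scores >= ths[i]
    prec[i] <- sum(pred & labels) / sum(pred)
    rec[i] <- sum(pred & labels) / sum(labels)
  }
  sum(diff(c(0, rec)) * prec)
}

# all-window log-odds scan for one sequence string (forward only)
oracle_scan_string <- function(s, pwm, bg, floor = 1e-4) {
  L <- ncol(pwm)
  l <- nchar(s)
  if (l < L) return(-Inf)
  best <- -Inf
  for (off in 0:(l - L)) {
    sc <- 0
    for (j in seq_len(L)) {
      b <- substr(s, off + j, off + j)
      if (!(b %in% ORACLE_BASES)) { sc <- -Inf; break }
      sc <- sc + log(max(pwm[b, j], floor) / bg[[b]])
    }
    best <- max(best, sc)
  }
  best
}

sort_occ <- function(df) {
  df <- df[order(df$seqname, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
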