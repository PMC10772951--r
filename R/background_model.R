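BASES <- c("A", "C", "G", "T")

#' Estimate a Markov background model from input sequences
#'
#' Builds the background matrices from substring frequencies of lengths 1-3
#' over the forward strands of the input:
#' \describe{
#'   \item{`M1`}{marginal probability of each nucleotide (length 4),}
#'   \item{`M2`}{conditional probability `M2(b | a)` of a nucleotide given
#'     the preceding one (4 x 4, rows condition),}
#'   \item{`M3`}{conditional probability `M3(c | ab)` given the preceding
#'     dinucleotide (16 x 4, rows condition).}
#' }
#' A pseudocount is added to every cell before normalisation so all entries
#' are strictly positive. Lower orders collapse the higher matrices: with
#' `order = 0` every row of `M2` and `M3` equals `M1`; with `order = 1`,
#' `M3(c | ab) = M2(c | b)`.
#'
#' @param seqs A `DNAStringSet`.
#' @param order Markov order, 0, 1 or 2 (default 2).
#' @param pseudocount Pseudocount per matrix cell (default 0.5).
#' @return An object of class `markov_background` with elements `M1`, `M2`,
#'   `M3`, `order`, `pseudocount`.
#' @export
estimate_background <- function(seqs, order = 2, pseudocount = 0.5) {
  stopifnot(order %in% 0:2, pseudocount >= 0)
  if (length(seqs) == 0L) stop("cannot estimate background from an empty sequence set")
  if (max(Biostrings::width(seqs)) < 3L) {
    stop("background estimation needs at least one sequence of length >= 3")
  }
  cnt1 <- count_words(seqs, 1L)
  cnt2 <- count_words(seqs, 2L)
  cnt3 <- count_words(seqs, 3L)

  m1 <- (cnt1[BASES] + pseudocount)
  m1 <- m1 / sum(m1)

  m2 <- matrix(cnt2[paste0(rep(BASES, each = 4), BASES)] + pseudocount,
               nrow = 4, byrow = TRUE, dimnames = list(BASES, BASES))
  m2 <- m2 / rowSums(m2)

  dinucs <- paste0(rep(BASES, each = 4), BASES)
  m3 <- matrix(cnt3[paste0(rep(dinucs, each = 4), BASES)] + pseudocount,
               nrow = 16, byrow = TRUE, dimnames = list(dinucs, BASES))
  m3 <- m3 / rowSums(m3)

  if (order == 0) {
    m2 <- matrix(rep(m1, each = 4), nrow = 4, dimnames = list(BASES, BASES))
    m3 <- matrix(rep(m1, each = 16), nrow = 16, dimnames = list(dinucs, BASES))
  } else if (order == 1) {
    m3 <- m2[substr(dinucs, 2, 2), , drop = FALSE]
    rownames(m3) <- dinucs
  }

  structure(
    list(M1 = m1, M2 = m2, M3 = m3, order = order, pseudocount = pseudocount),
    class = "markov_background"
  )
}

# collapsed word counts over forward strands; windows containing N are
# silently excluded by oligonucleotideFrequency
count_words <- function(seqs, width) {
  Biostrings::oligonucleotideFrequency(seqs, width = width,
                                       simplify.as = "collapsed")
}

#' @export
print.markov_background <- function(x, ...) {
  cat("Markov background model (order ", x$order, ", pseudocount ",
      x$pseudocount, ")\n", sep = "")
  cat("M1:", paste(sprintf("%s=%.4f", BASES, x$M1), collapse = " "), "\n")
  invisible(x)
}

#' Expected count of a k-mer under the background model
#'
#' Computes `lambda(t) = M1(a1) M2(a2|a1) M3(a3|a1a2) ... M3(ak|a(k-2)a(k-1))`
#' multiplied by the number of window positions. For `k = 2` the `M3`
#' factors are absent.
#'
#' @param model A `markov_background`.
#' @param t A k-mer (or character vector of k-mers, all the same length)
#'   over `{A,C,G,T}`.
#' @param total_positions Number of length-k window positions the expected
#'   count refers to (`sum_i (l_i - k + 1)`, doubled when counting both
#'   strands).
#' @return Expected count(s), numeric of the same length as `t`.
#' @export
expected_count <- function(model, t, total_positions) {
  stopifnot(inherits(model, "markov_background"), total_positions >= 0)
  k <- unique(nchar(t))
  if (length(k) != 1L) stop("all k-mers must have the same length")
  if (k < 2L) stop("expected_count requires k >= 2")
  if (any(grepl("[^ACGT]", t))) stop("k-mers must be over {A,C,G,T}")
  chars <- matrix(unlist(strsplit(t, "", fixed = TRUE), use.names = FALSE),
                  ncol = k, byrow = TRUE)
  p <- model$M1[chars[, 1L]] * model$M2[cbind(chars[, 1L], chars[, 2L])]
  if (k >= 3L) {
    for (j in 3:k) {
      ctx <- paste0(chars[, j - 2L], chars[, j - 1L])
      p <- p * model$M3[cbind(ctx, chars[, j])]
    }
  }
  unname(p * total_positions)
}

#' Upper-tail Poisson p-value for an observed k-mer count
#'
#' Probability of observing at least `n_t` occurrences under a Poisson
#' distribution with mean `lam`, i.e. `1 - sum_{x=0}^{n_t-1} e^-lam lam^x/x!`,
#' evaluated with the stable survival function and clipped to
#' `[.Machine$double.xmin, 1]`.
#'
#' @param n_t Observed count (non-negative integer, vectorised).
#' @param lam Expected count (non-negative, vectorised).
#' @return p-value(s) in (0, 1].
#' @export
poisson_pvalue <- function(n_t, lam) {
  if (any(n_t < 0) || any(lam < 0)) stop("n_t and lam must be non-negative")
  p <- stats::ppois(n_t - 1, lambda = lam, lower.tail = FALSE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Score and tier all observed k-mers
#'
#' Counts every k-mer over both strands (forward windows plus windows of
#' each sequence's reverse complement), computes its expected count under
#' the background model with the position total doubled to match, assigns
#' Poisson p-values, and ranks k-mers by decreasing `-log10(p)` with
#' lexicographic tie-breaks. Tier labels partition the ranking:
#' `K1` = top `min(100, ceil(m/2))`, `K2` = remainder of the top half,
#' `K3` = bottom half, for `m` distinct observed k-mers.
#'
#' @param seqs A `DNAStringSet`.
#' @param model A `markov_background` (estimated from `seqs` unless supplied
#'   otherwise).
#' @param k Word length (default 6).
#' @param top_k1 Size cap of the highly significant tier (default 100).
#' @return A `kmer_table`: a `data.frame` with columns `kmer`, `count`,
#'   `lambda`, `pvalue`, `neglog10p`, `tier`, in rank order, with attribute
#'   `k`.
#' @export
build_kmer_table <- function(seqs, model, k = 6, top_k1 = 100) {
  stopifnot(k >= 2, top_k1 >= 1)
  counts <- count_words(seqs, as.integer(k)) +
    count_words(Biostrings::reverseComplement(seqs), as.integer(k))
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no k-mers observed at k = ", k)
  tp2 <- 2 * total_positions(seqs, k)
  kmers <- names(counts)
  lambda <- expected_count(model, kmers, tp2)
  pval <- poisson_pvalue(as.numeric(counts), lambda)
  neglog10p <- -log10(pval)
  ord <- order(-neglog10p, kmers)
  m <- length(kmers)
  n_k2 <- ceiling(m / 2)
  n_k1 <- min(top_k1, n_k2)
  tier <- rep("K3", m)
  tier[seq_len(n_k2)] <- "K2"
  tier[seq_len(n_k1)] <- "K1"
  tab <- data.frame(
    kmer = kmers[ord],
    count = as.integer(counts[ord]),
    lambda = lambda[ord],
    pvalue = pval[ord],
    neglog10p = neglog10p[ord],
    tier = tier,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(tab, k = as.integer(k), class = c("kmer_table", "data.frame"))
}

#' K-mers of a significance tier
#'
#' `"K1"` returns the highly significant tier; `"K2"` the full significant
#' set (top half of the ranking, a superset of K1); `"K3"` the insignificant
#' remainder.
#'
#' @param table A `kmer_table`.
#' @param tier One of `"K1"`, `"K2"`, `"K3"`.
#' @return Character vector of k-mers in rank order.
#' @export
tier_kmers <- function(table, tier = c("K1", "K2", "K3")) {
  tier <- match.arg(tier)
  switch(tier,
    K1 = table$kmer[table$tier == "K1"],
    K2 = table$kmer[table$tier %in% c("K1", "K2")],
    K3 = table$kmer[table$tier == "K3"]
  )
}

#' Write a k-mer table as TSV
#'
#' @param table A `kmer_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
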