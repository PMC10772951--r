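#' Generate background sequences with planted motif instances
#'
#' Draws background sequences from a Markov chain of the requested order
#' (uniform i.i.d. by default) and, for a Bernoulli(`instance_rate`) subset
#' of sequences, implants one mutated copy of the consensus at a uniform
#' random offset on a uniform random strand. Mutation substitutes each
#' position independently with probability `mutation_rate`, uniformly among
#' the three other bases. Implantation overwrites background bases, so all
#' sequence lengths stay equal to `seq_length`.
#'
#' @param motif_consensus Consensus to plant (length 4-18 over `{A,C,G,T}`).
#' @param n_sequences Number of sequences.
#' @param seq_length Length of every sequence (nt).
#' @param instance_rate Fraction of sequences receiving one instance
#'   (default 0.3).
#' @param mutation_rate Per-position substitution probability
#'   (default 0.1; must be < 0.75).
#' @param background Optional `markov_background` to draw the background
#'   from; uniform i.i.d. when `NULL`.
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   identical seeds give identical output.
#' @return List with `seqs` (a named `DNAStringSet`, ids `seq_1..seq_n`)
#'   and `truth`: a `data.frame` of implanted sites (`seqname`, `start`
#'   0-based, `end`, `strand`, `word` as written on the forward strand).
#' @export
generate_planted_dataset <- function(motif_consensus, n_sequences,
                                     seq_length, instance_rate = 0.3,
                                     mutation_rate = 0.1,
                                     background = NULL, seed = NULL) {
  L <- nchar(motif_consensus)
  if (L < 4 || L > 18) stop("motif length must be in 4..18")
  if (grepl("[^ACGT]", motif_consensus)) stop("consensus must be over {A,C,G,T}")
  if (instance_rate < 0 || instance_rate > 1) stop("instance_rate must be in [0,1]")
  if (mutation_rate < 0 || mutation_rate >= 0.75) stop("mutation_rate must be in [0, 0.75)")
  if (L > seq_length) stop("motif longer than seq_length")
  if (!is.null(seed)) set.seed(seed)

  chars <- matrix("", nrow = n_sequences, ncol = seq_length)
  if (is.null(background)) {
    chars[] <- sample(BASES, n_sequences * seq_length, replace = TRUE)
  } else {
    for (i in seq_len(n_sequences)) {
      chars[i, ] <- sample_markov_chain(background, seq_length)
    }
  }

  planted <- which(stats::runif(n_sequences) < instance_rate)
  motif_chars <- strsplit(motif_consensus, "", fixed = TRUE)[[1]]
  truth <- list()
  for (i in planted) {
    inst <- motif_chars
    mut <- which(stats::runif(L) < mutation_rate)
    for (j in mut) {
      inst[j] <- sample(setdiff(BASES, inst[j]), 1L)
    }
    strand <- sample(c("+", "-"), 1L)
    word <- paste(inst, collapse = "")
    fwd_word <- if (strand == "+") word else reverse_complement(word)
    start0 <- sample.int(seq_length - L + 1L, 1L) - 1L
    chars[i, (start0 + 1L):(start0 + L)] <-
      strsplit(fwd_word, "", fixed = TRUE)[[1]]
    truth[[length(truth) + 1L]] <- data.frame(
      seqname = paste0("seq_", i), start = start0, end = start0 + L,
      strand = strand, word = fwd_word, stringsAsFactors = FALSE
    )
  }
  truth <- if (length(truth) > 0) do.call(rbind, truth)
           else data.frame(seqname = character(), start = integer(),
                           end = integer(), strand = character(),
                           word = character(), stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(apply(chars, 1, paste, collapse = ""))
  names(seqs) <- paste0("seq_", seq_len(n_sequences))
  list(seqs = seqs, truth = truth)
}

sample_markov_chain <- function(model, len) {
  out <- character(len)
  out[1] <- sample(BASES, 1L, prob = model$M1)
  if (len >= 2) out[2] <- sample(BASES, 1L, prob = model$M2[out[1], ])
  if (len >= 3) {
    for (i in 3:len) {
      out[i] <- sample(BASES, 1L,
                       prob = model$M3[paste0(out[i - 2], out[i - 1]), ])
    }
  }
  out
}

#' Site-level precision and recall of reported motifs against ground truth
#'
#' A truth site counts as recovered when some reported occurrence on the
#' same sequence (either strand) overlaps it by at least
#' `truth length - slop` positions; a reported occurrence is correct when
#' it overlaps some truth site by the same margin.
#'
#' @param motifs List of `motif_result` objects (or a `cemig_result`).
#' @param truth Truth site `data.frame` from [generate_planted_dataset()].
#' @param slop Allowed shortfall in overlap, nt (default 2).
#' @return List with `recall`, `precision` (0 with attribute
#'   `no_predictions = TRUE` when nothing was reported), `n_truth`,
#'   `n_reported`.
#' @export
score_recovery <- function(motifs, truth, slop = 2) {
  if (inherits(motifs, "cemig_result")) motifs <- motifs$motifs
  occ <- if (length(motifs) == 0L) NULL
         else do.call(rbind, c(lapply(motifs, function(m)
           m$occurrences[, c("seqname", "start", "end")]),
           make.row.names = FALSE))
  n_truth <- nrow(truth)
  if (is.null(occ) || nrow(occ) == 0L) {
    precision <- structure(0, no_predictions = TRUE)
    return(list(recall = 0, precision = precision,
                n_truth = n_truth, n_reported = 0L))
  }
  need <- pmax(truth$end - truth$start - slop, 1L)
  occ_by_seq <- split(occ, occ$seqname)
  recovered <- vapply(seq_len(n_truth), function(i) {
    o <- occ_by_seq[[truth$seqname[i]]]
    if (is.null(o)) return(FALSE)
    ov <- pmin(o$end, truth$end[i]) - pmax(o$start, truth$start[i])
    any(ov >= need[i])
  }, logical(1))
  truth_by_seq <- split(truth, truth$seqname)
  correct <- vapply(seq_len(nrow(occ)), function(j) {
    tr <- truth_by_seq[[occ$seqname[j]]]
    if (is.null(tr)) return(FALSE)
    ov <- pmin(occ$end[j], tr$end) - pmax(occ$start[j], tr$start)
    any(ov >= pmax(tr$end - tr$start - slop, 1L))
  }, logical(1))
  list(recall = if (n_truth == 0) 0 else mean(recovered),
       precision = mean(correct),
       n_truth = n_truth, n_reported = nrow(occ))
}

#' Write truth sites as BED6
#'
#' @param truth Truth `data.frame` from [generate_planted_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, path) {
  df <- data.frame(chrom = truth$seqname, start = truth$start,
                   end = truth$end, name = "planted", score = 0L,
                   strand = truth$strand, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
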