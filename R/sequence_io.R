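#' Read input sequences from a FASTA file
#'
#' Reads a (possibly gzip-compressed) FASTA file into a
#' [Biostrings::DNAStringSet], upper-casing all residues. Only the alphabet
#' `A, C, G, T, N` is accepted; any other character is an error naming the
#' offending record.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` with one element per FASTA record, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  # read with the unconstrained alphabet first so invalid characters are
  # caught here rather than silently dropped
  raw <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(raw) == 0L) {
    stop("empty FASTA input: ", path)
  }
  # first whitespace-delimited token of the header is the record id
  names(raw) <- sub("\\s.*$", "", names(raw))
  chars <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chars)
  if (any(bad)) {
    stop("sequence '", names(raw)[which(bad)[1L]],
         "' contains characters outside {A,C,G,T,N}")
  }
  Biostrings::DNAStringSet(stats::setNames(chars, names(raw)))
}

validate_alphabet <- function(seqs) {
  freq <- Biostrings::alphabetFrequency(seqs, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(bad > 0)) {
    offender <- names(seqs)[which(bad > 0)[1L]]
    stop("sequence '", offender, "' contains characters outside {A,C,G,T,N}")
  }
  invisible(seqs)
}

#' Extract interval sequences from a genome FASTA using a BED file
#'
#' Intervals use 0-based half-open BED coordinates. Records are named
#' `chrom:start-end`; minus-strand intervals are reverse-complemented.
#'
#' @param bed_path Path to a BED file (at least 3 columns; strand honoured
#'   when a 6th column is present).
#' @param genome_fasta Path to the reference FASTA (a `.fai` index is created
#'   next to it if absent).
#' @return A `DNAStringSet` with one record per interval, in BED order.
#' @export
extract_bed_sequences <- function(bed_path, genome_fasta) {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  if (!file.exists(genome_fasta)) stop("genome FASTA not found: ", genome_fasta)
  gr <- rtracklayer::import(bed_path, format = "BED")
  fa <- Rsamtools::FaFile(genome_fasta)
  if (!file.exists(paste0(genome_fasta, ".fai"))) {
    Rsamtools::indexFa(genome_fasta)
  }
  info <- Rsamtools::seqinfo(fa)
  missing_chr <- setdiff(as.character(GenomicRanges::seqnames(gr)),
                         GenomeInfoDb::seqnames(info))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) not in genome FASTA: ", paste(missing_chr, collapse = ", "))
  }
  chr_len <- stats::setNames(GenomeInfoDb::seqlengths(info),
                             GenomeInfoDb::seqnames(info))
  ends <- GenomicRanges::end(gr)
  over <- ends > chr_len[as.character(GenomicRanges::seqnames(gr))]
  if (any(over)) {
    i <- which(over)[1L]
    stop("interval ", as.character(GenomicRanges::seqnames(gr))[i], ":",
         GenomicRanges::start(gr)[i] - 1L, "-", ends[i],
         " extends beyond chromosome end")
  }
  # getSeq on a stranded GRanges reverse-complements minus-strand hits
  strands <- as.character(GenomicRanges::strand(gr))
  strands[strands == "*"] <- "+"
  GenomicRanges::strand(gr) <- strands
  seqs <- Rsamtools::getSeq(fa, gr)
  names(seqs) <- paste0(GenomicRanges::seqnames(gr), ":",
                        GenomicRanges::start(gr) - 1L, "-",
                        GenomicRanges::end(gr))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  validate_alphabet(seqs)
  seqs
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; `N` maps to `N`.
#'
#' @param seq A single DNA string over `{A,C,G,T,N}`.
#' @return The reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Total number of length-k windows in a sequence set
#'
#' Computes `sum_i (l_i - k + 1)` over sequences with `l_i >= k`; shorter
#' sequences contribute zero (never negative terms).
#'
#' @param seqs A `DNAStringSet`.
#' @param k Word length.
#' @return Non-negative integer count of forward-strand window positions.
#' @export
total_positions <- function(seqs, k) {
  stopifnot(k >= 1)
  l <- Biostrings::width(seqs)
  sum(pmax(l - k + 1L, 0L))
}

#' Enumerate k-mer windows of a sequence set
#'
#' Yields every length-`k` window that contains no `N`, with its 0-based
#' forward-strand offset. With `both_strands = TRUE` windows of each
#' sequence's reverse complement are also emitted (offsets remain 0-based on
#' the reverse-complement string; `strand` records the origin).
#'
#' @param seqs A `DNAStringSet`.
#' @param k Word length (>= 2).
#' @param both_strands Also enumerate reverse-complement windows.
#' @return A `data.frame` with columns `kmer`, `seq_index`, `offset`,
#'   `strand`.
#' @export
iter_kmers <- function(seqs, k, both_strands = FALSE) {
  stopifnot(k >= 2)
  if (all(Biostrings::width(seqs) < k)) {
    warning("k = ", k, " exceeds every sequence length; no windows")
    return(data.frame(kmer = character(), seq_index = integer(),
                      offset = integer(), strand = character()))
  }
  one_strand <- function(chars, strand) {
    out <- vector("list", length(chars))
    for (i in seq_along(chars)) {
      s <- chars[[i]]
      l <- nchar(s)
      if (l < k) next
      starts <- seq_len(l - k + 1L)
      words <- substring(s, starts, starts + k - 1L)
      keep <- !grepl("N", words, fixed = TRUE)
      if (!any(keep)) next
      out[[i]] <- data.frame(kmer = words[keep], seq_index = i,
                             offset = starts[keep] - 1L, strand = strand)
    }
    do.call(rbind, out)
  }
  fwd <- one_strand(as.character(seqs), "+")
  if (!both_strands) {
    res <- fwd
  } else {
    rev <- one_strand(as.character(Biostrings::reverseComplement(seqs)), "-")
    res <- rbind(fwd, rev)
  }
  if (is.null(res)) {
    res <- data.frame(kmer = character(), seq_index = integer(),
                      offset = integer(), strand = character())
  }
  rownames(res) <- NULL
  res
}

#' Write sequences to FASTA
#'
#' @param seqs A `DNAStringSet`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, filepath = path, format = "fasta")
  invisible(path)
}
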