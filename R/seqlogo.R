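# Consensus and entropy-scaled logo statistics for aligned sequences
# (e.g. the S4 helix across HCN or EAG family members).

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (equal-length) FASTA file.
#' @return Character vector of aligned sequences, named by record id.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aln))
  if (length(seqs) == 0) stop("alignment is empty")
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: sequences differ in length")
  seqs
}

# alignment as a matrix of single characters, with validation shared by
# column_stats and consensus
.aln_matrix <- function(msa) {
  if (length(msa) == 0) stop("alignment is empty")
  msa <- toupper(msa)
  if (length(unique(nchar(msa))) != 1)
    stop("ragged alignment: sequences differ in length")
  do.call(rbind, strsplit(msa, ""))
}

#' Per-column alignment statistics
#'
#' Residue frequencies (over the 20 amino acids, gaps excluded from the
#' normalisation by default), Shannon entropy `H = -sum p log2 p` in bits,
#' and a logo stack height. The default height is the information content
#' `log2(20) - H` (the standard logo convention); `height_mode =
#' "inverse_entropy"` instead returns `c / (H + eps)`, a literal
#' inverse-proportionality reading that needs the regulariser `eps` to be
#' defined at perfectly conserved columns.
#'
#' @param msa Character vector of aligned sequences (or a path readable by
#'   [read_alignment()]).
#' @param position 1-based column index.
#' @param include_gaps Count gaps in the frequency denominator (default
#'   `FALSE`).
#' @param height_mode `"information"` (default) or `"inverse_entropy"`.
#' @param inverse_c,inverse_eps Constant and regulariser (bits) for the
#'   inverse-entropy mode; defaults 1 and 0.1.
#' @return Object of class `alignment_column`: list with `position`,
#'   `frequencies` (named over residues present), `gap_fraction`,
#'   `n_sequences`, `entropy` (bits), `stack_height`.
#' @export
column_stats <- function(msa, position, include_gaps = FALSE,
                         height_mode = c("information", "inverse_entropy"),
                         inverse_c = 1, inverse_eps = 0.1) {
  height_mode <- match.arg(height_mode)
  if (length(msa) == 1 && file.exists(msa)) msa <- read_alignment(msa)
  m <- .aln_matrix(msa)
  if (position < 1 || position > ncol(m))
    stop("position out of range: ", position)
  col <- m[, position]
  gap <- col %in% c("-", ".")
  denom_chars <- if (include_gaps) col else col[!gap]
  counts <- table(factor(col[!gap], levels = .AA20))
  if (length(denom_chars) > 0) {
    freqs <- as.numeric(counts) / length(denom_chars)
  } else {
    freqs <- rep(0, length(.AA20))
  }
  names(freqs) <- .AA20
  p <- freqs[freqs > 0]
  H <- if (length(p) > 0) -sum(p * log2(p)) else 0
  height <- switch(height_mode,
                   information = log2(20) - H,
                   inverse_entropy = inverse_c / (H + inverse_eps))
  structure(list(position = position,
                 frequencies = freqs[freqs > 0],
                 gap_fraction = mean(gap),
                 n_sequences = nrow(m),
                 entropy = H,
                 stack_height = height),
            class = "alignment_column")
}

#' Consensus sequence of an alignment
#'
#' Modal non-gap residue at each column, ties broken alphabetically and
#' flagged. All-gap columns yield `"-"` with frequency 0.
#'
#' @param msa Character vector of aligned sequences (or a path).
#' @return data.frame with columns `position`, `residue`, `frequency`
#'   (fraction of non-gap symbols) and `tie` (logical), plus attribute
#'   `consensus` holding the consensus string.
#' @export
consensus <- function(msa) {
  if (length(msa) == 1 && file.exists(msa)) msa <- read_alignment(msa)
  m <- .aln_matrix(msa)
  out <- data.frame(position = seq_len(ncol(m)), residue = "-",
                    frequency = 0, tie = FALSE)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[!(col %in% c("-", "."))]
    if (length(col) == 0) next
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    out$residue[j] <- sort(top)[1]   # alphabetical tie-break
    out$frequency[j] <- max(tab) / length(col)
    out$tie[j] <- length(top) > 1
  }
  attr(out, "consensus") <- paste(out$residue, collapse = "")
  out
}

#' Per-position logo table for an alignment
#'
#' Convenience wrapper computing [column_stats()] at every column.
#'
#' @inheritParams column_stats
#' @return data.frame with one row per position: `position`, `entropy`,
#'   `stack_height`, `consensus`, `consensus_freq`.
#' @export
logo_table <- function(msa, include_gaps = FALSE,
                       height_mode = "information") {
  if (length(msa) == 1 && file.exists(msa)) msa <- read_alignment(msa)
  m <- .aln_matrix(msa)
  cons <- consensus(msa)
  stats_ <- lapply(seq_len(ncol(m)), function(j)
    column_stats(msa, j, include_gaps = include_gaps,
                 height_mode = height_mode))
  data.frame(position = seq_len(ncol(m)),
             entropy = vapply(stats_, `[[`, numeric(1), "entropy"),
             stack_height = vapply(stats_, `[[`, numeric(1),
                                   "stack_height"),
             consensus = cons$residue,
             consensus_freq = cons$frequency)
}
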