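# Nucleotides are stored as integers 1..4 = A, C, G, T.  A transition
# (purine<->purine or pyrimidine<->pyrimidine) is exactly |i - j| == 2 in this
# coding, which the event-log summaries rely on.
BASES <- c("A", "C", "G", "T")

#' Convert between integer-coded and character nucleotide sequences
#'
#' Sequences are held internally as integer vectors (1 = A, 2 = C, 3 = G,
#' 4 = T) for fast in-place substitution.
#'
#' @param x An integer vector (for `seq_to_char()`) or a single character
#'   string / character vector of single letters (for `char_to_seq()`).
#' @return `seq_to_char()` returns a single string; `char_to_seq()` an integer
#'   vector.
#' @examples
#' char_to_seq("ACGT")
#' seq_to_char(c(1L, 2L, 3L, 4L))
#' @export
seq_to_char <- function(x) {
  paste(BASES[x], collapse = "")
}

#' @rdname seq_to_char
#' @export
char_to_seq <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  out <- match(toupper(x), BASES)
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("non-ACGT character '", x[bad], "' at position ", bad,
         "; sequences must be pure nucleotide", call. = FALSE)
  }
  out
}

#' Create a genome object
#'
#' A genome is an ordered list of gene instances over a single concatenated
#' nucleotide sequence.  Gene ids identify homology across lineages: two
#' genomes carrying the same gene id hold homologous (equal-length) copies.
#' Genomes use reference semantics (they are environments) so that the
#' simulation engine can substitute single sites without copying the whole
#' sequence; use [genome_clone()] to take an independent copy.
#'
#' @param seq Integer-coded nucleotide sequence (see [char_to_seq()]).
#' @param gene_id Character vector of unique gene identifiers, in genome order.
#' @param gene_len Integer vector of gene lengths (bp); each a multiple of 3
#'   and summing to `length(seq)`.
#' @return An environment of class `"genome"` with fields `seq`, `gene_id`,
#'   `gene_len`.
#' @export
new_genome <- function(seq, gene_id, gene_len) {
  gene_len <- as.integer(gene_len)
  stopifnot(length(gene_id) == length(gene_len))
  if (sum(gene_len) != length(seq))
    stop("gene lengths (", sum(gene_len), ") do not sum to sequence length (",
         length(seq), ")", call. = FALSE)
  if (any(gene_len %% 3L != 0L))
    stop("gene lengths must be multiples of 3", call. = FALSE)
  if (anyDuplicated(gene_id))
    stop("duplicate gene ids within one genome", call. = FALSE)
  g <- new.env(parent = baseenv())
  g$seq <- as.integer(seq)
  g$gene_id <- as.character(gene_id)
  g$gene_len <- gene_len
  class(g) <- "genome"
  g
}

# In-place write into a genome sequence.  Complex assignment through `$`
# (g$seq[i] <- v) holds an extra reference to the vector and copies it on
# every event; evaluating the subassignment inside the genome environment
# keeps the reference count at one so the write is O(|idx|), not O(L).
.seq_set <- function(g, idx, val) {
  g$.idx <- idx
  g$.val <- val
  evalq(seq[.idx] <- .val, g)
  invisible(g)
}

#' @rdname new_genome
#' @param g A genome.
#' @export
genome_clone <- function(g) {
  new_genome(g$seq, g$gene_id, g$gene_len)
}

#' @rdname new_genome
#' @export
genome_nbp <- function(g) length(g$seq)

# 1-based start offsets of each gene on the concatenate
genome_starts <- function(g) {
  if (length(g$gene_len) == 0L) return(integer(0))
  cumsum(c(1L, g$gene_len[-length(g$gene_len)]))
}

# gene index containing 1-based site(s)
genome_gene_at <- function(g, sites) {
  findInterval(sites, cumsum(c(1L, g$gene_len)), rightmost.closed = FALSE)
}

#' Partition a root sequence into fixed-size genes
#'
#' The root genome is modelled as a concatenate of protein-coding genes with
#' no intergenic DNA.  Gene boundaries are laid down every `gene_length` bp
#' (the last gene absorbs the remainder, which is still a multiple of 3).
#'
#' @param seq Integer-coded root sequence; length a multiple of 3.
#' @param gene_length Nominal gene size in bp, a positive multiple of 3.
#' @return A [new_genome()] object whose gene ids are `g00001, g00002, ...`.
#' @export
partition_root_genome <- function(seq, gene_length = 999L) {
  L <- length(seq)
  if (L %% 3L != 0L) stop("root sequence length must be a multiple of 3", call. = FALSE)
  gene_length <- as.integer(gene_length)
  if (gene_length < 3L || gene_length %% 3L != 0L)
    stop("gene_length must be a positive multiple of 3", call. = FALSE)
  n_full <- L %/% gene_length
  rem <- L - n_full * gene_length
  if (n_full == 0L) {
    lens <- L
  } else {
    lens <- rep(gene_length, n_full)
    if (rem > 0L) lens[n_full] <- lens[n_full] + rem
  }
  new_genome(seq, sprintf("g%05d", seq_along(lens)), lens)
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", length(x$gene_id), " genes, ", length(x$seq), " bp\n", sep = "")
  invisible(x)
}
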