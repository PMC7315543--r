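#' Draw gene gain and loss counts for a branch segment
#'
#' Gains and losses are Poisson with means `gain_rate * l` and
#' `loss_rate * l`, i.e. proportional to branch length, with rates expressed
#' relative to the substitution rate like the recombination rate.
#'
#' @param gain_rate,loss_rate Non-negative rates per unit branch length.
#' @param l Branch overlap length within the segment (substitutions/site).
#' @return Integer vector `c(n_gains, n_losses)`.
#' @export
draw_flux_events <- function(gain_rate, loss_rate, l) {
  if (gain_rate < 0 || loss_rate < 0) stop("flux rates must be >= 0", call. = FALSE)
  c(rpois(1L, gain_rate * l), rpois(1L, loss_rate * l))
}

#' Gain a new gene by external horizontal transfer
#'
#' Gene gain models the acquisition of a sequence external to the simulated
#' dataset: a fresh gene id is minted, its sequence is generated de novo at
#' the configured GC content, and it is inserted at a uniformly random rank
#' in the genome's gene order.  Descendant lineages inherit the new gene.
#' This is distinct from homologous recombination, which only exchanges SNPs
#' among sequences already in the dataset.
#'
#' @param genome A [new_genome()]; modified in place.
#' @param gc GC content for the new sequence.
#' @param gene_length Length of the gained gene (positive multiple of 3).
#' @param gene_id Identifier for the new gene (minted by the caller so ids
#'   are globally unique across lineages).
#' @return Invisibly, the modified genome.
#' @export
gain_gene <- function(genome, gc, gene_length, gene_id) {
  gene_length <- as.integer(gene_length)
  if (gene_length < 3L || gene_length %% 3L != 0L)
    stop("gene_length must be a positive multiple of 3", call. = FALSE)
  if (gene_id %in% genome$gene_id)
    stop("gene id '", gene_id, "' already present", call. = FALSE)
  piece <- random_sequence(gene_length, gc)
  n <- length(genome$gene_id)
  rank <- sample.int(n + 1L, 1L) - 1L   # 0 = before first gene
  st <- genome_starts(genome)
  ins_at <- if (rank == 0L) 0L else st[rank] + genome$gene_len[rank] - 1L
  genome$seq <- append(genome$seq, piece, after = ins_at)
  genome$gene_id <- append(genome$gene_id, gene_id, after = rank)
  genome$gene_len <- append(genome$gene_len, gene_length, after = rank)
  invisible(genome)
}

#' Lose one gene
#'
#' Removes a uniformly chosen gene from the lineage; descendants inherit the
#' absence.  Whole genes only — fragments are never deleted.  Any current
#' gene is eligible: "core" is a property of the final dataset, not a
#' protection during simulation.
#'
#' @param genome A [new_genome()]; modified in place.
#' @return Invisibly, the id of the lost gene, or `NULL` if the genome was
#'   already empty (the skipped event is logged by the engine).
#' @export
lose_gene <- function(genome) {
  n <- length(genome$gene_id)
  if (n == 0L) return(invisible(NULL))
  i <- sample.int(n, 1L)
  gid <- genome$gene_id[i]
  .genome_drop_gene(genome, gid)
  invisible(gid)
}

#' Map a recipient tract onto homologous donor coordinates
#'
#' For each position of the tract (recipient coordinates), returns the
#' homologous donor position when the containing gene is shared between the
#' two genomes, `NA` when the gene is absent from the donor.  Also reports
#' the whole accessory genes eligible for transfer: donor-only genes fully
#' contained between the two breakpoint genes (insertion candidates) and
#' recipient-only genes fully contained between them (deletion candidates).
#' Candidates are only actionable when both breakpoints fall in shared genes
#' (`both_breakpoints_shared`).
#'
#' @param recipient,donor Genomes.
#' @param start 1-based tract start on the recipient concatenate.
#' @param len Tract length in bp.
#' @return List: `donor_pos` (integer vector, `NA` = absent), `insert_ids`,
#'   `delete_ids`, `start_gene`, `end_gene`, `both_breakpoints_shared`.
#' @export
homologous_interval <- function(recipient, donor, start, len) {
  sites <- start:(start + len - 1L)
  r_gene <- genome_gene_at(recipient, sites)
  r_starts <- genome_starts(recipient)
  d_starts <- genome_starts(donor)
  d_of_r <- match(recipient$gene_id, donor$gene_id)   # donor gene index or NA

  dg <- d_of_r[r_gene]
  donor_pos <- ifelse(is.na(dg), NA_integer_,
                      d_starts[dg] + (sites - r_starts[r_gene]))

  g1 <- r_gene[1L]; g2 <- r_gene[length(r_gene)]
  start_shared <- !is.na(d_of_r[g1])
  end_shared <- !is.na(d_of_r[g2])
  both <- start_shared && end_shared

  insert_ids <- character(0); delete_ids <- character(0)
  if (both && g2 > g1) {
    if (g2 - g1 > 1L) {
      between_r <- recipient$gene_id[(g1 + 1L):(g2 - 1L)]
      delete_ids <- between_r[is.na(match(between_r, donor$gene_id))]
    }
    d1 <- d_of_r[g1]; d2 <- d_of_r[g2]
    lo <- min(d1, d2); hi <- max(d1, d2)
    if (hi - lo > 1L) {
      between_d <- donor$gene_id[(lo + 1L):(hi - 1L)]
      insert_ids <- between_d[is.na(match(between_d, recipient$gene_id))]
    }
  }
  list(donor_pos = as.integer(donor_pos),
       insert_ids = insert_ids, delete_ids = delete_ids,
       start_gene = recipient$gene_id[g1], end_gene = recipient$gene_id[g2],
       both_breakpoints_shared = both)
}
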