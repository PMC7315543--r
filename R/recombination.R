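#' Draw a recombination tract on a linear genome
#'
#' The tract start is uniform along the recipient sequence and the raw length
#' is geometric with mean `delta` (support 1, 2, ..., success probability
#' `1/delta`).  Genomes are linear, so the tract is truncated at the right
#' end rather than wrapping or being redrawn; truncation slightly lowers the
#' realized mean tract length, which is reported in the run statistics.
#'
#' @param L Alignable sequence length (>= 1).
#' @param delta Mean tract length in bp (>= 1).
#' @return List with `start` (1-based), `length` (post-truncation) and
#'   `raw_length` (the untruncated geometric draw).
#' @examples
#' draw_tract(1000, delta = 100)
#' @export
draw_tract <- function(L, delta) {
  if (delta < 1) stop("delta (mean tract length) must be >= 1", call. = FALSE)
  if (L < 1) stop("sequence length must be >= 1", call. = FALSE)
  start <- sample.int(L, 1L)
  raw <- rgeom(1L, prob = 1 / delta) + 1L
  list(start = start, length = min(raw, L - start + 1L), raw_length = raw)
}

#' Divergence-dependent recombination acceptance probability
#'
#' The probability that a candidate homologous recombination event succeeds
#' declines log-linearly with donor-recipient sequence divergence:
#' `p = 10^(-pi * phi)`.  The default slope `phi = 18.1` is the value
#' experimentally inferred for *Streptococcus pneumoniae*, intermediate among
#' species with measured slopes.
#'
#' @param pi Per-site divergence of the candidate tract, in `[0, 1]`.
#' @param phi Non-negative slope of the log-linear relationship.
#' @return Acceptance probability in `[0, 1]`.
#' @examples
#' acceptance_probability(0.1, 18.1)  # 10^-1.81
#' @export
acceptance_probability <- function(pi, phi) {
  min(1, 10^(-pi * phi))
}

#' Bias model for divergence-dependent recombination
#'
#' @param enabled Whether the divergence bias is applied.
#' @param phi Slope of the log-linear divergence-acceptance relationship.
#' @return Class `"bias_model"` list.
#' @export
bias_model <- function(enabled = FALSE, phi = 18.1) {
  if (!is.numeric(phi) || phi < 0) stop("phi must be >= 0", call. = FALSE)
  structure(list(enabled = isTRUE(enabled), phi = phi), class = "bias_model")
}

#' Pick a recombination donor within a time segment
#'
#' The donor is drawn uniformly among the segment's lineages, excluding the
#' recipient (self-recombination is a no-op that would deflate the realized
#' SNP exchange).  With only one lineage alive the event cannot happen.
#'
#' @param members Identifiers of the lineages alive in the segment.
#' @param recipient The recipient's identifier.
#' @return A donor identifier, or `NULL` when no donor is available (the
#'   caller records the skipped attempt).
#' @export
pick_donor <- function(members, recipient) {
  others <- members[members != recipient]
  if (length(others) == 0L) return(NULL)
  others[sample.int(length(others), 1L)]
}

#' Apply one homologous recombination (gene conversion) event
#'
#' Non-reciprocal transfer: positions of the recipient tract whose containing
#' gene is shared with the donor are overwritten by the donor's homologous
#' bases; the donor is never modified.  If the divergence bias is enabled,
#' the per-site divergence `pi` of the homologous portion of the tract is
#' computed first and the event is *discarded* (no sequence change, recorded
#' with `accepted = FALSE`) with probability `1 - 10^(-pi*phi)`.
#'
#' Accessory-gene semantics: tract positions falling in genes absent from the
#' recipient are not transferred.  Only when *both* tract breakpoints lie
#' inside genes shared by donor and recipient are entire intervening
#' accessory genes inserted (donor-only genes) or deleted (recipient-only
#' genes), so recombination never introduces partial indels.
#'
#' @param recipient,donor Genomes ([new_genome()]); the recipient is modified
#'   in place when the event is accepted.
#' @param tract List with `start` and `length` on the recipient coordinate
#'   (see [draw_tract()]).
#' @param bias A [bias_model()].
#' @return A list event record: `start`, `length`, `hom_length` (homologous
#'   bp actually eligible), `snps` (positions changed), `pi`, `accepted`,
#'   `status` (`"ok"`, `"rejected_bias"` or `"no_homology"`), `genes_gained`,
#'   `genes_lost` (character vectors of whole accessory genes moved).
#' @export
apply_recombination <- function(recipient, donor, tract, bias = bias_model()) {
  start <- tract$start
  len <- tract$length
  sites <- start:(start + len - 1L)
  hom <- homologous_interval(recipient, donor, start, len)
  hom_idx <- which(!is.na(hom$donor_pos))
  rec <- list(start = start, length = len, hom_length = length(hom_idx),
              snps = 0L, pi = NA_real_, accepted = FALSE, status = "no_homology",
              genes_gained = character(0), genes_lost = character(0))
  if (length(hom_idx) == 0L) return(rec)

  r_sites <- sites[hom_idx]
  d_sites <- hom$donor_pos[hom_idx]
  diffs <- recipient$seq[r_sites] != donor$seq[d_sites]
  rec$pi <- mean(diffs)

  if (bias$enabled) {
    p <- acceptance_probability(rec$pi, bias$phi)
    if (runif(1L) > p) {
      rec$status <- "rejected_bias"
      return(rec)
    }
  }
  # transfer homologous bases (non-reciprocal)
  .seq_set(recipient, r_sites, donor$seq[d_sites])
  rec$snps <- sum(diffs)
  rec$accepted <- TRUE
  rec$status <- "ok"

  # whole-gene insertion/deletion only when both breakpoints are in shared genes
  if (isTRUE(hom$both_breakpoints_shared)) {
    for (gid in hom$delete_ids) .genome_drop_gene(recipient, gid)
    if (length(hom$insert_ids) > 0L)
      .genome_insert_genes(recipient, donor, hom$insert_ids, hom$start_gene)
    rec$genes_gained <- hom$insert_ids
    rec$genes_lost <- hom$delete_ids
  }
  rec
}

# remove one gene (id) from a genome in place
.genome_drop_gene <- function(g, gid) {
  i <- match(gid, g$gene_id)
  if (is.na(i)) return(invisible(g))
  st <- genome_starts(g)[i]
  g$seq <- g$seq[-(st:(st + g$gene_len[i] - 1L))]
  g$gene_id <- g$gene_id[-i]
  g$gene_len <- g$gene_len[-i]
  invisible(g)
}

# insert copies of donor genes (ids, donor order) right after gene `after_id`
# in the recipient's gene order
.genome_insert_genes <- function(g, donor, ids, after_id) {
  pos <- match(after_id, g$gene_id)
  if (is.na(pos)) pos <- length(g$gene_id)
  dstarts <- genome_starts(donor)
  for (gid in ids) {
    j <- match(gid, donor$gene_id)
    piece <- donor$seq[dstarts[j]:(dstarts[j] + donor$gene_len[j] - 1L)]
    st <- genome_starts(g)
    ins_at <- if (pos == 0L) 0L else st[pos] + g$gene_len[pos] - 1L
    g$seq <- append(g$seq, piece, after = ins_at)
    g$gene_id <- append(g$gene_id, gid, after = pos)
    g$gene_len <- append(g$gene_len, donor$gene_len[j], after = pos)
    pos <- pos + 1L
  }
  invisible(g)
}
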