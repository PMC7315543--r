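#' Aggregate simulation statistics: eta and the effective recombination rate
#'
#' `eta` is the per-site density of polymorphisms exchanged in accepted
#' recombination tracts: total SNPs exchanged divided by total recombined
#' (homologous) bp.  With this per-site reading, `eta * delta` is the mean
#' number of SNPs per event and the effective recombination rate follows the
#' relationship `r/m = rho * eta * delta`.  The direct count
#' `r/m = total SNPs exchanged / total mutations` is also reported and is the
#' authoritative value: tract truncation at sequence ends, skipped attempts
#' and bias rejection all make the realized rate differ slightly from the
#' formula.
#'
#' @param sim A `recomb_sim` result (or a list with `mutations`,
#'   `recombinations` and `config`).
#' @return A list of class `"sim_stats"`: counters (`n_mutations`,
#'   `n_recomb_attempts`, `n_recomb_accepted`, `n_recomb_skipped`,
#'   `total_recomb_bp`, `total_snps_exchanged`), `eta`, `eta_flag` (TRUE when
#'   no recombined bp were available and eta is reported as 0),
#'   `mean_snps_per_event`, `mean_tract_raw`, `mean_tract_realized`,
#'   `r_over_m_formula` and `r_over_m_direct`.
#' @export
finalize_stats <- function(sim) {
  mut <- sim$mutations
  rec <- sim$recombinations
  cfg <- sim$config
  n_mut <- nrow(mut)
  acc <- rec[!is.na(rec$accepted) & rec$accepted == 1, , drop = FALSE]
  attempts <- nrow(rec)
  n_acc <- nrow(acc)
  tot_bp <- if (n_acc > 0) sum(acc$hom_length) else 0
  tot_snps <- if (n_acc > 0) sum(acc$snps) else 0
  eta_flag <- tot_bp == 0
  eta <- if (eta_flag) 0 else tot_snps / tot_bp
  structure(list(
    n_mutations = n_mut,
    n_recomb_attempts = attempts,
    n_recomb_accepted = n_acc,
    n_recomb_skipped = sum(rec$status == "no_donor"),
    n_recomb_rejected_bias = sum(rec$status == "rejected_bias"),
    total_recomb_bp = tot_bp,
    total_snps_exchanged = tot_snps,
    eta = eta,
    eta_flag = eta_flag,
    mean_snps_per_event = if (n_acc > 0) tot_snps / n_acc else 0,
    mean_tract_raw = if (attempts > 0) mean(rec$raw_length, na.rm = TRUE) else NA_real_,
    mean_tract_realized = if (n_acc > 0) mean(acc$hom_length) else NA_real_,
    r_over_m_formula = if (eta_flag) 0 else cfg$rho * eta * cfg$delta,
    r_over_m_direct = if (n_mut > 0) tot_snps / n_mut else 0
  ), class = "sim_stats")
}

#' @export
print.sim_stats <- function(x, ...) {
  kv <- unclass(x)
  for (k in names(kv)) cat(sprintf("%-24s %s\n", k, format(kv[[k]], digits = 6)))
  invisible(x)
}

#' Parameter-recovery summary of a simulated alignment
#'
#' Computes the verification statistics used to check that the entered
#' parameters were simulated as expected: the realized GC content of the core
#' alignment, the fraction of segregating (polymorphic) core columns at each
#' codon position, the distribution of logged mutation events over codon
#' positions, and the transition/transversion split of the true event log
#' with the implied kappa estimate (`kappa_hat = 2 * transitions /
#' transversions`, the inverse of the per-event target-choice expectation
#' under K2P).
#'
#' @param sim A `recomb_sim` result with at least 2 leaf genomes.
#' @return A list: `gc`, `alignment_length`, `n_segregating`,
#'   `seg_fraction_by_pos` (length 3), `event_fraction_by_pos` (length 3),
#'   `n_transitions`, `n_transversions`, `kappa_hat`.
#' @export
measure_alignment <- function(sim) {
  aln <- core_alignment(sim)
  if (length(aln) < 2L) stop("need at least 2 leaf genomes", call. = FALSE)
  if (any(nchar(aln) == 0L)) stop("empty alignment", call. = FALSE)
  m <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gc <- mean(m == "G" | m == "C")
  ncol_a <- ncol(m)
  seg <- vapply(seq_len(ncol_a), function(j) length(unique(m[, j])) > 1L, logical(1))
  pos <- (seq_len(ncol_a) - 1L) %% 3L + 1L
  seg_frac <- vapply(1:3, function(k) {
    n <- sum(pos == k)
    if (n == 0L) NA_real_ else sum(seg[pos == k]) / n
  }, numeric(1))

  mut <- sim$mutations
  ev_frac <- if (nrow(mut) > 0) as.numeric(table(factor(mut$codon_pos, 1:3)) / nrow(mut))
             else rep(NA_real_, 3)
  is_ts <- abs(mut$old - mut$new) == 2   # A<->G, C<->T in the 1..4 coding
  n_ts <- sum(is_ts); n_tv <- sum(!is_ts)
  list(
    gc = gc,
    alignment_length = ncol_a,
    n_segregating = sum(seg),
    seg_fraction_by_pos = seg_frac,
    event_fraction_by_pos = ev_frac,
    n_transitions = n_ts,
    n_transversions = n_tv,
    kappa_hat = if (n_tv > 0) 2 * n_ts / n_tv else NA_real_
  )
}
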