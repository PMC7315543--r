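#' Read a root genome from a FASTA file
#'
#' The file must contain exactly one ACGT-only record whose length is a
#' multiple of 3.
#'
#' @param path FASTA file.
#' @return Integer-coded sequence (see [char_to_seq()]).
#' @export
read_root_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L)
    stop("root FASTA must contain exactly one record, found ", length(ss), call. = FALSE)
  char_to_seq(as.character(ss[[1L]]))
}

#' Write all simulation outputs to a directory
#'
#' Produces: `core_alignment.fasta` (one equal-length record per leaf, root
#' gene order, no gaps), `genomes/<leaf>.fasta` (full genome of each leaf,
#' one record per gene, accessory genes included), `presence_absence.tsv`
#' (rows = gene ids, columns = leaves, values 0/1), `mutations.tsv` and
#' `recombinations.tsv` (event logs; coordinates 0-based half-open on the
#' recipient's gene concatenate at event time, as stated in the header
#' comment), `stats.txt` (key-value summary) and `run_log.txt` (config echo,
#' seed, package version).
#'
#' @param sim A `recomb_sim` result.
#' @param dir Output directory (created if needed; must be writable).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  probe <- file.path(dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) }, warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", dir, call. = FALSE)
  unlink(probe)

  paths <- character(0)

  aln <- core_alignment(sim)
  p <- file.path(dir, "core_alignment.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln), p)
  paths <- c(paths, p)

  gdir <- file.path(dir, "genomes")
  dir.create(gdir, showWarnings = FALSE)
  for (leaf in names(sim$leaf_genomes)) {
    g <- sim$leaf_genomes[[leaf]]
    st <- genome_starts(g)
    recs <- vapply(seq_along(g$gene_id), function(i)
      seq_to_char(g$seq[st[i]:(st[i] + g$gene_len[i] - 1L)]), character(1))
    names(recs) <- g$gene_id
    p <- file.path(gdir, paste0(leaf, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(recs), p)
    paths <- c(paths, p)
  }

  pa <- presence_absence(sim)
  p <- file.path(dir, "presence_absence.tsv")
  write.table(data.frame(gene_id = rownames(pa), pa, check.names = FALSE),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  mut <- sim$mutations
  if (nrow(mut) > 0) {
    mut$site <- mut$site - 1                       # 0-based in the written log
    mut$old <- BASES[mut$old]; mut$new <- BASES[mut$new]
  }
  p <- file.path(dir, "mutations.tsv")
  con <- file(p, "w")
  writeLines("# sites are 0-based on the recipient gene concatenate at event time", con)
  write.table(mut, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paths <- c(paths, p)

  rec <- sim$recombinations
  if (nrow(rec) > 0) rec$start <- rec$start - 1
  p <- file.path(dir, "recombinations.tsv")
  con <- file(p, "w")
  writeLines("# start is 0-based, tracts half-open on the recipient gene concatenate at event time", con)
  write.table(rec, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  paths <- c(paths, p)

  p <- file.path(dir, "stats.txt")
  st <- unclass(sim$stats)
  writeLines(sprintf("%s\t%s", names(st),
                     vapply(st, function(v) format(v, digits = 12), character(1))), p)
  paths <- c(paths, p)

  cfg <- sim$config
  p <- file.path(dir, "run_log.txt")
  writeLines(c(
    paste0("recombsim version ", as.character(packageVersion("recombsim"))),
    paste0("seed = ", cfg$seed),
    paste0("L = ", cfg$L),
    paste0("gc = ", cfg$gc),
    paste0("model = ", cfg$model$name),
    paste0("model_params = ", paste(names(cfg$model$params),
           vapply(cfg$model$params, function(x) paste(x, collapse = ","), character(1)),
           sep = "=", collapse = "; ")),
    paste0("codon_rates = ", paste(format(unclass(cfg$profile), digits = 6), collapse = ",")),
    paste0("rho = ", cfg$rho),
    paste0("delta = ", cfg$delta),
    paste0("bias = ", cfg$bias$enabled, "; phi = ", cfg$bias$phi),
    paste0("gain_rate = ", cfg$gain_rate, "; loss_rate = ", cfg$loss_rate),
    paste0("scale = ", cfg$scale),
    paste0("gene_length = ", cfg$gene_length),
    paste0("leaves = ", length(sim$leaf_genomes))
  ), p)
  paths <- c(paths, p)
  invisible(paths)
}

#' Run a simulation from a control file
#'
#' Thin driver used by the command-line entry point: parses the control file,
#' runs [simulate_genomes()] and, when an output directory is configured (or
#' given), writes all outputs.
#'
#' @param control_path Path to a control file (see [parse_control()]).
#' @param output_dir Optional override of the control file's `output_dir`.
#' @param seed Optional override of the control file's `seed`.
#' @return The `recomb_sim` result, invisibly.
#' @export
run_simulation <- function(control_path, output_dir = NULL, seed = NULL) {
  ctl <- parse_control(control_path)
  cfg <- ctl$config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir <- if (!is.null(output_dir)) output_dir else ctl$output_dir
  if (!is.null(dir)) {
    # fail on an unwritable destination before doing any simulation work
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  sim <- simulate_genomes(cfg)
  if (!is.null(dir)) write_outputs(sim, dir)
  invisible(sim)
}
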