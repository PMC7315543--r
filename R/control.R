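#' Parse a plain-text control file into a simulation configuration
#'
#' The control file carries one `key = value` pair per line; blank lines and
#' `#` comments are ignored.  Unknown keys are rejected with the offending
#' line number, as are unparseable values.  Recognised keys:
#'
#' \tabular{lll}{
#'   `tree` \tab path to a Newick file \tab required \cr
#'   `rho` \tab relative recombination rate \tab required \cr
#'   `L` \tab root genome length (bp) \tab required unless `root_fasta` \cr
#'   `gc` \tab GC content \tab default 0.5 \cr
#'   `root_fasta` \tab single-record ACGT FASTA for the root \tab optional \cr
#'   `model` \tab JC69 / K2P / K3P / GTR \tab default JC69 \cr
#'   `kappa` \tab K2P transition/transversion ratio \tab required for K2P \cr
#'   `kappa1`, `kappa2` \tab K3P parameters \tab required for K3P \cr
#'   `gtr_rates` \tab six comma-separated rates (AC,AG,AT,CG,CT,GT) \tab required for GTR \cr
#'   `gtr_freqs` \tab four comma-separated equilibrium frequencies (A,C,G,T) \tab optional \cr
#'   `codon_rates` \tab three comma-separated relative rates \tab default 1,1,1 \cr
#'   `delta` \tab mean recombination tract length (bp) \tab default 100 \cr
#'   `bias` \tab on/off divergence-dependent acceptance \tab default off \cr
#'   `phi` \tab bias slope \tab default 18.1 \cr
#'   `gain_rate`, `loss_rate` \tab gene flux rates \tab default 0 \cr
#'   `scale` \tab tree rescaling coefficient \tab default 1.0 \cr
#'   `seed` \tab RNG seed \tab default 1 \cr
#'   `gene_length` \tab root/gained gene size (bp) \tab default 999 \cr
#'   `output_dir` \tab where [write_outputs()] puts results \tab optional \cr
#' }
#'
#' @param path Path to the control file.
#' @return A list with `$config` (a validated [sim_config()]) and
#'   `$output_dir` (possibly `NULL`).
#' @export
parse_control <- function(path) {
  if (!file.exists(path)) stop("control file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  known <- c("tree", "root_fasta", "L", "gc", "model", "kappa", "kappa1",
             "kappa2", "gtr_rates", "gtr_freqs", "codon_rates", "rho", "delta",
             "bias", "phi", "gain_rate", "loss_rate", "scale", "seed",
             "gene_length", "output_dir")
  kv <- list(); kline <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (!grepl("=", ln, fixed = TRUE))
      stop("line ", i, ": expected 'key = value', got '", lines[i], "'", call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!(key %in% known))
      stop("line ", i, ": unknown parameter '", key, "'", call. = FALSE)
    if (key %in% names(kv))
      stop("line ", i, ": duplicate parameter '", key, "'", call. = FALSE)
    kv[[key]] <- val
    kline[[key]] <- i
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    x <- suppressWarnings(as.numeric(strsplit(kv[[key]], ",", fixed = TRUE)[[1]]))
    if (anyNA(x))
      stop("line ", kline[[key]], ": '", key, "' is not numeric: ", kv[[key]], call. = FALSE)
    x
  }
  flag <- function(key, default = FALSE) {
    if (is.null(kv[[key]])) return(default)
    v <- tolower(kv[[key]])
    if (v %in% c("on", "true", "yes", "1")) return(TRUE)
    if (v %in% c("off", "false", "no", "0")) return(FALSE)
    stop("line ", kline[[key]], ": '", key, "' must be on/off", call. = FALSE)
  }
  if (is.null(kv$tree)) stop("missing required parameter 'tree'", call. = FALSE)
  if (!file.exists(kv$tree))
    stop("line ", kline$tree, ": tree file not found: ", kv$tree, call. = FALSE)
  if (is.null(kv$rho)) stop("missing required parameter 'rho'", call. = FALSE)
  if (is.null(kv$root_fasta) && is.null(kv$L))
    stop("missing required parameter 'L' (or provide root_fasta)", call. = FALSE)

  model <- if (is.null(kv$model)) "JC69" else toupper(kv$model)
  params <- list()
  if (model == "K2P") {
    if (is.null(kv$kappa)) stop("model K2P requires 'kappa'", call. = FALSE)
    params$kappa <- num("kappa")
  } else if (model == "K3P") {
    if (is.null(kv$kappa1) || is.null(kv$kappa2))
      stop("model K3P requires 'kappa1' and 'kappa2'", call. = FALSE)
    params$kappa1 <- num("kappa1"); params$kappa2 <- num("kappa2")
  } else if (model == "GTR") {
    if (is.null(kv$gtr_rates))
      stop("model GTR requires 'gtr_rates' (six comma-separated exchangeabilities)",
           call. = FALSE)
    params$rates <- num("gtr_rates")
    if (!is.null(kv$gtr_freqs)) params$freqs <- num("gtr_freqs")
  }

  L <- num("L")
  if (!is.null(L) && is.null(kv$root_fasta) && L %% 3 != 0)
    stop("line ", kline$L, ": L must be a multiple of 3", call. = FALSE)

  cfg <- sim_config(
    tree = kv$tree,
    L = if (is.null(L)) 30000L else as.integer(L),
    gc = num("gc", 0.5),
    model = model, model_params = params,
    codon_rates = num("codon_rates", c(1, 1, 1)),
    rho = num("rho"),
    delta = num("delta", 100),
    bias = flag("bias", FALSE),
    phi = num("phi", 18.1),
    gain_rate = num("gain_rate", 0),
    loss_rate = num("loss_rate", 0),
    scale = num("scale", 1),
    seed = num("seed", 1),
    gene_length = num("gene_length", 999),
    root_seq = kv$root_fasta
  )
  list(config = cfg, output_dir = kv$output_dir)
}
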