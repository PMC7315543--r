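#' Simulation configuration
#'
#' Collects and validates all simulation parameters.  Branch lengths of the
#' input tree are interpreted as expected substitutions per site, so the
#' expected number of mutations on a branch of length `l` is `l * L` for a
#' genome of `L` bp.  The recombination rate `rho` is defined relative to the
#' substitution rate: the expected number of recombination *attempts* on a
#' branch segment is `rho` times the expected number of mutations.
#'
#' @param tree A `sim_tree`, a Newick string, or a path to a Newick file.
#' @param L Root core genome length in bp (multiple of 3).  Ignored when
#'   `root_seq` is given.
#' @param gc GC content for the root sequence and for gained genes.
#' @param model Substitution model name (`"JC69"`, `"K2P"`, `"K3P"`,
#'   `"GTR"`) or a prebuilt [build_model()] object.
#' @param model_params Named list of model parameters (see [build_model()]).
#' @param codon_rates Relative substitution rates of codon positions 1-3.
#' @param rho Recombination rate relative to the substitution rate (>= 0).
#' @param delta Mean recombination tract length in bp (>= 1).
#' @param bias Enable divergence-dependent recombination acceptance.
#' @param phi Slope of the log-linear divergence bias (default 18.1).
#' @param gain_rate,loss_rate Gene gain/loss rates per unit branch length.
#' @param scale Tree rescaling coefficient (> 0).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @param gene_length Nominal gene size used to partition the root genome and
#'   for gained genes (positive multiple of 3).
#' @param root_seq Optional root sequence: an integer-coded vector, an ACGT
#'   string, or a path to a single-record FASTA file.  Must be ACGT-only with
#'   length a multiple of 3.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(tree, L = 30000L, gc = 0.5,
                       model = "JC69", model_params = list(),
                       codon_rates = c(1, 1, 1),
                       rho = 0, delta = 100,
                       bias = FALSE, phi = 18.1,
                       gain_rate = 0, loss_rate = 0,
                       scale = 1, seed = 1L,
                       gene_length = 999L, root_seq = NULL) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) parse_newick(path = tree) else parse_newick(tree)
  }
  if (!inherits(tree, "sim_tree")) stop("tree must be a sim_tree, Newick string or file", call. = FALSE)
  if (!is.numeric(rho) || rho < 0) stop("rho must be >= 0", call. = FALSE)
  if (rho > 0 && delta < 1) stop("delta must be >= 1 when rho > 0", call. = FALSE)
  if (scale <= 0) stop("scale must be > 0", call. = FALSE)
  if (gain_rate < 0 || loss_rate < 0) stop("flux rates must be >= 0", call. = FALSE)
  if (!is.null(root_seq)) {
    if (is.character(root_seq) && length(root_seq) == 1L && file.exists(root_seq))
      root_seq <- read_root_fasta(root_seq)
    else if (is.character(root_seq)) root_seq <- char_to_seq(root_seq)
    if (length(root_seq) %% 3L != 0L)
      stop("root sequence length must be a multiple of 3", call. = FALSE)
    L <- length(root_seq)
  } else {
    if (L %% 3L != 0L) stop("L must be a multiple of 3", call. = FALSE)
    if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]", call. = FALSE)
  }
  if (!inherits(model, "subst_model")) model <- build_model(model, model_params, gc = gc)
  structure(list(
    tree = tree, L = as.integer(L), gc = gc, model = model,
    profile = codon_profile(codon_rates), rho = rho, delta = delta,
    bias = bias_model(bias, phi), gain_rate = gain_rate, loss_rate = loss_rate,
    scale = scale, seed = as.integer(seed), gene_length = as.integer(gene_length),
    root_seq = root_seq
  ), class = "sim_config")
}

#' Draw the per-branch event budget for one time segment
#'
#' Mutations: `M_t ~ Poisson(l * L_current)`.  Recombination attempts:
#' `R_t ~ Poisson(rho * l * L_current)`, i.e. attempts arrive at `rho` times
#' the substitution rate.
#'
#' @param l Branch overlap length in the segment (substitutions/site).
#' @param L_current Current alignable genome length of the lineage (bp).
#' @param rho Relative recombination rate.
#' @return Integer vector `c(M, R)`.
#' @export
draw_budget <- function(l, L_current, rho) {
  c(rpois(1L, l * L_current), rpois(1L, rho * l * L_current))
}

# growable event-log accumulator; rows are written in place inside the
# accumulator environment (writing through `$` would copy the whole matrix
# on every event)
.new_log <- function(ncol, nms) {
  e <- new.env(parent = baseenv())
  e$m <- matrix(NA_real_, nrow = 1024L, ncol = ncol, dimnames = list(NULL, nms))
  e$n <- 0L
  e
}
.log_push <- function(e, row) {
  if (e$n == nrow(e$m)) {
    m2 <- matrix(NA_real_, nrow = 2L * nrow(e$m), ncol = ncol(e$m),
                 dimnames = dimnames(e$m))
    m2[seq_len(e$n), ] <- e$m[seq_len(e$n), ]
    e$m <- m2
  }
  e$n <- e$n + 1L
  e$.row <- row
  evalq(m[n, ] <- .row, e)
  invisible(e)
}
.log_df <- function(e) as.data.frame(e$m[seq_len(e$n), , drop = FALSE])

#' Run a forward-in-time genome simulation
#'
#' Evolves a root genome along the (rescaled) input phylogeny.  Time segments
#' are processed in depth order; within each segment every living branch
#' receives Poisson mutation and recombination budgets, and the events are
#' then introduced in random interleaved order across the co-existing
#' lineages so that all sequences of a segment evolve simultaneously.
#' At internal nodes the parent genome is copied verbatim to each child
#' lineage.  Only lineages alive in the same segment can exchange sequence;
#' recombination with ancestral or already-terminated lineages never occurs.
#'
#' @param config A [sim_config()].
#' @return An object of class `"recomb_sim"`: a list with `leaf_genomes`
#'   (named list of genomes), `tree` (the rescaled `sim_tree`), `mutations`,
#'   `recombinations` and `flux` event tables, `budgets` (the per-segment
#'   Poisson draws, for auditing conservation), `gene_order` (canonical gene
#'   order for alignments), `stats` (see [finalize_stats()]) and `config`.
#' @examples
#' cfg <- sim_config("(A:0.01,B:0.01);", L = 3000, rho = 0, seed = 42)
#' sim <- simulate_genomes(cfg)
#' sim$stats$n_mutations
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- rescale_tree(config$tree, config$scale)
  edges <- tree$edges

  root_raw <- if (!is.null(config$root_seq)) as.integer(config$root_seq)
              else random_sequence(config$L, config$gc)
  root_genome <- partition_root_genome(root_raw, config$gene_length)
  gene_order <- root_genome$gene_id
  hgt_counter <- 0L

  segs <- time_segments(tree)
  phy <- tree$phy
  n_tip <- tree$n_leaves
  root_node <- n_tip + 1L

  # preorder over nodes (parents before children, stable for zero-length edges)
  kids <- split(seq_len(nrow(edges)), edges$parent)
  preorder <- integer(0)
  stack <- root_node
  while (length(stack) > 0L) {
    nd <- stack[1L]; stack <- stack[-1L]
    preorder <- c(preorder, nd)
    rows <- kids[[as.character(nd)]]
    if (!is.null(rows)) stack <- c(edges$child[rows], stack)
  }
  node_depth <- tree$node_depth

  edge_gen <- new.env(parent = emptyenv())
  leaf_genomes <- list()
  mut_log <- .new_log(6L, c("segment", "edge_id", "site", "old", "new", "codon_pos"))
  rec_log <- .new_log(12L, c("segment", "recipient", "donor", "start", "length",
                             "raw_length", "hom_length", "snps", "pi", "accepted",
                             "status", "n_gene_moves"))
  budget_log <- .new_log(6L, c("segment", "edge_id", "l", "L_current", "M", "R"))
  flux_rows <- list()

  arrive <- function(nd, genome) {
    rows <- kids[[as.character(nd)]]
    if (nd <= n_tip) {
      leaf_genomes[[phy$tip.label[nd]]] <<- genome
    } else {
      for (r in rows) {
        key <- as.character(edges$edge_id[r])
        assign(key, genome_clone(genome), envir = edge_gen)
      }
    }
  }

  incoming_edge_of <- function(nd) {
    r <- which(edges$child == nd)
    if (length(r) == 0L) NA_integer_ else r[1L]
  }

  processed <- rep(FALSE, length(preorder))
  tol <- 1e-9
  process_arrivals_upto <- function(depth_cut) {
    for (k in seq_along(preorder)) {
      if (processed[k]) next
      nd <- preorder[k]
      if (node_depth[nd] <= depth_cut + tol) {
        g <- if (nd == root_node && tree$root_edge == 0) {
          root_genome
        } else if (nd == root_node && tree$root_edge > 0) {
          get("0", envir = edge_gen)
        } else {
          get(as.character(edges$edge_id[incoming_edge_of(nd)]), envir = edge_gen)
        }
        arrive(nd, g)
        processed[k] <<- TRUE
      }
    }
  }
  # seed the root edge lineage, if any
  if (tree$root_edge > 0) assign("0", genome_clone(root_genome), envir = edge_gen)

  status_code <- c(ok = 0, rejected_bias = 1, no_homology = 2, no_donor = 3)

  for (si in seq_along(segs)) {
    seg <- segs[[si]]
    process_arrivals_upto(seg$start)
    keys <- as.character(seg$edge_id)
    nm <- length(keys)

    # gene flux first, so budgets see the post-flux genome length
    if (config$gain_rate > 0 || config$loss_rate > 0) {
      for (j in seq_len(nm)) {
        g <- get(keys[j], envir = edge_gen)
        fl <- draw_flux_events(config$gain_rate, config$loss_rate, seg$l[j])
        ops <- c(rep("gain", fl[1L]), rep("loss", fl[2L]))
        if (length(ops) > 1L) ops <- ops[sample.int(length(ops))]
        for (op in ops) {
          if (op == "gain") {
            hgt_counter <- hgt_counter + 1L
            gid <- sprintf("h%05d", hgt_counter)
            gain_gene(g, config$gc, config$gene_length, gid)
            gene_order <- c(gene_order, gid)
            flux_rows[[length(flux_rows) + 1L]] <-
              data.frame(segment = si, edge_id = seg$edge_id[j], type = "gain",
                         gene_id = gid, stringsAsFactors = FALSE)
          } else {
            gid <- lose_gene(g)
            flux_rows[[length(flux_rows) + 1L]] <-
              data.frame(segment = si, edge_id = seg$edge_id[j],
                         type = if (is.null(gid)) "loss_skipped" else "loss",
                         gene_id = if (is.null(gid)) NA_character_ else gid,
                         stringsAsFactors = FALSE)
          }
        }
      }
    }

    # Poisson budgets per member branch
    M <- integer(nm); R <- integer(nm)
    for (j in seq_len(nm)) {
      Lcur <- genome_nbp(get(keys[j], envir = edge_gen))
      b <- draw_budget(seg$l[j], Lcur, config$rho)
      M[j] <- b[1L]; R[j] <- b[2L]
      .log_push(budget_log, c(si, seg$edge_id[j], seg$l[j], Lcur, b[1L], b[2L]))
    }

    # random interleaving across lineages until all budgets are spent
    while (TRUE) {
      act <- which(M + R > 0L)
      if (length(act) == 0L) break
      j <- act[sample.int(length(act), 1L)]
      g <- get(keys[j], envir = edge_gen)
      if (runif(1L) * (M[j] + R[j]) < M[j]) {
        site <- draw_site(config$profile, genome_nbp(g))
        ev <- apply_mutation(g, site, config$model)
        .log_push(mut_log, c(si, seg$edge_id[j], site, ev$old, ev$new, ev$codon_pos))
        M[j] <- M[j] - 1L
      } else {
        donor_key <- pick_donor(keys, keys[j])
        if (is.null(donor_key)) {
          .log_push(rec_log, c(si, seg$edge_id[j], NA, NA, NA, NA, 0, 0, NA, 0,
                               status_code[["no_donor"]], 0))
        } else {
          dg <- get(donor_key, envir = edge_gen)
          tract <- draw_tract(genome_nbp(g), config$delta)
          ev <- apply_recombination(g, dg, tract, config$bias)
          .log_push(rec_log, c(si, seg$edge_id[j], as.numeric(donor_key),
                               ev$start, ev$length, tract$raw_length,
                               ev$hom_length, ev$snps, ev$pi,
                               as.numeric(ev$accepted), status_code[[ev$status]],
                               length(ev$genes_gained) + length(ev$genes_lost)))
        }
        R[j] <- R[j] - 1L
      }
    }
  }
  process_arrivals_upto(tree$max_depth)

  mutations <- .log_df(mut_log)
  recombinations <- .log_df(rec_log)
  recombinations$status <- names(status_code)[recombinations$status + 1]
  flux <- if (length(flux_rows) > 0L) do.call(rbind, flux_rows) else
    data.frame(segment = integer(0), edge_id = integer(0),
               type = character(0), gene_id = character(0))

  out <- structure(list(
    leaf_genomes = leaf_genomes[phy$tip.label],
    tree = tree, mutations = mutations, recombinations = recombinations,
    flux = flux, budgets = .log_df(budget_log),
    gene_order = gene_order, config = config
  ), class = "recomb_sim")
  out$stats <- finalize_stats(out)
  out
}

#' @export
print.recomb_sim <- function(x, ...) {
  cat("<recomb_sim> ", length(x$leaf_genomes), " leaf genomes, ",
      x$stats$n_mutations, " mutations, ",
      x$stats$n_recomb_accepted, "/", x$stats$n_recomb_attempts,
      " recombination events accepted\n", sep = "")
  cat("  r/m (direct) = ", format(x$stats$r_over_m_direct, digits = 4),
      "; r/m (rho.eta.delta) = ", format(x$stats$r_over_m_formula, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Core and per-leaf sequences of a finished simulation
#'
#' The core alignment contains the genes present in every leaf genome,
#' concatenated in canonical order (root gene order, then gained genes in
#' order of appearance).  Because genes are gained and lost only whole, core
#' columns exist in every leaf and the alignment has no gaps.
#'
#' @param sim A `recomb_sim` result.
#' @return A named character vector (one ACGT string per leaf).
#' @export
core_alignment <- function(sim) {
  leaves <- sim$leaf_genomes
  core_ids <- sim$gene_order[vapply(sim$gene_order, function(gid)
    all(vapply(leaves, function(g) gid %in% g$gene_id, logical(1))), logical(1))]
  vapply(leaves, function(g) {
    st <- genome_starts(g)
    idx <- unlist(lapply(core_ids, function(gid) {
      i <- match(gid, g$gene_id)
      st[i]:(st[i] + g$gene_len[i] - 1L)
    }), use.names = FALSE)
    seq_to_char(g$seq[idx])
  }, character(1))
}

#' Gene presence/absence matrix of a finished simulation
#'
#' @param sim A `recomb_sim` result.
#' @return A 0/1 integer matrix, rows = gene ids (canonical order), columns =
#'   leaves.
#' @export
presence_absence <- function(sim) {
  leaves <- sim$leaf_genomes
  m <- vapply(leaves, function(g) as.integer(sim$gene_order %in% g$gene_id),
              integer(length(sim$gene_order)))
  m <- matrix(m, nrow = length(sim$gene_order),
              dimnames = list(sim$gene_order, names(leaves)))
  m
}
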