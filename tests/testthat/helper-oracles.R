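# Independent oracles and shared fixtures.  These deliberately avoid the
# package's own code paths so they can validate them.

# Brute-force two-lineage evolution: a shared root sequence accumulates
# Poisson(d*L) uniform JC69 hits independently on each of two branches;
# returns the pairwise difference count.  Site choice, target choice and the
# hit count are all written directly against base R.
oracle_two_lineage_diffs <- function(L, d, gc = 0.5) {
  root <- sample.int(4L, L, replace = TRUE,
                     prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  evolve <- function(s) {
    n <- rpois(1L, d * L)
    for (k in seq_len(n)) {
      i <- sample.int(L, 1L)
      alt <- (1:4)[-s[i]]
      s[i] <- alt[sample.int(3L, 1L)]
    }
    s
  }
  sum(evolve(root) != evolve(root))
}

# Hand-built conditional substitution rows, enumerated per origin base with
# explicit transition partners, for checking build_model().
oracle_model_row <- function(model, origin, params, gc = 0.5) {
  bases <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  ring_partner <- c(A = "T", C = "G", G = "C", T = "A")
  targets <- setdiff(bases, origin)
  w <- vapply(targets, function(t) {
    if (model == "JC69") return(1)
    if (model == "K2P") return(if (t == ts_partner[origin]) params$kappa else 1)
    if (model == "K3P") {
      if (t == ts_partner[origin]) return(params$kappa1)
      if (t == ring_partner[origin]) return(params$kappa2)
      return(1)
    }
    if (model == "GTR") {
      pair <- paste(sort(c(origin, t)), collapse = "")
      r <- c(AC = params$rates[1], AG = params$rates[2], AT = params$rates[3],
             CG = params$rates[4], CT = params$rates[5], GT = params$rates[6])[pair]
      f <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)[t]
      return(r * f)
    }
    stop("unknown model in oracle")
  }, numeric(1))
  setNames(w / sum(w), targets)
}

# A genome pair with identical gene repertoire and an exact per-site
# divergence: `frac * L` evenly spaced sites differ.
make_diverged_pair <- function(L, frac, gene_length = L) {
  s <- rep(1:4, length.out = L)
  a <- partition_root_genome(s, gene_length)
  s2 <- s
  k <- round(frac * L)
  if (k > 0) {
    idx <- seq(1L, L, length.out = k)
    idx <- unique(as.integer(idx))
    s2[idx] <- s2[idx] %% 4L + 1L   # always a different base
  }
  b <- partition_root_genome(s2, gene_length)
  list(a = a, b = b, n_diff = sum(s != s2))
}

# fixed trees used across tests
tree2 <- function(d = 0.005) sprintf("(A:%g,B:%g);", d, d)
tree4 <- "((A:0.3,B:0.3):0.1,(C:0.3,D:0.3):0.1);"
tree8 <- paste0("(((A:0.02,B:0.02):0.02,(C:0.02,D:0.02):0.02):0.01,",
                "((E:0.02,F:0.02):0.02,(G:0.02,H:0.02):0.02):0.01);")
tree10 <- paste0("((A:0.04,(B:0.03,C:0.03):0.01):0.02,",
                 "((D:0.03,(E:0.02,F:0.02):0.01):0.02,",
                 "((G:0.02,H:0.02):0.02,(I:0.02,J:0.02):0.02):0.01):0.01);")

# member set of a tree at an arbitrary interior depth, straight off the edge
# table (oracle for segment membership)
members_at_depth <- function(tree, p) {
  sort(tree$edges$edge_id[tree$edges$pdepth <= p & tree$edges$cdepth > p])
}
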