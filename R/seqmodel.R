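#' Generate a random root sequence
#'
#' Each position is independently G or C with probability `gc` (split evenly
#' between G and C) and A or T otherwise (split evenly).
#'
#' @param L Sequence length in bp, at least 3 (one codon).
#' @param gc Target GC content in `[0, 1]`.
#' @return Integer-coded sequence of length `L` (see [char_to_seq()]).
#' @examples
#' s <- random_sequence(300, gc = 0.5)
#' mean(s == 2L | s == 3L)  # realized GC fraction
#' @export
random_sequence <- function(L, gc) {
  if (!is.numeric(L) || length(L) != 1L || L < 3)
    stop("L must be a single integer >= 3 (a sequence must hold a codon)", call. = FALSE)
  if (!is.numeric(gc) || gc < 0 || gc > 1)
    stop("gc must lie in [0, 1]", call. = FALSE)
  L <- as.integer(L)
  # P(A) = P(T) = (1-gc)/2, P(C) = P(G) = gc/2
  sample.int(4L, L, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Build a nucleotide substitution model
#'
#' Constructs the per-event conditional substitution distribution: given that
#' a substitution occurs at a site, the probability of each of the three
#' alternative bases.  The event *count* is governed separately by the
#' branch-length Poisson process, so only this conditional target choice is
#' needed.
#'
#' Supported models and their parameters:
#' \describe{
#'   \item{JC69}{no parameters; all three targets equiprobable.}
#'   \item{K2P}{`kappa`: transition/transversion ratio; the transition target
#'     gets weight `kappa`, each transversion target weight 1.}
#'   \item{K3P}{`kappa1` (transitions) and `kappa2` (transversions within the
#'     same complementary pair, A<->T and C<->G); the remaining transversions
#'     (A<->C, G<->T) get weight 1.}
#'   \item{GTR}{`rates`: six exchangeabilities named in the order
#'     AC, AG, AT, CG, CT, GT; target weight is exchangeability times the
#'     equilibrium frequency of the target.  Equilibrium frequencies default
#'     to `(gc/2, gc/2)` for G and C and `((1-gc)/2, (1-gc)/2)` for A and T,
#'     overridable via `freqs` (order A, C, G, T).}
#' }
#'
#' @param name Model name: `"JC69"`, `"K2P"`, `"K3P"` or `"GTR"`.
#' @param params Named list of model parameters (see Details).
#' @param gc GC content used for GTR equilibrium frequencies.
#' @return An object of class `"subst_model"` with elements `name`, `params`
#'   and `weights`, a 4x4 row-stochastic matrix (rows = origin base A,C,G,T;
#'   columns = target; diagonal 0).
#' @examples
#' m <- build_model("K2P", list(kappa = 1.6))
#' m$weights["A", ]  # transition A->G gets 1.6/3.6
#' @export
build_model <- function(name, params = list(), gc = 0.5) {
  name <- toupper(name)
  w <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  ts_pairs <- rbind(c(1L, 3L), c(3L, 1L), c(2L, 4L), c(4L, 2L))   # A<->G, C<->T
  ring_tv  <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L))   # A<->T, C<->G
  chk_pos <- function(x, what) {
    if (is.null(x)) stop("model ", name, " requires parameter '", what, "'", call. = FALSE)
    if (!is.numeric(x) || any(x < 0)) stop("parameter '", what, "' must be non-negative", call. = FALSE)
    x
  }
  if (name == "JC69") {
    w[] <- 1
  } else if (name == "K2P") {
    kappa <- chk_pos(params$kappa, "kappa")
    w[] <- 1
    w[ts_pairs] <- kappa
  } else if (name == "K3P") {
    kappa1 <- chk_pos(params$kappa1, "kappa1")
    kappa2 <- chk_pos(params$kappa2, "kappa2")
    w[] <- 1
    w[ts_pairs] <- kappa1
    w[ring_tv] <- kappa2
  } else if (name == "GTR") {
    r <- chk_pos(params$rates, "rates (six exchangeabilities: AC, AG, AT, CG, CT, GT)")
    if (length(r) != 6L)
      stop("GTR requires exactly six exchangeability rates (AC, AG, AT, CG, CT, GT)", call. = FALSE)
    freqs <- params$freqs
    if (is.null(freqs)) freqs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    if (length(freqs) != 4L || any(freqs < 0))
      stop("GTR freqs must be four non-negative values (A, C, G, T)", call. = FALSE)
    freqs <- freqs / sum(freqs)
    ex <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    ex[1, 2] <- ex[2, 1] <- r[1]  # AC
    ex[1, 3] <- ex[3, 1] <- r[2]  # AG
    ex[1, 4] <- ex[4, 1] <- r[3]  # AT
    ex[2, 3] <- ex[3, 2] <- r[4]  # CG
    ex[2, 4] <- ex[4, 2] <- r[5]  # CT
    ex[3, 4] <- ex[4, 3] <- r[6]  # GT
    w <- ex * rep(freqs, each = 4)
  } else {
    stop("unknown substitution model '", name,
         "'; choose one of JC69, K2P, K3P, GTR", call. = FALSE)
  }
  diag(w) <- 0
  rs <- rowSums(w)
  if (any(rs <= 0)) stop("model has an origin base with no possible target", call. = FALSE)
  w <- w / rs
  structure(list(name = name, params = params, weights = w),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> ", x$name, "\n", sep = "")
  print(round(x$weights, 4))
  invisible(x)
}

#' Codon-position rate profile
#'
#' Relative substitution rates of the three codon positions, renormalized to
#' sum to 1.  The profile redistributes where substitutions land; the total
#' number of substitutions stays fixed by the branch-length Poisson draw, so
#' the overall rate imposed by the tree is unchanged.
#'
#' @param weights Three non-negative reals (positions 1, 2, 3).
#' @return Class `"codon_profile"`: the normalized weights.
#' @export
codon_profile <- function(weights = c(1, 1, 1)) {
  if (length(weights) != 3L || !is.numeric(weights) || any(weights < 0))
    stop("codon profile needs three non-negative weights", call. = FALSE)
  if (sum(weights) <= 0) stop("all codon-position weights are zero", call. = FALSE)
  structure(weights / sum(weights), class = "codon_profile")
}

#' Draw a substitution site under a codon-position profile
#'
#' Picks a codon position class with probability proportional to the profile
#' weights, then a site uniformly within that class.
#'
#' @param profile A [codon_profile()].
#' @param L Sequence length, a positive multiple of 3.
#' @return A 1-based site index in `1..L`.
#' @export
draw_site <- function(profile, L) {
  if (L %% 3L != 0L) stop("sequence length must be divisible by 3", call. = FALSE)
  k <- sample.int(3L, 1L, prob = unclass(profile))
  3L * (sample.int(L %/% 3L, 1L) - 1L) + k
}

#' Apply one substitution event at a site
#'
#' Replaces the base at `site` by one of the three alternatives drawn from the
#' model's conditional weights for the current base.  The substitution is
#' always a real change.  The genome is modified in place (reference
#' semantics).
#'
#' @param genome A [new_genome()] object.
#' @param site 1-based site index.
#' @param model A [build_model()] object.
#' @return Invisibly, a list describing the event: `site`, `old`, `new`
#'   (integer base codes) and `codon_pos` (1, 2 or 3).
#' @export
apply_mutation <- function(genome, site, model) {
  old <- genome$seq[site]
  if (is.na(old) || old < 1L || old > 4L)
    stop("non-ACGT base at site ", site, call. = FALSE)
  new <- sample.int(4L, 1L, prob = model$weights[old, ])
  .seq_set(genome, site, new)
  invisible(list(site = site, old = old, new = new,
                 codon_pos = (site - 1L) %% 3L + 1L))
}
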