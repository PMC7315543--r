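test_that("tract draws are geometric with mean delta and stay on the genome", {
  set.seed(1)
  # degenerate geometric: every raw draw is exactly 1
  expect_true(all(replicate(50, draw_tract(100, 1)$raw_length) == 1L))

  raws <- replicate(1e5, draw_tract(1e6, 100)$raw_length)
  se <- sqrt(100 * 99 / 1e5)         # geometric sd = sqrt(delta*(delta-1))
  expect_lt(abs(mean(raws) - 100), 4 * se)

  # linear genome: truncation keeps tracts inside [1, L]
  for (k in 1:200) {
    tr <- draw_tract(50, 30)
    expect_gte(tr$start, 1L)
    expect_lte(tr$start + tr$length - 1L, 50L)
    expect_gte(tr$length, 1L)
  }
  expect_error(draw_tract(100, 0.5), "delta")
})

test_that("divergence bias probability follows p = 10^(-pi * phi)", {
  expect_equal(acceptance_probability(0, 18.1), 1)
  expect_equal(acceptance_probability(0.3, 0), 1)
  expect_equal(acceptance_probability(0.1, 18.1), 10^-1.81)
  expect_equal(acceptance_probability(1, 18.1), 10^-18.1)
})

test_that("donors are drawn uniformly among co-existing lineages, never self", {
  set.seed(2)
  expect_equal(pick_donor(c("x", "y"), "x"), "y")
  expect_null(pick_donor("x", "x"))
  keys <- letters[1:10]
  draws <- replicate(1e5, pick_donor(keys, "a"))
  expect_false(any(draws == "a"))
  frac <- as.numeric(table(factor(draws, letters[2:10]))) / 1e5
  se <- sqrt((1 / 9) * (8 / 9) / 1e5)
  expect_true(all(abs(frac - 1 / 9) < 4 * se))
})

test_that("recombination copies the donor tract and counts SNPs by diff oracle", {
  set.seed(3)
  pair <- make_diverged_pair(300, 0.2)
  # identical genomes: nothing changes
  same <- apply_recombination(genome_clone(pair$a), pair$a,
                              list(start = 10L, length = 50L))
  expect_true(same$accepted)
  expect_equal(same$snps, 0L)

  for (k in 1:50) {
    rec <- genome_clone(pair$a)
    don <- pair$b
    start <- sample.int(250, 1L); len <- sample.int(50, 1L)
    before <- rec$seq
    expected_snps <- sum(before[start:(start + len - 1L)] !=
                           don$seq[start:(start + len - 1L)])
    donor_before <- don$seq
    ev <- apply_recombination(rec, don, list(start = start, length = len))
    expect_true(ev$accepted)
    expect_equal(ev$snps, expected_snps)
    expect_equal(rec$seq[start:(start + len - 1L)],
                 don$seq[start:(start + len - 1L)])
    expect_identical(don$seq, donor_before)        # non-reciprocal
    expect_equal(rec$seq[-(start:(start + len - 1L))],
                 before[-(start:(start + len - 1L))])
  }
})

test_that("with bias disabled every attempt is accepted; enabled matches 10^(-pi*phi)", {
  set.seed(4)
  pair <- make_diverged_pair(2001, 0.05)
  pi0 <- pair$n_diff / 2001
  n <- 1e4
  acc <- logical(n)
  for (k in seq_len(n)) {
    rec <- genome_clone(pair$a)
    acc[k] <- apply_recombination(rec, pair$b, list(start = 1L, length = 2001L),
                                  bias_model(TRUE, 18.1))$accepted
  }
  p_want <- 10^(-pi0 * 18.1)
  se <- sqrt(p_want * (1 - p_want) / n)
  expect_lt(abs(mean(acc) - p_want), 4 * se)

  off <- vapply(1:200, function(k) {
    rec <- genome_clone(pair$a)
    apply_recombination(rec, pair$b, list(start = 1L, length = 100L),
                        bias_model(FALSE))$accepted
  }, logical(1))
  expect_true(all(off))

  # rejected events leave the recipient untouched
  rec <- genome_clone(pair$a)
  repeat {
    ev <- apply_recombination(rec, pair$b, list(start = 1L, length = 2000L),
                              bias_model(TRUE, 60))
    if (!ev$accepted) break
  }
  expect_equal(ev$status, "rejected_bias")
  expect_identical(rec$seq, pair$a$seq)
})

test_that("tract over a gene absent from the donor transfers only the shared fragment", {
  # recipient: G1 (30bp) | Y (12bp, accessory) | G2 (30bp); donor lacks Y
  s_rec <- rep(1L, 72)
  rec <- new_genome(s_rec, c("G1", "Y", "G2"), c(30L, 12L, 30L))
  don <- new_genome(rep(3L, 60), c("G1", "G2"), c(30L, 30L))
  # one breakpoint inside the accessory gene Y: tract 25..42 covers G1 end + Y
  ev <- apply_recombination(rec, don, list(start = 25L, length = 18L))
  expect_true(ev$accepted)
  expect_equal(ev$hom_length, 6L)                  # only the G1 fragment
  expect_equal(rec$seq[25:30], rep(3L, 6))         # shared fragment replaced
  expect_equal(rec$seq[31:42], rep(1L, 12))        # accessory gene untouched
  expect_equal(rec$gene_id, c("G1", "Y", "G2"))    # no whole-gene move
  expect_equal(ev$genes_lost, character(0))
})

test_that("tract entirely inside donor-absent sequence is discarded", {
  rec <- new_genome(rep(1L, 72), c("G1", "Y", "G2"), c(30L, 12L, 30L))
  don <- new_genome(rep(3L, 60), c("G1", "G2"), c(30L, 30L))
  ev <- apply_recombination(rec, don, list(start = 31L, length = 12L))
  expect_false(ev$accepted)
  expect_equal(ev$status, "no_homology")
  expect_equal(rec$seq, rep(1L, 72))
})

test_that("whole accessory genes move only when both breakpoints are shared", {
  # donor carries X between shared G1 and G2 -> X inserted whole
  rec <- new_genome(rep(1L, 60), c("G1", "G2"), c(30L, 30L))
  don <- new_genome(c(rep(3L, 30), rep(2L, 12), rep(3L, 30)),
                    c("G1", "X", "G2"), c(30L, 12L, 30L))
  ev <- apply_recombination(rec, don, list(start = 25L, length = 20L))
  expect_true(ev$accepted)
  expect_equal(ev$genes_gained, "X")
  expect_equal(rec$gene_id, c("G1", "X", "G2"))
  expect_equal(rec$seq[31:42], rep(2L, 12))        # the inserted gene, whole
  expect_equal(sum(rec$gene_len), 72L)

  # recipient-only Y between shared breakpoints -> Y deleted whole
  rec2 <- new_genome(rep(1L, 72), c("G1", "Y", "G2"), c(30L, 12L, 30L))
  don2 <- new_genome(rep(3L, 60), c("G1", "G2"), c(30L, 30L))
  ev2 <- apply_recombination(rec2, don2, list(start = 25L, length = 48L))
  expect_true(ev2$accepted)
  expect_equal(ev2$genes_lost, "Y")
  expect_equal(rec2$gene_id, c("G1", "G2"))
  expect_equal(length(rec2$seq), 60L)

  # breakpoint inside the accessory gene: no whole-gene move
  rec3 <- new_genome(rep(1L, 72), c("G1", "Y", "G2"), c(30L, 12L, 30L))
  ev3 <- apply_recombination(rec3, don2, list(start = 25L, length = 12L))
  expect_equal(ev3$genes_lost, character(0))
  expect_equal(rec3$gene_id, c("G1", "Y", "G2"))
})
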