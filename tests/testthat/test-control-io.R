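write_tree_file <- function(text = "(A:0.01,(B:0.005,C:0.005):0.005);") {
  p <- tempfile(fileext = ".nwk")
  writeLines(text, p)
  p
}

write_ctl <- function(lines) {
  p <- tempfile(fileext = ".ctl")
  writeLines(lines, p)
  p
}

test_that("a minimal control file parses with documented defaults", {
  tf <- write_tree_file()
  ctl <- write_ctl(c(
    "# minimal run",
    paste("tree =", tf),
    "L = 3000",
    "gc = 0.45",
    "rho = 0.5"
  ))
  parsed <- parse_control(ctl)
  cfg <- parsed$config
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$L, 3000L)
  expect_equal(cfg$gc, 0.45)
  expect_equal(cfg$rho, 0.5)
  expect_false(cfg$bias$enabled)           # bias off by default
  expect_equal(cfg$bias$phi, 18.1)         # default slope when enabled later
  expect_equal(cfg$gain_rate, 0)
  expect_equal(cfg$loss_rate, 0)
  expect_equal(cfg$scale, 1)
  expect_equal(cfg$delta, 100)
  expect_equal(cfg$model$name, "JC69")
})

test_that("control file errors carry line numbers and name the problem", {
  tf <- write_tree_file()
  expect_error(parse_control(write_ctl(c(paste("tree =", tf), "L = 3000"))),
               "rho")
  expect_error(parse_control(write_ctl(c(paste("tree =", tf), "rho = 0.5",
                                         "L = 3000", "frobnicate = 1"))),
               "line 4.*frobnicate")
  expect_error(parse_control(write_ctl(c(paste("tree =", tf), "rho = 0.5",
                                         "L = 1000"))),
               "line 3.*multiple of 3")
  expect_error(parse_control(write_ctl(c(paste("tree =", tf), "rho = 0.5",
                                         "L = 3000", "model = GTR"))),
               "gtr_rates")
  expect_error(parse_control(write_ctl(c("rho = 0.5", "L = 3000"))),
               "tree")
  expect_error(parse_control(write_ctl(c(paste("tree =", tf), "rho = 0.5",
                                         "L = 3000", "gc = abc"))),
               "line 4.*not numeric")
})

test_that("bias without an explicit slope defaults to phi = 18.1", {
  tf <- write_tree_file()
  ctl <- write_ctl(c(paste("tree =", tf), "L = 3000", "rho = 0.5", "bias = on"))
  cfg <- parse_control(ctl)$config
  expect_true(cfg$bias$enabled)
  expect_equal(cfg$bias$phi, 18.1)
})

test_that("K2P and GTR parameters flow through the control file", {
  tf <- write_tree_file()
  cfg <- parse_control(write_ctl(c(
    paste("tree =", tf), "L = 3000", "rho = 0", "model = K2P", "kappa = 1.6",
    "codon_rates = 0.15,0.07,0.78"
  )))$config
  expect_equal(cfg$model$name, "K2P")
  expect_equal(cfg$model$weights["A", "G"], 1.6 / 3.6)
  expect_equal(as.numeric(unclass(cfg$profile)), c(0.15, 0.07, 0.78))

  cfg2 <- parse_control(write_ctl(c(
    paste("tree =", tf), "L = 3000", "rho = 0", "model = GTR",
    "gtr_rates = 1,2,1,1,2,1", "gc = 0.4"
  )))$config
  expect_equal(cfg2$model$name, "GTR")
})

test_that("outputs round-trip and are byte-identical under the same seed", {
  tf <- write_tree_file()
  ctl <- write_ctl(c(
    paste("tree =", tf), "L = 3000", "rho = 0.5", "delta = 50", "seed = 21",
    "gene_length = 300", "gain_rate = 0.3", "loss_rate = 0.3"
  ))
  d1 <- file.path(tempfile(), "run1"); d2 <- file.path(tempfile(), "run2")
  sim <- run_simulation(ctl, output_dir = d1)
  run_simulation(ctl, output_dir = d2)

  aln <- Biostrings::readDNAStringSet(file.path(d1, "core_alignment.fasta"))
  expect_setequal(names(aln), c("A", "B", "C"))
  expect_equal(length(unique(Biostrings::width(aln))), 1L)
  expect_false(any(grepl("-", as.character(aln), fixed = TRUE)))

  for (f in c("core_alignment.fasta", "presence_absence.tsv", "mutations.tsv",
              "recombinations.tsv", "stats.txt")) {
    expect_identical(tools::md5sum(file.path(d1, f))[[1]],
                     tools::md5sum(file.path(d2, f))[[1]])
  }
  pa <- read.delim(file.path(d1, "presence_absence.tsv"), check.names = FALSE)
  expect_setequal(colnames(pa), c("gene_id", "A", "B", "C"))
  expect_true(all(as.matrix(pa[, -1]) %in% 0:1))
  expect_true(file.exists(file.path(d1, "run_log.txt")))
  expect_true(file.exists(file.path(d1, "genomes", "A.fasta")))

  # seed override changes the outcome
  sim2 <- run_simulation(ctl, output_dir = tempfile(), seed = 22)
  expect_false(identical(sim$leaf_genomes$A$seq, sim2$leaf_genomes$A$seq))
})

test_that("a user-supplied root FASTA drives the simulation", {
  tf <- write_tree_file("(A:0,B:0);")
  fa <- tempfile(fileext = ".fasta")
  root <- paste(rep("ACGTGA", 100), collapse = "")
  writeLines(c(">root", root), fa)
  ctl <- write_ctl(c(paste("tree =", tf), paste("root_fasta =", fa), "rho = 0"))
  sim <- run_simulation(ctl)
  expect_equal(seq_to_char(sim$leaf_genomes$A$seq), root)

  fa2 <- tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACGTGA", ">r2", "ACGTGA"), fa2)
  expect_error(read_root_fasta(fa2), "exactly one record")
})

test_that("core alignment equals L with zero flux and 34 records for 34 leaves", {
  set.seed(30)
  phy <- ape::rtree(34)
  phy$edge.length <- phy$edge.length * 0.001
  tf <- write_tree_file(ape::write.tree(phy))
  ctl <- write_ctl(c(paste("tree =", tf), "L = 999", "rho = 0", "seed = 30"))
  d <- tempfile()
  run_simulation(ctl, output_dir = d)
  aln <- Biostrings::readDNAStringSet(file.path(d, "core_alignment.fasta"))
  expect_equal(length(aln), 34L)
  expect_true(all(Biostrings::width(aln) == 999L))
})
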