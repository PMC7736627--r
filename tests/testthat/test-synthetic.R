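test_that("identical seed and config reproduce byte-identical datasets", {
  cfg <- simulation_config(seed = 303L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$root$sequence, d2$root$sequence)
  expect_identical(lapply(d1$genomes, `[[`, "sequence"),
                   lapply(d2$genomes, `[[`, "sequence"))
  expect_identical(d1$ledger, d2$ledger)
})

test_that("root genomes honour layout, ORF and composition targets", {
  ds <- get_sim3()
  root <- ds$root
  rep_ <- validate_gene_complement(root$table)
  expect_identical(unname(rep_$counts), c(13L, 22L, 2L, 1L, 1L))
  # size profile equals the S. tertius column
  ann <- rockfish_annotation("ST")
  expect_identical(unname(feature_size(root$table)),
                   unname(ann$end - ann$start + 1L))
  aud <- start_stop_audit(root)
  expect_identical(aud$start_codon[aud$gene == "COI"], "GTG")
  expect_identical(aud$stop_codon[aud$gene == "COII"], "T")
  expect_identical(sort(aud$gene[nchar(aud$stop_codon) < 3L]),
                   sort(c("ND2", "COII", "ATP6", "COIII", "ND3", "ND4", "CYTB")))
  comp <- composition(root$sequence)
  expect_lt(abs(comp$at_content - 55), 2)
})

test_that("whole-genome AT skew converges to its target", {
  for (sk in c(-0.1, 0, 0.1)) {
    cfg <- simulation_config(seed = 500L + round(100 * sk),
                             target_at_skew = sk)
    g <- generate_root_genome(cfg)$genome
    comp <- composition(g$sequence)
    n_at <- comp$counts[["A"]] + comp$counts[["T"]]
    se <- sqrt((1 - sk^2) / n_at)
    expect_lt(abs(comp$at_skew - sk), 3 * se)
  }
})

test_that("zero-length branches copy the root; evolved leaves stay ORF-clean", {
  cfg0 <- simulation_config(seed = 71L, tree = "(a:0,b:0);")
  d0 <- simulate_dataset(cfg0)
  expect_identical(d0$genomes$a$sequence, d0$root$sequence)
  expect_identical(d0$genomes$b$sequence, d0$root$sequence)

  ds <- get_sim3()
  for (g in ds$genomes) {
    aud <- start_stop_audit(g)  # would error on internal stops
    expect_identical(sum(aud$aa_length), 3800L)
  }
})

test_that("omega 0 admits no nonsynonymous change and NG86 sees Ka = 0", {
  cfg <- simulation_config(seed = 99L, omega = 1e-12,
                           tree = "(a:0.05,b:0.05);")
  ds <- simulate_dataset(cfg)
  nonsyn <- unlist(lapply(ds$ledger$branches, function(b) unlist(b$nonsyn)))
  expect_true(all(nonsyn == 0L))
  kk <- kaks_table(ds$genomes)
  expect_true(all(kk$pairs$Ka == 0))
})

test_that("ledger substitution counts line up with observed divergence", {
  ds <- get_sim3()
  br <- ds$ledger$branches
  tot_syn <- sum(unlist(lapply(br, function(b) unlist(b$syn))))
  tot_nonsyn <- sum(unlist(lapply(br, function(b) unlist(b$nonsyn))))
  expect_gt(tot_syn, 0)
  expect_gt(tot_syn, tot_nonsyn)  # purifying regime
  # pairwise differences cannot exceed total accepted events on the path
  cds_a <- paste(pcg_coding_sequences(ds$genomes[[1]]), collapse = "")
  cds_b <- paste(pcg_coding_sequences(ds$genomes[[2]]), collapse = "")
  ndiff <- sum(strsplit(cds_a, "")[[1]] != strsplit(cds_b, "")[[1]])
  expect_lte(ndiff, tot_syn + tot_nonsyn)
})

test_that("emitted files round-trip to the in-memory objects", {
  ds <- get_sim3()
  out <- file.path(tempdir(), "simout")
  paths <- emit_dataset(ds, out)
  expect_true(file.exists(paths$ledger))
  lg <- jsonlite::read_json(paths$ledger)
  expect_true(all(c("seed", "base_probs", "planted_repeat", "tree",
                    "branches") %in% names(lg)))
  for (nm in names(ds$genomes)) {
    fa <- read_fasta(paths[[nm]][["fasta"]])
    expect_identical(unname(fa), ds$genomes[[nm]]$sequence)
    tab <- read_feature_table(paths[[nm]][["tsv"]])
    expect_identical(tab$features$start, ds$genomes[[nm]]$table$features$start)
    gb <- read_genbank(paths[[nm]][["genbank"]])
    expect_identical(gb$sequence, ds$genomes[[nm]]$sequence)
  }
})
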