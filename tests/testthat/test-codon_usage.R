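test_that("translation follows the vertebrate mitochondrial code", {
  expect_identical(translate_mito(c("ATG", "TGA", "AAA"), initiator = FALSE),
                   "MWK")
  expect_identical(substr(translate_mito(c("GTG", "TTT")), 1, 1), "M")
  expect_identical(substr(translate_mito(c("ATA", "TTT")), 1, 1), "M")
  expect_identical(translate_mito("ANG", initiator = FALSE), "X")
  expect_identical(translate_mito("AGA", initiator = FALSE), "*")
})

test_that("coding records resolve complete and incomplete stops", {
  tab <- gene_table(data.frame(name = "ND1", start = 1L, end = 9L,
                               strand = "H", category = "PCG",
                               stringsAsFactors = FALSE))
  g <- mitogenome("ATGAAATAA", tab)
  rec <- extract_coding_record(g, "ND1")
  expect_identical(rec$codons, c("ATG", "AAA"))
  expect_identical(rec$stop_codon, "TAA")
  expect_identical(rec$aa_length, 2L)

  syn <- get_sim3()$genomes[[1]]
  co2 <- extract_coding_record(syn, "COII")
  expect_identical(co2$aa_length, 230L)
  expect_identical(co2$stop_codon, "T")
  nd2 <- extract_coding_record(syn, "ND2")
  expect_identical(nd2$aa_length, 348L)
  expect_identical(nd2$stop_codon, "TA")

  expect_error(extract_coding_record(toy_internal_stop_genome(), "ND1"),
               "internal stop codon TAA at codon 2")
})

test_that("length bookkeeping holds for every PCG of every species profile", {
  g <- get_sim3()$genomes[[1]]
  aud <- start_stop_audit(g)
  expect_true(all(3L * aud$aa_length + nchar(aud$stop_codon) == aud$size))
  expect_identical(sum(aud$aa_length), 3800L)
  # published start-codon conventions: ATG everywhere except GTG for COI
  expect_identical(aud$start_codon[aud$gene == "COI"], "GTG")
  expect_true(all(aud$start_codon[aud$gene != "COI"] == "ATG"))
})

test_that("RSCU matches its definition and conserves family sums", {
  cods <- c(rep("GCC", 3), rep("GCA", 3))  # Ala family, equal use of 2 of 4
  r <- rscu(codon_count_table(cods))
  ala <- r[r$family == "Ala", ]
  expect_equal(ala$rscu[ala$codon %in% c("GCA", "GCC")], c(2, 2))
  expect_equal(sum(ala$rscu), 4)

  # pooled six-codon Leu family: counts TTA 6, CTT 2, CTA 4 -> RSCU(TTA) = 3
  leu <- c(rep("TTA", 6), rep("CTT", 2), rep("CTA", 4))
  rp <- rscu(codon_count_table(leu, split_families = FALSE))
  expect_equal(rp$rscu[rp$codon == "TTA"], 3.0)
  # split families: TTA sits in the two-codon Leu(UUR) family
  rs <- rscu(codon_count_table(leu, split_families = TRUE))
  expect_equal(rs$rscu[rs$codon == "TTA"], 2.0)

  set.seed(42)
  cct <- codon_count_table(random_sense_codons(500))
  rr <- rscu(cct)
  for (fam in unique(rr$family)) {
    sub <- rr[rr$family == fam, ]
    if (!sub$undefined[1]) expect_equal(sum(sub$rscu), nrow(sub))
  }
  # a family never observed is flagged, not divided by zero
  r0 <- rscu(codon_count_table("ATG"))
  expect_true(all(r0$undefined[r0$family == "Cys"]))
  expect_true(all(r0$rscu[r0$family == "Cys"] == 0))
})

test_that("amino-acid usage pools and splits Leu/Ser families", {
  cct <- codon_count_table(c("ATG", "AAA", "AAA"))
  u <- aa_usage(cct)
  expect_identical(u$by_residue[["Met"]], 1L)
  expect_identical(u$by_residue[["Lys"]], 2L)

  g <- get_sim3()$genomes[[1]]
  cu <- codon_usage(g)
  u2 <- aa_usage(cu)
  expect_identical(sum(u2$by_residue), cu$total_codons)
  expect_identical(u2$by_residue[["Leu"]],
                   u2$by_family[["Leu(UUR)"]] + u2$by_family[["Leu(CUN)"]])
  # brute-force residue count via translation
  aas <- strsplit(translate_mito(rep(names(cu$X), cu$X), initiator = FALSE),
                  "")[[1]]
  expect_identical(unname(u2$by_residue[["Ala"]]), sum(aas == "A"))
})
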