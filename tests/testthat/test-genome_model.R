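test_that("feature sizes follow 1-based inclusive arithmetic", {
  ann <- rockfish_annotation("ST")
  nd5 <- ann[ann$name == "ND5", ]
  expect_identical(unname(feature_size(nd5)), 1839L)
  expect_identical(unname(feature_size(gene_feature("ND1", 7, 7))), 1L)
  sm <- rockfish_annotation("SM")
  expect_identical(unname(feature_size(sm[sm$name == "D-loop", ])), 1918L)
})

test_that("intervening spacers are signed gaps, negatives meaning overlap", {
  st <- rockfish_annotation("ST")
  f <- function(nm) st[st$name == nm, ]
  expect_identical(intervening_spacer(f("ATP8"), f("ATP6")), -10L)
  expect_identical(intervening_spacer(f("ND5"), f("ND6")), -4L)
  a <- gene_feature("tRNA-Phe", 1, 100)
  b <- gene_feature("12S-rRNA", 101, 200)
  expect_identical(intervening_spacer(a, b), 0L)
  expect_error(intervening_spacer(b, a), "precede")
})

test_that("gene complement audit counts categories and missing elements", {
  full <- validate_gene_complement(rockfish_gene_table("ST"))
  expect_identical(unname(full$counts),
                   c(13L, 22L, 2L, 1L, 1L))
  expect_identical(full$n_genes, 37L)
  expect_true(full$complete)

  empty <- validate_gene_complement(gene_table(data.frame(
    name = character(0), start = integer(0), end = integer(0),
    strand = character(0), category = character(0))))
  expect_true(all(empty$counts == 0L))
  expect_length(empty$missing, 39L)

  syn <- get_sim3()$genomes[[1]]
  expect_identical(validate_gene_complement(syn$table)$counts, full$counts)
})

test_that("extract_region honours coordinates, strand and orientation", {
  tab <- gene_table(data.frame(name = "ND1", start = 3L, end = 6L,
                               strand = "H", category = "PCG",
                               stringsAsFactors = FALSE),
                    genome_length = 8L)
  g <- mitogenome("AACCGGTT", tab)
  f <- tab$features[1, ]
  expect_identical(extract_region(g, f), "CCGG")
  fL <- f; fL$strand <- "L"
  expect_identical(extract_region(g, fL), "CCGG")  # palindrome
  expect_identical(extract_region(g, fL, orient = "h-strand"), "CCGG")
  fbad <- f; fbad$end <- 99L
  expect_error(extract_region(g, fbad), "exceed")
})

test_that("every synthetic PCG translates without internal stops", {
  g <- get_sim3()$genomes[[1]]
  aud <- start_stop_audit(g)  # errors on any internal stop
  expect_identical(nrow(aud), 13L)
  expect_false(any(grepl("\\*", vapply(aud$gene, function(gn)
    translate_mito(extract_coding_record(g, gn)$codons), ""))))
})

test_that("feature table TSV round-trips and fixture tables load", {
  t1 <- rockfish_gene_table("ST")
  expect_identical(t1$genome_length, 16910L)
  expect_identical(nrow(t1$features), 39L)
  tmp <- tempfile(fileext = ".tsv")
  write_feature_table(t1, tmp)
  t2 <- read_feature_table(tmp)
  expect_identical(t1$features, t2$features)
  expect_identical(t1$genome_length, t2$genome_length)
})

test_that("alias resolution maps mixed naming onto canonical labels", {
  expect_identical(canonical_name(c("ATPase6", "Cyt b", "COX1", "O_L")),
                   c("ATP6", "CYTB", "COI", "OL"))
})

test_that("GenBank dialect round-trips the generator's ground truth", {
  ds <- get_sim3()
  g <- ds$genomes$marmoratus
  tmp <- tempfile(fileext = ".gb")
  write_genbank(g, tmp)
  back <- read_genbank(tmp)
  expect_identical(back$sequence, g$sequence)
  expect_identical(back$table$features[, c("name", "start", "end", "strand", "category")],
                   g$table$features[, c("name", "start", "end", "strand", "category")])
  expect_identical(back$species, g$species)
})
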