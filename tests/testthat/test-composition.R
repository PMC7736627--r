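test_that("composition implements the skew formulas with ambiguity exclusion", {
  s <- composition("AAAT")
  expect_equal(s$at_skew, 0.5)
  expect_true(is.na(s$gc_skew))  # undefined, not 0
  s2 <- composition("ACGT")
  expect_equal(s2$at_content, 50)
  expect_equal(s2$at_skew, 0)
  expect_equal(s2$gc_skew, 0)
  expect_error(composition(""), "empty")
  s3 <- composition("NNNN")
  expect_identical(s3$n_ambiguous, 4L)
  expect_true(is.na(s3$at_skew) && is.na(s3$gc_skew))
  s4 <- composition("ACGTN")
  expect_identical(sum(s4$counts) + s4$n_ambiguous, 5L)
})

test_that("skews are antisymmetric under reverse complement", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE,
                      prob = c(0.4, 0.1, 0.2, 0.3)), collapse = "")
    a <- composition(s); b <- composition(reverse_complement(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
  }
})

test_that("partition counts sum to the union and match a brute-force count", {
  g <- get_sim3()$genomes[[1]]
  feat <- partition_composition(g, "feature")
  cat_ <- partition_composition(g, "category")
  for (cc in cat_$label) {
    idx <- g$table$features$category == cc
    expect_equal(cat_[cat_$label == cc, c("A", "C", "G", "T")],
                 as.data.frame(t(colSums(feat[idx, c("A", "C", "G", "T")]))),
                 ignore_attr = TRUE)
  }
  # independent character counter over the two rRNA substrings
  f <- g$table$features
  rr <- f[f$category == "rRNA", ]
  joined <- paste(substr(g$sequence, rr$start[1], rr$end[1]),
                  substr(g$sequence, rr$start[2], rr$end[2]), sep = "")
  tab <- table(factor(strsplit(joined, "")[[1]], levels = c("A", "C", "G", "T")))
  expect_equal(unlist(cat_[cat_$label == "rRNA", c("A", "C", "G", "T")]),
               c(tab), ignore_attr = TRUE)
})

test_that("codon-position partition excludes incomplete stops only", {
  g <- get_sim3()$genomes[[1]]
  cp <- partition_composition(g, "codon-position")
  expect_identical(cp$label,
                   c("codon_position_1", "codon_position_2", "codon_position_3"))
  total_sites <- sum(cp$A + cp$C + cp$G + cp$T + cp$n_ambiguous)
  aud <- start_stop_audit(g)
  complete_stops <- sum(nchar(aud$stop_codon) == 3L)
  expect_identical(total_sites, 3L * (sum(aud$aa_length) + complete_stops))
  # each position holds an equal share
  expect_true(all(cp$A + cp$C + cp$G + cp$T + cp$n_ambiguous == total_sites / 3L))
})

test_that("uniform ACGT repeats have zero skew in every partition", {
  tab <- gene_table(data.frame(name = "12S-rRNA", start = 1L, end = 40L,
                               strand = "H", category = "rRNA",
                               stringsAsFactors = FALSE))
  g <- mitogenome(strrep("ACGT", 10), tab)
  p <- partition_composition(g, "feature")
  expect_true(all(p$at_skew == 0) && all(p$gc_skew == 0))
})

test_that("motif scan matches IUPAC patterns at 1-based positions", {
  expect_identical(motif_scan("TTGCCGGAA", "GCCGG"), 3L)
  expect_identical(motif_scan("TTTTTT", "GCCGG"), integer(0))
  expect_identical(motif_scan("AGGTACC", "RRN"), c(1L, 2L))
  expect_error(motif_scan("ACGT", "GCZ"), "IUPAC")
  g <- get_sim3()$root
  ol <- extract_region(g, "OL", orient = "h-strand")
  expect_length(motif_scan(ol, "GCCGG"), 1L)
})
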