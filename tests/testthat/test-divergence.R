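test_that("p-distance counts mismatches over comparable sites", {
  expect_equal(as.numeric(p_distance("ACGTAC", "ACGTAC")), 0)
  expect_equal(as.numeric(p_distance("AAAA", "TTTT")), 1)
  p <- p_distance("AAAAAAAAAA", "AAAAAAAATT")
  expect_equal(as.numeric(p), 0.2)
  expect_identical(attr(p, "sites"), 10L)
  # pairwise deletion
  p2 <- p_distance("AANA", "AAAA")
  expect_identical(attr(p2, "sites"), 3L)
  expect_error(p_distance("NNN", "AAA"), "zero comparable")
  expect_error(p_distance("AC", "ACG"), "equal length")
})

test_that("codon-position partitions separate third-position change", {
  a <- c(g1 = "ATGCTGAAT")
  b <- c(g1 = "ATACTAAAC")  # differences at positions 3, 6, 9 only
  d <- codon_partition_distances(a, b)
  expect_equal(d$p12, 0)
  expect_equal(d$p3, 1)
  expect_identical(d$sites12, 6L)
  expect_error(codon_partition_distances(c(g1 = "ATGC"), c(g1 = "ATGC")),
               "frame")
  expect_error(codon_partition_distances(c(g1 = "ATG"), c(g2 = "ATG")),
               "gene sets")
})

test_that("NG86 sites partition exactly and fourfold sites are synonymous", {
  r0 <- nei_gojobori("ATGAAA", "ATGAAA")
  expect_equal(r0$Ka, 0); expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))
  expect_true("ratio_undefined" %in% r0$flags)

  # GGA -> GGC: fourfold degenerate third position
  r1 <- nei_gojobori("ATGGGA", "ATGGGC")
  expect_equal(r1$Sd, 1); expect_equal(r1$Nd, 0); expect_equal(r1$Ka, 0)

  set.seed(11)
  for (i in 1:25) {
    a <- random_sense_codons(8)
    b <- random_sense_codons(8)
    r <- nei_gojobori(a, b)
    expect_equal(r$S + r$N, 24)                       # S + N = 3 * codons
    expect_equal(r$Sd + r$Nd, sum(mapply(function(x, y)   # total differences
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]), a, b)))
    rba <- nei_gojobori(b, a)                          # symmetry
    expect_equal(r$Sd, rba$Sd); expect_equal(r$S, rba$S)
  }
})

test_that("NG86 pathway averaging equals exhaustive enumeration", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(1:5, 1)
    a <- random_sense_codons(n)
    b <- random_sense_codons(n)
    r <- nei_gojobori(a, b)
    orc <- colSums(do.call(rbind, Map(oracle_pathways, a, b)))
    expect_equal(r$Sd, unname(orc["sd"]), tolerance = 1e-12)
    expect_equal(r$Nd, unname(orc["nd"]), tolerance = 1e-12)
    expect_equal(r$S, (sum(vapply(a, oracle_syn_sites, 0)) +
                       sum(vapply(b, oracle_syn_sites, 0))) / 2,
                 tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction inflates and saturates as expected", {
  p <- seq(0.01, 0.74, by = 0.05)
  expect_true(all(jc_correct(p) >= p))
  expect_true(is.na(jc_correct(0.75)))
  # stop codon input is rejected
  expect_error(nei_gojobori(c("ATG", "TAA"), c("ATG", "TAA")), "stop")
})

test_that("selection classification brackets neutrality", {
  expect_identical(classify_selection(0.135), "purifying")
  expect_identical(classify_selection(1.0), "neutral")
  expect_identical(classify_selection(1 + 1e-12), "neutral")
  expect_identical(classify_selection(2.3), "positive")
  expect_error(classify_selection(NA_real_), "undefined")
})

test_that("synthetic congeners are uniformly under purifying selection", {
  ds <- get_sim3()
  kk <- kaks_table(ds$genomes)
  expect_identical(sort(unique(kk$pairs$gene)), sort(names(default_omega())))
  defined <- !is.na(kk$pairs$ratio)
  expect_true(all(kk$pairs$class[defined] == "purifying"))
  expect_true(all(kk$gene_means < 1, na.rm = TRUE))
})
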