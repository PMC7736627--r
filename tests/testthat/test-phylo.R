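test_that("supermatrix tiles trimmed genes in canonical order", {
  ds <- get_sim4()
  sm <- build_supermatrix(ds$genomes)
  aud <- start_stop_audit(ds$genomes[[1]])
  want <- sum(3L * aud$aa_length + ifelse(nchar(aud$stop_codon) == 3L, 3L, 0L))
  expect_identical(nchar(sm$alignment[[1]]), want)
  expect_identical(sm$gene_boundaries$gene[1], "ND1")
  expect_identical(sm$gene_boundaries$end[13], want)
  expect_true(all(nchar(sm$alignment) == want))

  # single taxon: width check only
  sm1 <- build_supermatrix(ds$genomes[1])
  expect_identical(nchar(sm1$alignment[[1]]), want)

  g2 <- ds$genomes[[2]]
  g2$table$features <- g2$table$features[g2$table$features$name != "ND6", ]
  broken <- ds$genomes; broken[[2]] <- g2
  expect_error(build_supermatrix(broken), "ND6")
})

test_that("TN93 distance matches an independent implementation", {
  expect_equal(as.numeric(tn93_distance("ACGTACGT", "ACGTACGT")), 0)
  set.seed(31)
  for (i in 1:10) {
    base <- sample(c("A", "C", "G", "T"), 1000, TRUE, prob = c(.3, .25, .2, .25))
    mut <- base
    idx <- sample(1000, 60)
    mut[idx] <- vapply(mut[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    a <- paste(base, collapse = ""); b <- paste(mut, collapse = "")
    mine <- as.numeric(tn93_distance(a, b))
    bin <- ape::as.DNAbin(rbind(a = base, b = mut))
    ref <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    expect_equal(mine, ref, tolerance = 1e-9)
    expect_gte(mine, as.numeric(p_distance(a, b)))  # correction inflates
  }
  expect_error(tn93_distance("NNN", "AAA"), "zero comparable")
})

test_that("three-taxon NJ solves the closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  expect_identical(ape::Ntip(tr), 3L)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["B"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["C"]], (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers additive trees exactly, matching the path metric", {
  set.seed(88)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    d <- ape::cophenetic.phylo(tr)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    est <- neighbor_joining(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), est)), 0)
    # branch lengths reproduce the generating path metric
    d2 <- ape::cophenetic.phylo(est)[rownames(d), colnames(d)]
    expect_equal(d2, d, tolerance = 1e-6)
    # and agrees with ape's own NJ topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(d), est)), 0)
  }
})

test_that("equidistant matrices resolve deterministically by tie-break", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap supports are seeded, reproducible and order-invariant", {
  ds <- get_sim4()
  sm <- build_supermatrix(ds$genomes)
  b1 <- bootstrap_support(sm, reps = 20, seed = 3)
  b2 <- bootstrap_support(sm, reps = 20, seed = 3)
  expect_identical(b1$supports, b2$supports)
  expect_true(all(b1$supports >= 0 & b1$supports <= 100))
  r1 <- bootstrap_support(sm, reps = 1, seed = 5)
  expect_true(all(r1$supports %in% c(0, 100)))
  perm <- rev(names(ds$genomes))
  b3 <- bootstrap_support(build_supermatrix(ds$genomes[perm]),
                          reps = 20, seed = 3)
  expect_identical(b1$supports[sort(names(b1$supports))],
                   b3$supports[sort(names(b3$supports))])
})

test_that("constraint checks test unrooted bipartitions", {
  tr <- ape::read.tree(text = "((ST:1,SA:1):1,SM:1,OUT:2);")
  got <- check_constraints(tr, list(c("ST", "SA"), c("ST", "SM"),
                                    c("ST", "SA", "SM")))
  expect_identical(unname(got), c(TRUE, FALSE, TRUE))
  expect_error(check_constraints(tr, list(c("ST", "nope"))), "unknown taxon")
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  ds <- get_sim4()
  sm <- build_supermatrix(ds$genomes)
  bs <- bootstrap_support(sm, reps = 10, seed = 9)
  tmp <- tempfile(fileext = ".nwk")
  write_newick(bs$tree, tmp)
  back <- read_newick(tmp)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(bs$tree),
                                         ape::unroot(back))), 0)
  expect_equal(sort(back$edge.length), sort(bs$tree$edge.length),
               tolerance = 1e-9)
  expect_identical(back$node.label, bs$tree$node.label)
})
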