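#' Build a concatenated PCG supermatrix
#'
#' Concatenates the 13 protein-coding genes of each genome in canonical
#' order on their coding strands, incomplete terminal stop bases trimmed
#' (complete stop codons kept). All genomes must supply all 13 genes with
#' matching per-gene lengths — the congeneric case; for genomes whose
#' gene lengths differ, align externally and supply equal-length inputs.
#'
#' @param genomes named list of [mitogenome()]s.
#' @return An object of class `supermatrix`: list with `taxa`,
#'   `alignment` (named equal-length sequences) and `gene_boundaries`
#'   (data frame `gene`, `start`, `end` of each gene's column interval).
#' @export
build_supermatrix <- function(genomes) {
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    stop("genomes must be a named list")
  per_gene <- lapply(genomes, function(g) {
    f <- g$table$features
    pcg <- f[f$category == "PCG", , drop = FALSE]
    missing <- setdiff(.pcg_names, pcg$name)
    if (length(missing))
      stop(sprintf("genome '%s' is missing gene(s): %s", g$species,
                   paste(missing, collapse = ", ")))
    seqs <- vapply(.pcg_names, function(gn) {
      i <- match(gn, pcg$name)
      s <- extract_region(g, pcg[i, , drop = FALSE], orient = "as-annotated")
      r <- nchar(s) %% 3L
      if (r > 0L) s <- substr(s, 1L, nchar(s) - r)
      s
    }, "")
    seqs
  })
  lens <- vapply(per_gene, nchar, numeric(length(.pcg_names)))
  if (is.matrix(lens)) {
    bad <- which(apply(lens, 1, function(x) length(unique(x)) > 1L))
    if (length(bad))
      stop("per-gene length mismatch across taxa for: ",
           paste(.pcg_names[bad], collapse = ", "),
           " — align these genes externally before concatenation")
  }
  gl <- vapply(per_gene[[1]], nchar, 0L)
  ends <- cumsum(gl)
  boundaries <- data.frame(gene = .pcg_names,
                           start = c(1L, utils::head(ends, -1) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  aln <- vapply(per_gene, paste, "", collapse = "")
  structure(list(taxa = names(genomes), alignment = aln,
                 gene_boundaries = boundaries), class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("supermatrix: %d taxa x %d columns (13 PCGs)\n",
              length(x$taxa), nchar(x$alignment[[1]])))
  invisible(x)
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 distance from the purine-transition proportion P1
#' (A<->G), pyrimidine-transition proportion P2 (C<->T) and transversion
#' proportion Q, with base frequencies estimated empirically from the
#' compared sites of both sequences. Pairwise deletion as in
#' [p_distance()]. When a logarithm argument is non-positive (distance
#' saturation) the result is `NA` with attribute `flag = "saturated"`.
#'
#' @param a,b aligned sequences of equal length.
#' @return TN93 distance (substitutions/site), `attr(,"sites")` compared.
#' @export
tn93_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  ok <- ac %in% c("A", "C", "G", "T") & bc %in% c("A", "C", "G", "T")
  ns <- sum(ok)
  if (ns == 0L) stop("zero comparable sites")
  ac <- ac[ok]; bc <- bc[ok]
  fr <- (table(factor(ac, levels = c("A", "C", "G", "T"))) +
         table(factor(bc, levels = c("A", "C", "G", "T")))) / (2 * ns)
  gA <- fr[["A"]]; gC <- fr[["C"]]; gG <- fr[["G"]]; gT <- fr[["T"]]
  gR <- gA + gG; gY <- gC + gT
  pair <- paste0(pmin(ac, bc), pmax(ac, bc))
  P1 <- mean(pair == "AG")
  P2 <- mean(pair == "CT")
  Q <- mean(ac != bc) - P1 - P2
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (any(!is.finite(c(w1, w2, w3))) || any(c(w1, w2, w3) <= 0)) {
    d <- NA_real_
    attr(d, "flag") <- "saturated"
  } else {
    d <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
  }
  attr(d, "sites") <- ns
  d
}

#' Pairwise distance matrix over a supermatrix
#'
#' @param sm a [build_supermatrix()] result.
#' @param method `"tn93"` or `"p"` (proportion distance).
#' @return Symmetric numeric matrix with zero diagonal and taxa
#'   dimnames. Errors if any pair is saturated (NA distance).
#' @export
distance_matrix <- function(sm, method = c("tn93", "p")) {
  method <- match.arg(method)
  taxa <- sm$taxa
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- if (method == "tn93")
      tn93_distance(sm$alignment[[i]], sm$alignment[[j]])
    else p_distance(sm$alignment[[i]], sm$alignment[[j]])
    if (is.na(v)) stop("saturated/undefined distance for pair ",
                       taxa[i], "-", taxa[j])
    d[i, j] <- d[j, i] <- as.numeric(v)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the Q criterion. Ties in Q are broken
#' deterministically by lexicographic order of the (sorted) taxon-pair
#' labels involved, so identical input always yields an identical tree.
#' Negative branch length estimates are clamped to zero; the total
#' clamped deficit is carried in attribute `clamped`.
#'
#' @param d symmetric distance matrix with taxa dimnames (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  taxa <- rownames(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining requires >= 3 taxa")
  if (any(is.na(d))) stop("NaN/NA distances forbidden")
  # working labels are Newick fragments; key labels track the smallest
  # contained taxon for deterministic tie-breaking
  frag <- taxa
  key <- taxa
  clamped <- 0
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(d)
    qbest <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      q <- (n - 2) * d[i, j] - r[i] - r[j]
      better <- q < qbest - 1e-12
      tie <- abs(q - qbest) <= 1e-12
      if (better || (tie && !is.na(bi) &&
                     paste(sort(c(key[i], key[j])), collapse = "\r") <
                     paste(sort(c(key[bi], key[bj])), collapse = "\r"))) {
        qbest <- q; bi <- i; bj <- j
      }
    }
    vi <- d[bi, bj] / 2 + (r[bi] - r[bj]) / (2 * (n - 2))
    vj <- d[bi, bj] - vi
    clamped <- clamped + sum(pmax(-c(vi, vj), 0))
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[bi], fmt(vi), frag[bj], fmt(vj))
    newkey <- min(key[bi], key[bj])
    dk <- (d[bi, ] + d[bj, ] - d[bi, bj]) / 2
    keep <- setdiff(seq_len(n), c(bi, bj))
    d2 <- matrix(0, n - 1L, n - 1L)
    d2[seq_along(keep), seq_along(keep)] <- d[keep, keep]
    d2[n - 1L, seq_along(keep)] <- d2[seq_along(keep), n - 1L] <- dk[keep]
    d <- d2
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    n <- n - 1L
  }
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  clamped <- clamped + sum(pmax(-c(va, vb, vc), 0))
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], fmt(va), frag[2], fmt(vb),
                 frag[3], fmt(vc))
  tr <- ape::read.tree(text = nwk)
  attr(tr, "clamped") <- clamped
  tr
}

# Canonical keys for the nontrivial bipartitions of an unrooted tree:
# for each internal edge, the tip set on the side NOT containing the
# alphabetically first tip, sorted and collapsed with "|".
tree_bipartitions <- function(tr) {
  tips <- sort(tr$tip.label)
  ref <- tips[1]
  tr <- ape::unroot(tr)
  pp <- ape::prop.part(ape::root(tr, outgroup = ref, resolve.root = TRUE))
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(ix) {
    side <- labs[ix]
    if (ref %in% side) side <- setdiff(tr$tip.label, side)
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[vapply(pp, length, 0L) < length(tips) &
              vapply(strsplit(keys, "\\|"), length, 0L) > 1L])
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples supermatrix columns with replacement, rebuilds the NJ tree
#' per replicate, and reports for each internal bipartition of the full
#' tree the percentage of replicates containing it. Fully seeded and
#' reproducible.
#'
#' @param sm a [build_supermatrix()] result (>= 4 taxa for nontrivial
#'   bipartitions).
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param method distance method, see [distance_matrix()].
#' @return A list with `tree` (NJ tree on the full matrix, bootstrap
#'   percentages as `node.label` where placeable) and `supports` (named
#'   numeric vector, one entry per internal bipartition key).
#' @export
bootstrap_support <- function(sm, reps = 100L, seed = 1L,
                              method = c("tn93", "p")) {
  method <- match.arg(method)
  if (reps < 1L) stop("reps must be >= 1")
  main <- neighbor_joining(distance_matrix(sm, method))
  keys <- tree_bipartitions(main)
  counts <- stats::setNames(numeric(length(keys)), keys)
  chars <- lapply(sm$alignment, function(s) strsplit(s, "")[[1]])
  W <- length(chars[[1]])
  set.seed(as.integer(seed))
  for (b in seq_len(reps)) {
    cols <- sample.int(W, W, replace = TRUE)
    bsm <- sm
    bsm$alignment <- vapply(chars, function(ch) paste(ch[cols], collapse = ""), "")
    bt <- neighbor_joining(distance_matrix(bsm, method))
    bk <- tree_bipartitions(bt)
    hit <- keys %in% bk
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / reps
  tree <- main
  if (length(keys)) {
    # attach supports as internal node labels via rooted representation
    ref <- sort(tree$tip.label)[1]
    rt <- ape::root(ape::unroot(tree), outgroup = ref, resolve.root = TRUE)
    pp <- ape::prop.part(rt)
    labs <- attr(pp, "labels")
    node_lab <- rep("", rt$Nnode)
    for (k in seq_along(pp)) {
      side <- labs[pp[[k]]]
      if (ref %in% side) side <- setdiff(rt$tip.label, side)
      key <- paste(sort(side), collapse = "|")
      if (key %in% keys) node_lab[k] <- sprintf("%g", supports[[key]])
    }
    rt$node.label <- node_lab
    tree <- rt
  }
  list(tree = tree, supports = supports)
}

#' Check clade constraints on an unrooted tree
#'
#' A constraint (a set of taxa) holds iff that set forms one side of a
#' bipartition of the unrooted tree — i.e. the clade is monophyletic
#' given any outgroup on the other side.
#'
#' @param tr an `ape::phylo` tree.
#' @param constraints list of character vectors of taxon names.
#' @return Named logical vector (names are the collapsed constraint
#'   sets).
#' @export
check_constraints <- function(tr, constraints) {
  tips <- tr$tip.label
  keys <- tree_bipartitions(tr)
  ref <- sort(tips)[1]
  out <- vapply(constraints, function(cl) {
    unknown <- setdiff(cl, tips)
    if (length(unknown)) stop("unknown taxon: ", paste(unknown, collapse = ", "))
    side <- if (ref %in% cl) setdiff(tips, cl) else cl
    if (length(side) < 2L || length(side) > length(tips) - 2L)
      return(TRUE)  # trivial bipartitions always hold
    paste(sort(side), collapse = "|") %in% keys
  }, NA)
  names(out) <- vapply(constraints, paste, "", collapse = "+")
  out
}

#' Read and write Newick trees
#'
#' Thin wrappers over ape's Newick parser/serializer; bootstrap supports
#' travel as internal node labels.
#'
#' @param x an `ape::phylo` tree (for write) or a path/text (for read).
#' @param path file path.
#' @return `read_newick` returns an `ape::phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
write_newick <- function(x, path) {
  ape::write.tree(x, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}
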