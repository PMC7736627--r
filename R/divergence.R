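## Nei-Gojobori (1986) counting under the vertebrate mitochondrial code.
## Site fractions and pathway-averaged difference counts are precomputed
## once per session over the 60 sense codons and cached.

.ng_cache <- new.env(parent = emptyenv())

.ng_tables <- function() {
  if (!is.null(.ng_cache$syn)) return(.ng_cache)
  code <- mito_code()
  bases <- c("A", "C", "G", "T")
  sense <- names(code)[code != "*"]

  # Fractional synonymous sites per codon: at each position, the fraction
  # of the three possible single-base changes that preserve the amino
  # acid. Changes creating a stop codon count as nonsynonymous, so
  # S + N = 3 exactly for every codon.
  syn <- stats::setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) for (b in setdiff(bases, ch[p])) {
      alt <- ch; alt[p] <- b
      altc <- paste(alt, collapse = "")
      if (code[[altc]] != "*" && code[[altc]] == code[[cod]]) s <- s + 1/3
    }
    syn[cod] <- s
  }

  # Pathway-averaged synonymous/nonsynonymous differences for every
  # ordered pair of sense codons. Minimal pathways change one differing
  # position at a time; pathways passing through a stop codon are
  # excluded (all pathways equally weighted). If every pathway is
  # blocked, stop-exclusion is dropped for that pair.
  n <- length(sense)
  sd_tab <- matrix(0, n, n, dimnames = list(sense, sense))
  nd_tab <- matrix(0, n, n, dimnames = list(sense, sense))
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (i in seq_len(n)) {
    a <- sense[i]; ach <- strsplit(a, "")[[1]]
    for (j in seq_len(n)) {
      if (i == j) next
      b <- sense[j]; bch <- strsplit(b, "")[[1]]
      diffpos <- which(ach != bch)
      k <- length(diffpos)
      perms <- switch(k, list(1L), perms2, perms3)
      paths <- lapply(perms, function(ord) {
        cur <- ach; sdc <- 0; ndc <- 0; blocked <- FALSE
        for (p in diffpos[ord]) {
          nxt <- cur; nxt[p] <- bch[p]
          c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
          if (code[[c2]] == "*") blocked <- TRUE
          if (code[[c1]] == code[[c2]]) sdc <- sdc + 1 else ndc <- ndc + 1
          cur <- nxt
        }
        c(sd = sdc, nd = ndc, blocked = as.numeric(blocked))
      })
      m <- do.call(rbind, paths)
      ok <- m[, "blocked"] == 0
      if (!any(ok)) ok <- rep(TRUE, nrow(m))
      sd_tab[i, j] <- mean(m[ok, "sd"])
      nd_tab[i, j] <- mean(m[ok, "nd"])
    }
  }
  .ng_cache$syn <- syn
  .ng_cache$sd <- sd_tab
  .ng_cache$nd <- nd_tab
  .ng_cache
}

#' Proportion distance between two aligned sequences
#'
#' Mismatches over compared sites, with pairwise deletion: only positions
#' where both sequences carry unambiguous A/C/G/T bases are compared.
#'
#' @param a,b aligned sequences of equal length.
#' @param positions optional integer subset of alignment positions.
#' @return The p-distance, with attribute `sites` (number compared).
#' @export
p_distance <- function(a, b, positions = NULL) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  if (!is.null(positions)) {
    if (any(positions < 1L | positions > length(ac)))
      stop("positions out of range")
    ac <- ac[positions]; bc <- bc[positions]
  }
  ok <- ac %in% c("A", "C", "G", "T") & bc %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("zero comparable sites")
  p <- sum(ac[ok] != bc[ok]) / sum(ok)
  attr(p, "sites") <- sum(ok)
  p
}

#' Codon-position-partitioned p-distances for a pair of genomes
#'
#' For each shared gene, computes the p-distance pooled over first and
#' second codon positions (`p12`) and over third positions alone (`p3`).
#' Inputs are per-gene in-frame aligned sequences (incomplete stops
#' already trimmed), as named character vectors.
#'
#' @param a,b named character vectors of in-frame gene sequences; names
#'   and lengths must match gene-by-gene.
#' @return Data frame with columns `gene`, `p12`, `p3`, `sites12`,
#'   `sites3`.
#' @export
codon_partition_distances <- function(a, b) {
  genes <- names(a)
  if (is.null(genes) || !setequal(genes, names(b)))
    stop("gene sets of the two inputs differ")
  rows <- lapply(genes, function(gn) {
    sa <- a[[gn]]; sb <- b[[gn]]
    if (nchar(sa) != nchar(sb))
      stop("length mismatch for gene ", gn, " (alignment required)")
    if (nchar(sa) %% 3L != 0L)
      stop("frame violation: length of ", gn, " not divisible by 3")
    pos <- seq_len(nchar(sa))
    p12 <- p_distance(sa, sb, positions = pos[pos %% 3L != 0L])
    p3 <- p_distance(sa, sb, positions = pos[pos %% 3L == 0L])
    data.frame(gene = gn, p12 = as.numeric(p12), p3 = as.numeric(p3),
               sites12 = attr(p12, "sites"), sites3 = attr(p3, "sites"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-gene aligned coding sequences of a mitogenome
#'
#' Sense-codon sequences (stop codons excluded) of the 13 PCGs on their
#' coding strands, suitable for pairwise comparison between congeners
#' whose gene lengths match.
#'
#' @param g a [mitogenome()] with sequence and table.
#' @return Named character vector, one in-frame sequence per PCG.
#' @export
pcg_coding_sequences <- function(g) {
  f <- g$table$features
  pcg <- f[f$category == "PCG", , drop = FALSE]
  out <- vapply(seq_len(nrow(pcg)), function(i) {
    rec <- extract_coding_record(g, pcg[i, , drop = FALSE])
    paste(rec$codons, collapse = "")
  }, "")
  stats::setNames(out, pcg$name)
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)`; undefined (NA) for `p >= 3/4`.
#'
#' @param p proportion of differing sites.
#' @return Corrected distance.
#' @export
jc_correct <- function(p) {
  ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NA_real_)
}

#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Counts fractional synonymous (S) and nonsynonymous (N) sites per codon
#' from the fates of all single-base changes under the vertebrate
#' mitochondrial code (changes to stops count as nonsynonymous, so
#' `S + N = 3 * codons` exactly; S and N are averaged over the two
#' sequences). Codons differing at several positions are resolved by
#' averaging synonymous/nonsynonymous step counts over all minimal
#' substitution pathways, excluding pathways through stop codons. The
#' proportions `pS = Sd/S` and `pN = Nd/N` are Jukes-Cantor corrected to
#' Ks and Ka.
#'
#' @param a,b in-frame coding sequences (or codon vectors) of equal
#'   length with no internal stops.
#' @param gene optional gene label carried into the result.
#' @return A list of class `kaks_result`: `gene`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ratio`, `selection_class`, `flags`
#'   (character vector; e.g. saturation or undefined ratio).
#' @export
nei_gojobori <- function(a, b, gene = NA_character_) {
  tabs <- .ng_tables()
  if (length(a) == 1L) a <- split_codons(toupper(a))
  if (length(b) == 1L) b <- split_codons(toupper(b))
  if (length(a) != length(b)) stop("sequences differ in codon count")
  if (any(grepl("[^ACGT]", c(a, b)))) stop("non-ACGT codons not supported")
  if (any(a %in% .stop_codons) || any(b %in% .stop_codons))
    stop("internal stop codon in input")
  S <- (sum(tabs$syn[a]) + sum(tabs$syn[b])) / 2
  N <- 3 * length(a) - S
  idx <- which(a != b)
  Sd <- sum(tabs$sd[cbind(a[idx], b[idx])])
  Nd <- sum(tabs$nd[cbind(a[idx], b[idx])])
  pS <- Sd / S; pN <- Nd / N
  flags <- character(0)
  if (pS >= 0.75) flags <- c(flags, "pS_saturated")
  if (pN >= 0.75) flags <- c(flags, "pN_saturated")
  Ks <- jc_correct(pS); Ka <- jc_correct(pN)
  ratio <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  if (is.na(ratio)) flags <- c(flags, "ratio_undefined")
  res <- structure(list(gene = gene, S = S, N = N, Sd = Sd, Nd = Nd,
                        pS = pS, pN = pN, Ks = Ks, Ka = Ka, ratio = ratio,
                        selection_class = NA_character_, flags = flags),
                   class = "kaks_result")
  if (!is.na(ratio)) res$selection_class <- classify_selection(res)
  res
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86 %s: S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ka=%s Ks=%s Ka/Ks=%s (%s)\n",
              ifelse(is.na(x$gene), "", x$gene), x$S, x$N, x$Sd, x$Nd,
              format(x$Ka, digits = 4), format(x$Ks, digits = 4),
              format(x$ratio, digits = 4),
              ifelse(is.na(x$selection_class), "undefined", x$selection_class)))
  invisible(x)
}

#' Classify the selection regime from a Ka/Ks ratio
#'
#' Purifying for ratio < 1, neutral at 1 (within `tol`), positive above.
#'
#' @param r a `kaks_result` or a bare ratio.
#' @param tol half-width of the neutrality band around 1.
#' @return `"purifying"`, `"neutral"` or `"positive"`.
#' @export
classify_selection <- function(r, tol = 1e-9) {
  ratio <- if (inherits(r, "kaks_result")) r$ratio else r
  if (is.na(ratio)) stop("Ka/Ks ratio undefined; cannot classify")
  if (abs(ratio - 1) <= tol) "neutral"
  else if (ratio < 1) "purifying" else "positive"
}

#' Per-gene Ka/Ks over all genome pairs
#'
#' Runs [nei_gojobori()] for every gene and every unordered pair of
#' genomes, and summarizes the per-gene arithmetic mean ratio across
#' pairs.
#'
#' @param genomes named list of [mitogenome()]s with equal per-gene
#'   coding lengths.
#' @return A list with `pairs` (data frame: gene, pair, S, N, Sd, Nd, Ka,
#'   Ks, ratio, class) and `gene_means` (named mean ratio per gene,
#'   NA-dropped).
#' @export
kaks_table <- function(genomes) {
  stopifnot(length(genomes) >= 2L)
  cds <- lapply(genomes, pcg_coding_sequences)
  taxa <- names(genomes)
  rows <- list()
  for (i in seq_along(taxa)[-length(taxa)]) for (j in (i + 1):length(taxa)) {
    genes <- intersect(names(cds[[i]]), names(cds[[j]]))
    for (gn in genes) {
      r <- nei_gojobori(cds[[i]][[gn]], cds[[j]][[gn]], gene = gn)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gn, pair = paste(taxa[i], taxa[j], sep = "-"),
        S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, Ka = r$Ka, Ks = r$Ks,
        ratio = r$ratio, class = r$selection_class, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  gene_means <- vapply(split(pairs$ratio, pairs$gene),
                       function(x) mean(x, na.rm = TRUE), 0)
  list(pairs = pairs, gene_means = gene_means)
}
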