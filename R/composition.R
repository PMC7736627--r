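#' Base composition, A+T content and AT/GC skew
#'
#' Counts the unambiguous bases of a sequence and summarizes strand
#' asymmetry with the usual skew statistics:
#' \deqn{AT\text{-}skew = (A - T)/(A + T), \quad GC\text{-}skew = (G - C)/(G + C)}
#' A+T content is `100 * (A + T) / (A + C + G + T)`. IUPAC ambiguity codes
#' are excluded from all counts and from skew denominators and reported
#' separately in `n_ambiguous`. A skew whose denominator is zero is
#' undefined and reported as `NA`, never as 0.
#'
#' @param seq non-empty nucleotide string.
#' @return A list of class `composition_summary` with elements `counts`
#'   (named integer vector A/C/G/T), `n_ambiguous`, `at_content` (percent),
#'   `at_skew`, `gc_skew`.
#' @export
composition <- function(seq) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || !nzchar(seq)) stop("empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- c(A = sum(ch == "A"), C = sum(ch == "C"),
              G = sum(ch == "G"), T = sum(ch == "T"))
  n_amb <- length(ch) - sum(counts)
  at <- counts[["A"]] + counts[["T"]]
  gc <- counts[["G"]] + counts[["C"]]
  structure(list(
    counts = counts,
    n_ambiguous = as.integer(n_amb),
    at_content = if (at + gc > 0) 100 * at / (at + gc) else NA_real_,
    at_skew = if (at > 0) (counts[["A"]] - counts[["T"]]) / at else NA_real_,
    gc_skew = if (gc > 0) (counts[["G"]] - counts[["C"]]) / gc else NA_real_),
    class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("A=%d C=%d G=%d T=%d (ambiguous %d)\n",
              x$counts[["A"]], x$counts[["C"]], x$counts[["G"]],
              x$counts[["T"]], x$n_ambiguous))
  cat(sprintf("A+T%% = %.2f  AT-skew = %s  GC-skew = %s\n", x$at_content,
              format(x$at_skew, digits = 4), format(x$gc_skew, digits = 4)))
  invisible(x)
}

.comp_row <- function(label, seq) {
  s <- composition(seq)
  data.frame(label = label, A = s$counts[["A"]], C = s$counts[["C"]],
             G = s$counts[["G"]], T = s$counts[["T"]],
             n_ambiguous = s$n_ambiguous, at_content = s$at_content,
             at_skew = s$at_skew, gc_skew = s$gc_skew,
             stringsAsFactors = FALSE)
}

#' Composition summaries over genome partitions
#'
#' Computes one composition summary per element of the requested partition
#' of a mitogenome.
#'
#' Scopes:
#' \describe{
#'   \item{`whole`}{the full H-strand sequence.}
#'   \item{`category`}{one pooled summary per feature category (PCG, tRNA,
#'     rRNA, origin, control), H-strand substrings.}
#'   \item{`feature`}{one summary per feature, H-strand substrings.}
#'   \item{`codon-position`}{the 13 PCGs concatenated in table order on
#'     their coding strands (ND6 reverse-complemented), incomplete
#'     terminal stop bases (T/TA) excluded, complete stop codons kept,
#'     split into codon positions 1, 2 and 3.}
#' }
#'
#' @param g a [mitogenome()] with sequence and table.
#' @param scope partition scope, see Details.
#' @return A data frame with columns `label`, `A`, `C`, `G`, `T`,
#'   `n_ambiguous`, `at_content`, `at_skew`, `gc_skew`.
#' @export
partition_composition <- function(g, scope = c("whole", "category",
                                               "feature", "codon-position")) {
  scope <- match.arg(scope)
  if (is.null(g$sequence)) stop("mitogenome carries no sequence")
  f <- g$table$features
  rows <- switch(scope,
    "whole" = list(.comp_row("whole", g$sequence)),
    "category" = {
      lapply(unique(f$category), function(cat) {
        idx <- which(f$category == cat)
        seqs <- vapply(idx, function(i)
          extract_region(g, f[i, , drop = FALSE], orient = "h-strand"), "")
        .comp_row(cat, paste(seqs, collapse = ""))
      })
    },
    "feature" = {
      lapply(seq_len(nrow(f)), function(i)
        .comp_row(f$name[i], extract_region(g, f[i, , drop = FALSE],
                                            orient = "h-strand")))
    },
    "codon-position" = {
      cc <- concatenate_pcgs(g, trim_incomplete = TRUE)
      ch <- strsplit(cc, "", fixed = TRUE)[[1]]
      pos <- (seq_along(ch) - 1L) %% 3L + 1L
      lapply(1:3, function(p)
        .comp_row(sprintf("codon_position_%d", p),
                  paste(ch[pos == p], collapse = "")))
    })
  do.call(rbind, rows)
}

#' Concatenate the 13 protein-coding genes on their coding strands
#'
#' Genes are taken in table order, L-strand genes reverse-complemented.
#' With `trim_incomplete = TRUE` the trailing incomplete stop bases
#' (length mod 3 of 1 or 2) are dropped from each gene; complete terminal
#' codons are kept.
#'
#' @param g a [mitogenome()] with sequence and table.
#' @param trim_incomplete drop trailing incomplete stop bases per gene.
#' @return Single nucleotide string.
#' @export
concatenate_pcgs <- function(g, trim_incomplete = TRUE) {
  f <- g$table$features
  pcg <- f[f$category == "PCG", , drop = FALSE]
  if (!nrow(pcg)) stop("no PCG features in table")
  seqs <- vapply(seq_len(nrow(pcg)), function(i) {
    s <- extract_region(g, pcg[i, , drop = FALSE], orient = "as-annotated")
    if (trim_incomplete) {
      r <- nchar(s) %% 3L
      if (r > 0L) s <- substr(s, 1L, nchar(s) - r)
    }
    s
  }, "")
  paste(seqs, collapse = "")
}

#' Scan a sequence for an IUPAC motif
#'
#' Exact matching of a motif that may contain IUPAC ambiguity codes
#' (e.g. the conserved light-strand origin block `GCCGG`), on the strand
#' of the sequence as given.
#'
#' @param seq nucleotide string.
#' @param motif non-empty IUPAC pattern.
#' @return Integer vector of 1-based match start positions (possibly
#'   empty).
#' @export
motif_scan <- function(seq, motif) {
  motif <- toupper(as.character(motif))
  if (!nzchar(motif)) stop("motif must be non-empty")
  if (grepl("[^ACGTRYSWKMBDHVN]", motif))
    stop("invalid IUPAC symbol in motif: ", motif)
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(toupper(seq)),
                                   fixed = FALSE)
  as.integer(Biostrings::start(hits))
}
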