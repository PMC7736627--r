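## Vertebrate mitochondrial genetic code (NCBI transl_table 2):
## TGA = Trp, ATA = Met, AGA/AGG = stop. Stops are "*".
.mito_code <- NULL

mito_code <- function() {
  if (is.null(.mito_code))
    utils::assignInMyNamespace(".mito_code", Biostrings::getGeneticCode("2"))
  .mito_code
}

.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
          E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
          M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
          Y = "Tyr", V = "Val", `*` = "Stop")

#' Translate codons under the vertebrate mitochondrial code
#'
#' NCBI transl_table 2: TGA reads Trp, ATA reads Met, AGA/AGG are stops
#' (returned as `"*"`). Alternative initiators GTG and ATA at position 1
#' are translated as Met when `initiator = TRUE`. Triplets containing
#' non-ACGT characters translate to `"X"`.
#'
#' @param codons character vector of triplets.
#' @param initiator treat the first codon as the initiation codon.
#' @return Single amino-acid string (one-letter code).
#' @export
translate_mito <- function(codons, initiator = TRUE) {
  codons <- toupper(codons)
  if (any(nchar(codons) != 3L)) stop("codons must be triplets")
  code <- mito_code()
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (initiator && length(aa) && codons[1] %in% c("ATG", "GTG", "ATA", "ATT", "ATC"))
    aa[1] <- "M"
  paste(aa, collapse = "")
}

#' Split a nucleotide string into codons
#'
#' @param seq in-frame nucleotide string; length must be divisible by 3.
#' @return Character vector of triplets.
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

.stop_codons <- c("TAA", "TAG", "AGA", "AGG")

#' Extract the coding record of a protein-coding gene
#'
#' Reads a PCG on its coding strand from position 1 and resolves the
#' mitochondrial stop-codon convention: if the feature length mod 3 is 1
#' the trailing base is an incomplete stop (completed to TAA by
#' polyadenylation), if it is 2 the trailing dinucleotide is; otherwise
#' the final in-frame triplet must be a complete stop. Sense codons are
#' everything before the stop, initiation codon included, so
#' `3 * aa_length + nchar(stop_codon) == feature_size`.
#'
#' @param g a [mitogenome()] with sequence.
#' @param f a PCG feature row or canonical gene name.
#' @return A list of class `pcg_coding_record`: `gene`, `codons` (sense
#'   codons), `start_codon`, `stop_codon` (a triplet, `"TA"` or `"T"`),
#'   `aa_length`.
#' @export
extract_coding_record <- function(g, f) {
  if (is.character(f)) {
    i <- match(canonical_name(f), g$table$features$name)
    if (is.na(i)) stop("gene not in table: ", f)
    f <- g$table$features[i, , drop = FALSE]
  }
  if (!identical(f$category, "PCG")) stop(f$name, " is not a PCG")
  s <- extract_region(g, f, orient = "as-annotated")
  n <- nchar(s)
  r <- n %% 3L
  stop_codon <- if (r > 0L) substr(s, n - r + 1L, n) else ""
  body <- substr(s, 1L, n - r)
  codons <- split_codons(body)
  if (r == 0L) {
    last <- codons[length(codons)]
    if (last %in% .stop_codons) {
      stop_codon <- last
      codons <- codons[-length(codons)]
    } else {
      warning(f$name, ": no terminal stop codon found", call. = FALSE)
    }
  }
  internal <- which(codons %in% .stop_codons)
  if (length(internal))
    stop(sprintf("internal stop codon %s at codon %d of %s",
                 codons[internal[1]], internal[1], f$name))
  structure(list(gene = f$name, codons = codons, start_codon = codons[1],
                 stop_codon = stop_codon, aa_length = length(codons)),
            class = "pcg_coding_record")
}

#' Start/stop codon and length audit of all PCGs
#'
#' @param g a [mitogenome()] with sequence and table.
#' @return Data frame with one row per PCG: `gene`, `start_codon`,
#'   `stop_codon`, `aa_length`, `size`.
#' @export
start_stop_audit <- function(g) {
  f <- g$table$features
  pcg <- f[f$category == "PCG", , drop = FALSE]
  recs <- lapply(seq_len(nrow(pcg)), function(i)
    extract_coding_record(g, pcg[i, , drop = FALSE]))
  data.frame(gene = vapply(recs, `[[`, "", "gene"),
             start_codon = vapply(recs, `[[`, "", "start_codon"),
             stop_codon = vapply(recs, `[[`, "", "stop_codon"),
             aa_length = vapply(recs, `[[`, 0L, "aa_length"),
             size = feature_size(pcg), stringsAsFactors = FALSE)
}

# Synonymous-family map under transl_table 2. With split = TRUE the
# six-fold Leu and Ser families are split 2 + 4 by first-two-base class
# (UUR/CUN, AGY/UCN), matching how RSCU is usually plotted per tRNA family.
codon_families <- function(split = TRUE) {
  code <- mito_code()
  sense <- names(code)[code != "*"]
  lab <- unname(.aa3[code[sense]])
  if (split) {
    lab[sense %in% c("TTA", "TTG")] <- "Leu(UUR)"
    lab[substr(sense, 1, 2) == "CT"] <- "Leu(CUN)"
    lab[substr(sense, 1, 2) == "TC"] <- "Ser(UCN)"
    lab[sense %in% c("AGT", "AGC")] <- "Ser(AGY)"
  }
  split(sense, lab)
}

#' Tabulate codon usage over sense codons
#'
#' Builds the codon-count table feeding RSCU and amino-acid usage. Stop
#' codons are excluded from the counts and tallied separately.
#'
#' @param codons character vector of sense codons (e.g. pooled over the
#'   13 PCGs of one genome), or a list of `pcg_coding_record`s.
#' @param split_families split six-fold Leu/Ser into 2+4 sub-families
#'   (Leu(UUR)/Leu(CUN), Ser(UCN)/Ser(AGY)).
#' @return A list of class `codon_count_table`: `X` (named counts over
#'   all sense codons), `families` (list family label -> codon set),
#'   `total_codons`, `n_stop_excluded`.
#' @export
codon_count_table <- function(codons, split_families = TRUE) {
  if (is.list(codons) && !is.data.frame(codons))
    codons <- unlist(lapply(codons, function(r)
      if (inherits(r, "pcg_coding_record")) r$codons else r), use.names = FALSE)
  codons <- toupper(codons)
  bad <- grepl("[^ACGT]", codons) | nchar(codons) != 3L
  if (any(bad)) stop("non-ACGT or non-triplet codons in input")
  is_stop <- codons %in% .stop_codons
  fam <- codon_families(split_families)
  sense <- unlist(fam, use.names = FALSE)
  X <- stats::setNames(integer(length(sense)), sense)
  tab <- table(codons[!is_stop])
  X[names(tab)] <- as.integer(tab)
  structure(list(X = X, families = fam, total_codons = sum(X),
                 n_stop_excluded = sum(is_stop)),
            class = "codon_count_table")
}

#' Relative synonymous codon usage
#'
#' For codon *j* in a synonymous family *i* of size `n_i`,
#' \deqn{RSCU_{ij} = \frac{X_{ij}}{\bar X_i} = \frac{n_i X_{ij}}{\sum_j X_{ij}},}
#' the observed count over the family mean. RSCU sums to `n_i` within each
#' family with nonzero total; families never observed get RSCU 0 with
#' `undefined = TRUE`.
#'
#' @param cct a [codon_count_table()].
#' @return Data frame with columns `codon`, `family`, `count`, `rscu`,
#'   `undefined`, in family order.
#' @export
rscu <- function(cct) {
  stopifnot(inherits(cct, "codon_count_table"))
  rows <- lapply(names(cct$families), function(famname) {
    cods <- cct$families[[famname]]
    x <- cct$X[cods]
    tot <- sum(x)
    data.frame(codon = cods, family = famname, count = as.integer(x),
               rscu = if (tot > 0) length(cods) * x / tot else rep(0, length(cods)),
               undefined = tot == 0, stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Amino-acid usage counts
#'
#' Counts residues over the sense codons of a codon-count table. Leu and
#' Ser are reported both pooled and split into their tRNA families.
#'
#' @param cct a [codon_count_table()].
#' @return A list with `by_family` (named counts per synonymous family,
#'   split Leu/Ser when the table was built split) and `by_residue`
#'   (named counts per pooled residue, three-letter codes).
#' @export
aa_usage <- function(cct) {
  stopifnot(inherits(cct, "codon_count_table"))
  by_family <- vapply(cct$families, function(cods) sum(cct$X[cods]), 0L)
  code <- mito_code()
  resid <- unname(.aa3[code[names(cct$X)]])
  by_residue <- vapply(split(cct$X, resid), sum, 0L)
  list(by_family = by_family, by_residue = by_residue)
}

#' Codon usage of a whole mitogenome
#'
#' Extracts all 13 PCG coding records and pools their sense codons.
#'
#' @param g a [mitogenome()] with sequence and table.
#' @param split_families see [codon_count_table()].
#' @return A [codon_count_table()].
#' @export
codon_usage <- function(g, split_families = TRUE) {
  f <- g$table$features
  pcg <- f[f$category == "PCG", , drop = FALSE]
  recs <- lapply(seq_len(nrow(pcg)), function(i)
    extract_coding_record(g, pcg[i, , drop = FALSE]))
  codon_count_table(recs, split_families = split_families)
}
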