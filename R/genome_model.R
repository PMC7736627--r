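#' Construct a gene feature
#'
#' A gene feature is a single annotated element of a mitogenome: a gene,
#' rRNA, tRNA, replication origin or the control region, with 1-based
#' inclusive coordinates on the circular molecule and an H/L strand call.
#'
#' @param name element name; resolved against the canonical registry.
#' @param start,end 1-based inclusive coordinates, `end >= start >= 1`
#'   (no feature wraps the origin in this data model).
#' @param strand `"H"` (heavy) or `"L"` (light).
#' @param category one of `"PCG"`, `"tRNA"`, `"rRNA"`, `"origin"`,
#'   `"control"`; inferred from the registry when missing.
#' @param letter_code optional single-letter tRNA code.
#' @return A one-row data frame with class `gene_feature`.
#' @export
gene_feature <- function(name, start, end, strand = "H", category = NULL,
                         letter_code = NA_character_) {
  name <- canonical_name(name)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || start < 1L) stop("start must be >= 1")
  if (is.na(end) || end < start) stop("end must be >= start (no wrap-around features)")
  if (!strand %in% c("H", "L")) stop("strand must be 'H' or 'L'")
  reg <- canonical_elements()
  if (is.null(category)) {
    idx <- match(name, reg$name)
    if (is.na(idx)) stop("cannot infer category for unknown element: ", name)
    category <- reg$category[idx]
  }
  if (!category %in% c("PCG", "tRNA", "rRNA", "origin", "control"))
    stop("invalid category: ", category)
  idx <- match(name, reg$name)
  if (!is.na(idx) && reg$category[idx] != category)
    stop(sprintf("category '%s' inconsistent with canonical element '%s' (%s)",
                 category, name, reg$category[idx]))
  f <- data.frame(name = name, start = start, end = end, strand = strand,
                  category = category, letter_code = as.character(letter_code),
                  stringsAsFactors = FALSE)
  class(f) <- c("gene_feature", "data.frame")
  f
}

#' Construct a gene table
#'
#' The ordered feature table of one mitogenome (the in-memory analogue of a
#' published gene/element summary table). Features are sorted by start
#' coordinate; the genome length defaults to the maximum end coordinate,
#' which for a complete table equals the molecule length because the
#' control region is the last element.
#'
#' @param features data frame with columns `name`, `start`, `end`,
#'   `strand`, `category` (and optionally `letter_code`).
#' @param genome_length molecule length in bp; defaults to `max(end)`.
#' @return An object of class `gene_table`: a list with elements
#'   `features` (data frame in start order) and `genome_length`.
#' @export
gene_table <- function(features, genome_length = NULL) {
  stopifnot(is.data.frame(features))
  req <- c("name", "start", "end", "strand", "category")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("feature table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"letter_code" %in% names(features))
    features$letter_code <- rep(NA_character_, nrow(features))
  features <- features[, c(req, "letter_code"), drop = FALSE]
  features$name <- canonical_name(features$name)
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (nrow(features)) {
    if (any(features$start < 1L)) stop("all starts must be >= 1")
    if (any(features$end < features$start))
      stop("end < start for feature(s): ",
           paste(features$name[features$end < features$start], collapse = ", "))
    if (any(!features$strand %in% c("H", "L"))) stop("strand must be 'H' or 'L'")
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  if (is.null(genome_length)) {
    genome_length <- if (nrow(features)) max(features$end) else 0L
  }
  genome_length <- as.integer(genome_length)
  if (nrow(features) && genome_length < max(features$end))
    stop("genome_length smaller than last feature end")
  structure(list(features = features, genome_length = genome_length),
            class = "gene_table")
}

#' @export
print.gene_table <- function(x, ...) {
  cat(sprintf("gene_table: %d features, genome length %d bp\n",
              nrow(x$features), x$genome_length))
  rep <- validate_gene_complement(x)
  cat("complement:", paste(sprintf("%s=%d", names(rep$counts), rep$counts),
                           collapse = " "), "\n")
  invisible(x)
}

#' Construct a mitogenome
#'
#' Couples a circular nucleotide sequence with its gene table and metadata.
#' When both sequence and table are present their lengths must agree.
#'
#' @param sequence nucleotide string over A/C/G/T plus IUPAC ambiguity
#'   codes, or `NULL` for a table-only record.
#' @param table a [gene_table()].
#' @param species,accession free-text metadata.
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(sequence = NULL, table = NULL, species = NA_character_,
                       accession = NA_character_) {
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != 1L || !nzchar(sequence)) stop("sequence must be a single non-empty string")
    bad <- gsub("[ACGTRYSWKMBDHVN]", "", sequence)
    if (nzchar(bad)) stop("sequence contains non-IUPAC characters: ",
                          paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  if (!is.null(table)) {
    stopifnot(inherits(table, "gene_table"))
    if (!is.null(sequence) && nchar(sequence) != table$genome_length)
      stop(sprintf("sequence length (%d) != table genome_length (%d)",
                   nchar(sequence), table$genome_length))
  }
  structure(list(sequence = sequence, table = table,
                 species = species, accession = accession),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("mitogenome: %s (%s), %s bp, %d features\n",
              x$species, x$accession,
              if (is.null(x$sequence)) "no sequence" else nchar(x$sequence),
              if (is.null(x$table)) 0L else nrow(x$table$features)))
  invisible(x)
}

#' Feature size in bp
#'
#' Length of a feature under 1-based inclusive coordinates:
#' `end - start + 1`. Vectorized over the rows of a feature data frame.
#'
#' @param f a `gene_feature`, a feature data frame, or a [gene_table()].
#' @return Integer vector of sizes, named by feature.
#' @export
feature_size <- function(f) {
  if (inherits(f, "gene_table")) f <- f$features
  stats::setNames(as.integer(f$end - f$start + 1L), f$name)
}

#' Signed spacer between two adjacent features
#'
#' Number of bases strictly between two features in table order:
#' `start2 - end1 - 1`. Positive values are intergenic spacers, negative
#' values are overlaps of that magnitude, zero means contiguous.
#'
#' @param f1,f2 single features; `f1` must precede `f2` (`start1 <= start2`).
#' @return Integer signed spacer.
#' @export
intervening_spacer <- function(f1, f2) {
  if (f1$start > f2$start) stop("f1 must precede f2 in table order")
  as.integer(f2$start - f1$end - 1L)
}

#' Spacers between all adjacent feature pairs
#'
#' @param t a [gene_table()].
#' @return Integer vector of length `nrow - 1`, named
#'   `"<name1>|<name2>"`, of signed spacers between consecutive features.
#' @export
adjacent_spacers <- function(t) {
  f <- t$features
  if (nrow(f) < 2L) return(integer(0))
  sp <- as.integer(f$start[-1L] - f$end[-nrow(f)] - 1L)
  names(sp) <- paste(f$name[-nrow(f)], f$name[-1L], sep = "|")
  sp
}

#' Audit a gene table against the canonical 37-gene complement
#'
#' Counts features per category and reports which canonical elements are
#' missing or duplicated. A complete vertebrate mitogenome has 13 PCGs,
#' 22 tRNAs (two tRNA-Leu and two tRNA-Ser), 2 rRNAs, one replication
#' origin and one control region. This reports and never raises, so it is
#' safe on partial tables.
#'
#' @param t a [gene_table()].
#' @return A list with `counts` (named integer vector over the five
#'   categories), `n_genes` (PCG + tRNA + rRNA count), `missing`,
#'   `duplicated` (canonical names), and `complete` (logical).
#' @export
validate_gene_complement <- function(t) {
  f <- t$features
  cats <- c("PCG", "tRNA", "rRNA", "origin", "control")
  counts <- stats::setNames(integer(5), cats)
  tab <- table(factor(f$category, levels = cats))
  counts[names(tab)] <- as.integer(tab)
  reg <- canonical_elements()
  missing <- setdiff(reg$name, f$name)
  dup <- unique(f$name[duplicated(f$name)])
  complete <- length(missing) == 0L && length(dup) == 0L
  if (complete) {
    stopifnot(sum(grepl("^tRNA-Leu", f$name)) == 2L,
              sum(grepl("^tRNA-Ser", f$name)) == 2L)
  }
  list(counts = counts, n_genes = sum(counts[c("PCG", "tRNA", "rRNA")]),
       missing = missing, duplicated = dup, complete = complete)
}

#' Reverse complement of a nucleotide string
#'
#' @param seq nucleotide string (IUPAC codes allowed).
#' @return The reverse complement, as a plain string.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the sequence of a feature
#'
#' Returns the 1-based inclusive substring `[start, end]`. With
#' `orient = "as-annotated"` (default) L-strand features are
#' reverse-complemented so the result reads 5'->3' on the coding strand;
#' `orient = "h-strand"` always returns the heavy-strand substring.
#'
#' @param g a [mitogenome()] with sequence.
#' @param f a single feature (one-row data frame with `start`, `end`,
#'   `strand`) or a canonical element name looked up in `g`'s table.
#' @param orient `"as-annotated"` or `"h-strand"`.
#' @return Nucleotide string.
#' @export
extract_region <- function(g, f, orient = c("as-annotated", "h-strand")) {
  orient <- match.arg(orient)
  if (is.null(g$sequence)) stop("mitogenome carries no sequence")
  if (is.character(f)) {
    nm <- canonical_name(f)
    i <- match(nm, g$table$features$name)
    if (is.na(i)) stop("feature not in table: ", f)
    f <- g$table$features[i, , drop = FALSE]
  }
  if (f$end > nchar(g$sequence)) stop("feature coordinates exceed genome length")
  s <- substr(g$sequence, f$start, f$end)
  if (orient == "as-annotated" && identical(f$strand, "L")) s <- reverse_complement(s)
  s
}

# ---- file I/O ---------------------------------------------------------------

#' Read a feature table
#'
#' Reads either the package's TSV dialect (header
#' `name  start  end  strand  category  letter_code`, extra columns
#' ignored) or a minimal GenBank flat-file dialect (LOCUS/FEATURES/ORIGIN
#' with CDS, tRNA, rRNA, D-loop and rep_origin keys; `+/-` feature
#' locations map to H/L).
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"genbank"`.
#' @return A [gene_table()].
#' @export
read_feature_table <- function(path, dialect = c("tsv", "genbank")) {
  dialect <- match.arg(dialect)
  if (dialect == "genbank") return(read_genbank(path)$table)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("name", "start", "end", "strand", "category")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("malformed feature TSV (", path, "): missing column(s) ",
         paste(miss, collapse = ", "))
  bad <- which(is.na(suppressWarnings(as.integer(d$start))) |
               is.na(suppressWarnings(as.integer(d$end))))
  if (length(bad))
    stop(sprintf("parse error in %s: non-integer coordinates at data line %d",
                 path, bad[1]))
  unknown <- setdiff(canonical_name(d$name), canonical_elements()$name)
  if (length(unknown))
    warning("unknown element name(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  gene_table(d[, c(req, intersect("letter_code", names(d)))])
}

#' Write a feature table as TSV
#'
#' @param t a [gene_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path) {
  utils::write.table(t$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a mitogenome FASTA
#'
#' @param path FASTA file with one or more records.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

# GenBank feature keys for each category of the data model.
.gb_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
             origin = "rep_origin", control = "D-loop")

#' Write a mitogenome as a minimal GenBank flat file
#'
#' Emits LOCUS, FEATURES and ORIGIN blocks. PCGs become CDS features with
#' `/transl_table=2`; L-strand features use `complement(start..end)`
#' locations; every feature carries `/product` with the canonical name.
#'
#' @param g a [mitogenome()] with sequence and table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(g, path) {
  if (is.null(g$sequence) || is.null(g$table)) stop("need sequence and table")
  con <- file(path, "w"); on.exit(close(con))
  len <- nchar(g$sequence)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular VRT",
                     ifelse(is.na(g$accession), "UNKNOWN", g$accession), len), con)
  writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                     ifelse(is.na(g$species), "unknown organism", g$species)), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  writeLines(sprintf("                     /organism=\"%s\"",
                     ifelse(is.na(g$species), "unknown", g$species)), con)
  f <- g$table$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "L") loc <- sprintf("complement(%s)", loc)
    key <- .gb_key[[f$category[i]]]
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf("                     /product=\"%s\"", f$name[i]), con)
    if (f$category[i] == "PCG")
      writeLines("                     /transl_table=2", con)
  }
  writeLines("ORIGIN", con)
  for (off in seq(1L, len, by = 60L)) {
    chunk <- substr(g$sequence, off, min(off + 59L, len))
    grp <- gsub("(.{10})", "\\1 ", tolower(chunk))
    writeLines(sprintf("%9d %s", off, trimws(grp)), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a minimal GenBank flat file
#'
#' Parses the dialect written by [write_genbank()]: feature keys CDS,
#' tRNA, rRNA, rep_origin and D-loop, simple and `complement()` locations,
#' `/product` qualifiers, and the ORIGIN sequence block.
#'
#' @param path GenBank file path.
#' @return A [mitogenome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  sp <- NA_character_; acc <- NA_character_
  m <- grep("^LOCUS", lines, value = TRUE)
  if (length(m)) acc <- strsplit(trimws(sub("^LOCUS", "", m[1])), "\\s+")[[1]][1]
  m <- grep("/organism=", lines, value = TRUE)
  if (length(m)) sp <- sub('.*/organism="([^"]*)".*', "\\1", m[1])
  key2cat <- stats::setNames(names(.gb_key), unname(.gb_key))
  feat <- list()
  i <- 1L
  while (i <= length(lines)) {
    ln <- lines[i]
    mm <- regmatches(ln, regexec(
      "^     (CDS|tRNA|rRNA|rep_origin|D-loop)\\s+(complement\\()?(\\d+)\\.\\.(\\d+)\\)?", ln))[[1]]
    if (length(mm)) {
      prod <- NA_character_
      j <- i + 1L
      while (j <= length(lines) && grepl("^                     /", lines[j])) {
        if (grepl("/product=", lines[j]))
          prod <- sub('.*/product="([^"]*)".*', "\\1", lines[j])
        j <- j + 1L
      }
      if (is.na(prod)) stop("GenBank feature at line ", i, " lacks /product")
      feat[[length(feat) + 1L]] <- data.frame(
        name = prod, start = as.integer(mm[4]), end = as.integer(mm[5]),
        strand = if (nzchar(mm[3])) "L" else "H",
        category = key2cat[[mm[2]]], letter_code = NA_character_,
        stringsAsFactors = FALSE)
      i <- j
    } else i <- i + 1L
  }
  o <- grep("^ORIGIN", lines)
  seq <- NULL
  if (length(o)) {
    body <- lines[(o[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^a-zA-Z]", "", paste(body, collapse = "")))
    if (!nzchar(seq)) seq <- NULL
  }
  tab <- if (length(feat)) gene_table(do.call(rbind, feat)) else NULL
  mitogenome(sequence = seq, table = tab, species = sp, accession = acc)
}

# ---- bundled study tables ---------------------------------------------------

#' Published annotation tables for the three Sebastiscus mitogenomes
#'
#' Returns the bundled gene/element table for one of the three rockfish
#' mitogenomes as printed in the study's feature summary: coordinates,
#' strand, category, plus the printed size, intervening-spacer,
#' amino-acid-count, and start/stop-codon columns (`*_printed` columns are
#' reproduced verbatim, including the handful of size cells that disagree
#' with their own coordinates; see the methods vignette).
#'
#' @param species `"ST"` (*S. tertius*, MT117231), `"SA"`
#'   (*S. albofasciatus*, MT117230) or `"SM"` (*S. marmoratus*, MT789709).
#' @return A data frame with one row per element in genome order.
#' @export
rockfish_annotation <- function(species = c("ST", "SA", "SM")) {
  species <- match.arg(species)
  path <- system.file("extdata", sprintf("feature_table_%s.tsv", species),
                      package = "mitocomp", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}

#' Gene table for one of the three Sebastiscus mitogenomes
#'
#' @inheritParams rockfish_annotation
#' @return A [gene_table()] built from the bundled annotation coordinates.
#' @export
rockfish_gene_table <- function(species = c("ST", "SA", "SM")) {
  gene_table(rockfish_annotation(species))
}
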