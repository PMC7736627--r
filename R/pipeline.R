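#' Run the comparative-mitogenomics pipeline
#'
#' Orchestrates the analysis stages in dependency order — feature-table
#' accounting, composition/codon usage, divergence (p-distances and
#' Ka/Ks), control-region repeats, and the concatenated-PCG tree — over a
#' set of genomes, and returns (optionally writes) a combined report.
#' Stages that need sequence are skipped with a notice for table-only
#' genomes.
#'
#' @param genomes named list of [mitogenome()]s.
#' @param stages subset of `c("model", "composition", "codon",
#'   "divergence", "repeats", "tree")`.
#' @param out_dir if non-NULL, per-stage TSVs and a JSON summary are
#'   written there.
#' @param seed integer seed (bootstrap resampling).
#' @param bootstrap_reps NJ bootstrap replicates for the tree stage.
#' @param constraints optional list of taxon sets checked against the
#'   tree (see [check_constraints()]).
#' @param repeat_params list of overrides for [find_tandem_repeats()].
#' @return A report list with one element per executed stage plus
#'   `schema_version`, `seed` and `skipped`.
#' @export
run_pipeline <- function(genomes,
                         stages = c("model", "composition", "codon",
                                    "divergence", "repeats", "tree"),
                         out_dir = NULL, seed = 1L, bootstrap_reps = 100L,
                         constraints = NULL, repeat_params = list()) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (length(genomes) < 1L) stop("need at least one genome")
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g)
      ifelse(is.na(g$species), "genome", g$species), "")
  has_seq <- all(vapply(genomes, function(g) !is.null(g$sequence), NA))
  report <- list(schema_version = "1.0", seed = as.integer(seed),
                 skipped = character(0))

  if ("model" %in% stages) {
    report$model <- lapply(genomes, function(g) {
      comp <- validate_gene_complement(g$table)
      list(genome_length = g$table$genome_length,
           counts = as.list(comp$counts), n_genes = comp$n_genes,
           complete = comp$complete,
           sizes = as.list(feature_size(g$table)),
           spacers = as.list(adjacent_spacers(g$table)))
    })
  }
  need_seq <- intersect(stages, c("composition", "codon", "divergence",
                                  "repeats", "tree"))
  if (!has_seq && length(need_seq)) {
    message("sequence absent: skipping stage(s) ",
            paste(need_seq, collapse = ", "))
    report$skipped <- need_seq
    need_seq <- character(0)
  }
  if ("composition" %in% need_seq) {
    report$composition <- lapply(genomes, function(g) list(
      whole = partition_composition(g, "whole"),
      category = partition_composition(g, "category"),
      codon_position = partition_composition(g, "codon-position")))
  }
  if ("codon" %in% need_seq) {
    report$codon <- lapply(genomes, function(g) {
      cct <- codon_usage(g)
      list(audit = start_stop_audit(g), rscu = rscu(cct),
           aa_usage = aa_usage(cct)$by_family,
           total_codons = cct$total_codons)
    })
  }
  if ("divergence" %in% need_seq) {
    if (length(genomes) >= 2L) {
      kk <- kaks_table(genomes)
      taxa <- names(genomes)
      dist_rows <- list()
      for (i in seq_along(taxa)[-length(taxa)]) for (j in (i + 1):length(taxa)) {
        pd <- codon_partition_distances(pcg_coding_sequences(genomes[[i]]),
                                        pcg_coding_sequences(genomes[[j]]))
        pd$pair <- paste(taxa[i], taxa[j], sep = "-")
        dist_rows[[length(dist_rows) + 1L]] <- pd
      }
      report$divergence <- list(p_distances = do.call(rbind, dist_rows),
                                kaks = kk$pairs,
                                kaks_gene_means = as.list(kk$gene_means))
    } else {
      message("divergence stage needs >= 2 genomes; skipped")
      report$skipped <- c(report$skipped, "divergence")
    }
  }
  if ("repeats" %in% need_seq) {
    report$repeats <- lapply(genomes, function(g)
      do.call(repeat_report, c(list(g), repeat_params)))
  }
  if ("tree" %in% need_seq) {
    if (length(genomes) < 3L)
      stop("tree stage requires >= 3 taxa, got ", length(genomes))
    sm <- build_supermatrix(genomes)
    bs <- bootstrap_support(sm, reps = bootstrap_reps, seed = seed)
    report$tree <- list(newick = ape::write.tree(bs$tree),
                        supports = as.list(bs$supports),
                        width = nchar(sm$alignment[[1]]))
    if (!is.null(constraints))
      report$tree$constraints <- as.list(check_constraints(bs$tree, constraints))
  }
  if (!is.null(out_dir)) .write_report(report, genomes, out_dir)
  report
}

.write_report <- function(report, genomes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# mitocomp %s",
                 as.character(utils::packageVersion("mitocomp")))
  put <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
    path
  }
  if (!is.null(report$composition))
    put(do.call(rbind, lapply(names(report$composition), function(nm) {
      d <- report$composition[[nm]]$category; d$taxon <- nm; d
    })), "composition.tsv")
  if (!is.null(report$codon))
    put(do.call(rbind, lapply(names(report$codon), function(nm) {
      d <- report$codon[[nm]]$audit; d$taxon <- nm; d
    })), "codon_audit.tsv")
  if (!is.null(report$divergence)) {
    put(report$divergence$p_distances, "p_distances.tsv")
    put(report$divergence$kaks, "kaks.tsv")
  }
  if (!is.null(report$repeats))
    put(do.call(rbind, lapply(names(report$repeats), function(nm) {
      d <- report$repeats[[nm]]
      if (nrow(d)) d$taxon <- nm
      d
    })), "repeats.tsv")
  if (!is.null(report$tree))
    writeLines(c(hdr, report$tree$newick), file.path(out_dir, "tree.nwk"))
  jsonlite::write_json(report, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}
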