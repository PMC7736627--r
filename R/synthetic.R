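## Synthetic circular mitogenomes with the canonical 39-element layout,
## stop-free ORFs under the vertebrate mitochondrial code, a planted
## control-region tandem repeat, a conserved GCCGG block in the
## replication origin, and codon-level evolution along a tree with
## per-gene dN/dS — plus a ground-truth ledger sufficient to recheck
## every downstream statistic without re-simulation.

# Stop-codon conventions of the S. tertius column: which genes end in an
# incomplete stop and which complete stop each of the others uses.
.default_stops <- c(
  ND1 = "TAG", ND2 = "TA", COI = "TAA", COII = "T", ATP8 = "TAA",
  ATP6 = "TA", COIII = "TA", ND3 = "T", ND4L = "TAA", ND4 = "T",
  ND5 = "TAA", ND6 = "TAG", CYTB = "T")

.default_starts <- c(
  ND1 = "ATG", ND2 = "ATG", COI = "GTG", COII = "ATG", ATP8 = "ATG",
  ATP6 = "ATG", COIII = "ATG", ND3 = "ATG", ND4L = "ATG", ND4 = "ATG",
  ND5 = "ATG", ND6 = "ATG", CYTB = "ATG")

#' Default per-gene dN/dS for the simulator
#'
#' Strong purifying selection across all 13 PCGs, strongest on ND3, ATP6
#' and CYTB and weakest on ND2 and ATP8, mirroring the relative ordering
#' reported for the rockfish congeners.
#'
#' @return Named numeric vector over the 13 PCGs.
#' @export
default_omega <- function() c(
  ND1 = 0.05, ND2 = 0.135, COI = 0.02, COII = 0.03, ATP8 = 0.188,
  ATP6 = 0.014, COIII = 0.02, ND3 = 0.013, ND4L = 0.05, ND4 = 0.05,
  ND5 = 0.05, ND6 = 0.06, CYTB = 0.014)

#' Simulation configuration
#'
#' @param seed integer seed; all randomness derives from it.
#' @param tree Newick text or `ape::phylo` with branch lengths in
#'   proposed substitutions/site.
#' @param omega per-PCG dN/dS (scalar or named vector), > 0; the
#'   probability that a nonsynonymous proposal is accepted.
#' @param kappa transition/transversion rate ratio of the HKY mutation
#'   proposal process.
#' @param target_at_content genome A+T percent in (0, 100).
#' @param target_at_skew target (A-T)/(A+T), |skew| < 1.
#' @param target_gc_skew target (G-C)/(G+C), |skew| < 1.
#' @param repeat_spec `list(period, copies, noise)` for the planted
#'   control-region tandem repeat, or `NULL` for a repeat-free D-loop.
#' @param gene_length_profile named sizes (bp) of the 39 elements;
#'   default: the *S. tertius* column of the bundled annotation.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              tree = "((tertius:0.04,albofasciatus:0.04):0.02,marmoratus:0.06);",
                              omega = default_omega(),
                              kappa = 4,
                              target_at_content = 55,
                              target_at_skew = 0.1,
                              target_gc_skew = -0.25,
                              repeat_spec = list(period = 22L, copies = 6, noise = 0.02),
                              gene_length_profile = NULL) {
  stopifnot(all(omega > 0), kappa > 0,
            target_at_content > 0, target_at_content < 100,
            abs(target_at_skew) < 1, abs(target_gc_skew) < 1)
  if (!is.null(repeat_spec))
    stopifnot(repeat_spec$period >= 1, repeat_spec$copies >= 1,
              repeat_spec$noise >= 0, repeat_spec$noise < 0.5)
  if (is.null(gene_length_profile)) {
    ann <- rockfish_annotation("ST")
    gene_length_profile <- stats::setNames(ann$end - ann$start + 1L, ann$name)
  }
  om <- default_omega()
  if (length(omega) == 1L && is.null(names(omega))) {
    om[] <- omega
  } else {
    om[names(omega)] <- omega
  }
  structure(list(seed = as.integer(seed), tree = tree, omega = om,
                 kappa = kappa, target_at_content = target_at_content,
                 target_at_skew = target_at_skew,
                 target_gc_skew = target_gc_skew,
                 repeat_spec = repeat_spec,
                 gene_length_profile = gene_length_profile),
            class = "sim_config")
}

# Stationary base probabilities implied by the composition targets.
.base_probs <- function(cfg) {
  at <- cfg$target_at_content / 100
  gc <- 1 - at
  c(A = at * (1 + cfg$target_at_skew) / 2,
    C = gc * (1 - cfg$target_gc_skew) / 2,
    G = gc * (1 + cfg$target_gc_skew) / 2,
    T = at * (1 - cfg$target_at_skew) / 2)
}

# Sense-codon sampling distribution: independent positions under tilted
# base probabilities, stop codons excluded. Excluding the four A/G-rich
# stop codons shifts the marginal base composition, so the per-position
# probabilities are calibrated iteratively until the marginal of the
# sense-codon distribution matches the composition targets.
.sense_codon_probs <- function(pi) {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(p1 = bases, p2 = bases, p3 = bases,
                      stringsAsFactors = FALSE)
  cods <- paste0(grid$p1, grid$p2, grid$p3)
  keep <- !cods %in% .stop_codons
  pic <- pi
  for (it in 1:50) {
    pr <- pic[grid$p1] * pic[grid$p2] * pic[grid$p3]
    pr[!keep] <- 0
    pr <- pr / sum(pr)
    marg <- (vapply(bases, function(b) sum(pr[grid$p1 == b]), 0) +
             vapply(bases, function(b) sum(pr[grid$p2 == b]), 0) +
             vapply(bases, function(b) sum(pr[grid$p3 == b]), 0)) / 3
    if (max(abs(marg - pi)) < 1e-10) break
    pic <- pic * pi / marg
    pic <- pic / sum(pic)
  }
  stats::setNames(pr[keep] / sum(pr[keep]), cods[keep])
}

.sample_bases <- function(n, pi) {
  if (n == 0L) return(character(0))
  sample(names(pi), n, replace = TRUE, prob = pi)
}

#' Generate the root synthetic mitogenome
#'
#' Builds the canonical 39-element layout at the configured sizes
#' (adjacent elements are contiguous or separated by the published
#' non-negative spacers; overlaps are not modelled, see the vignette),
#' with: stop-free ORFs under the vertebrate mitochondrial code using the
#' published start/stop conventions (COI starts GTG, seven genes carry
#' incomplete stops), exactly one GCCGG block inside the replication
#' origin, the configured tandem repeat planted in the control region,
#' and all remaining positions drawn i.i.d. from the composition targets.
#'
#' @param cfg a [simulation_config()].
#' @return A list: `genome` (a [mitogenome()]) and `ledger` (ground
#'   truth: planted repeat coordinates, base-probability targets, seed).
#' @export
generate_root_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  pi <- .base_probs(cfg)
  codp <- .sense_codon_probs(pi)
  # composition bias is modelled as a property of the genome strand, so
  # L-strand genes draw codons whose reverse complement matches pi
  pi_comp <- stats::setNames(pi[c("T", "G", "C", "A")], c("A", "C", "G", "T"))
  codp_l <- .sense_codon_probs(pi_comp)
  sense_codons <- names(codp)

  ann <- rockfish_annotation("ST")
  sizes <- cfg$gene_length_profile[ann$name]
  if (any(is.na(sizes))) stop("gene_length_profile must name all 39 elements")
  spacers <- pmax(ifelse(is.na(ann$spacer_printed), 0L, ann$spacer_printed), 0L)
  starts <- integer(nrow(ann)); ends <- integer(nrow(ann))
  pos <- 1L
  for (i in seq_len(nrow(ann))) {
    starts[i] <- pos
    ends[i] <- pos + sizes[[i]] - 1L
    pos <- ends[i] + 1L + if (i < nrow(ann)) spacers[i] else 0L
  }
  L <- ends[nrow(ann)]
  genome <- .sample_bases(L, pi)

  repeat_truth <- NULL
  for (i in seq_len(nrow(ann))) {
    nm <- ann$name[i]; cat_i <- ann$category[i]
    span <- starts[i]:ends[i]
    size <- sizes[[i]]
    if (cat_i == "PCG") {
      stop_c <- .default_stops[[nm]]
      nsense <- if (nchar(stop_c) == 3L) size %/% 3L - 1L
                else (size - nchar(stop_c)) %/% 3L
      prb <- if (ann$strand[i] == "L") codp_l else codp
      cods <- c(.default_starts[[nm]],
                sample(sense_codons, nsense - 1L, replace = TRUE, prob = prb))
      coding <- paste0(paste(cods, collapse = ""), stop_c)
      stopifnot(nchar(coding) == size)
      if (ann$strand[i] == "L") coding <- reverse_complement(coding)
      genome[span] <- strsplit(coding, "")[[1]]
    } else if (nm == "OL") {
      repeat {
        s <- .sample_bases(size, pi)
        off <- max(1L, size - 9L)
        s[off:(off + 4L)] <- c("G", "C", "C", "G", "G")
        if (length(motif_scan(paste(s, collapse = ""), "GCCGG")) == 1L) break
      }
      genome[span] <- s
    } else if (nm == "D-loop" && !is.null(cfg$repeat_spec)) {
      rs <- cfg$repeat_spec
      alen <- as.integer(round(rs$period * rs$copies))
      if (alen > size) stop("repeat array does not fit in the control region")
      unit <- .sample_bases(rs$period, pi)
      arr <- rep(unit, length.out = alen)
      noisy <- stats::runif(alen) < rs$noise
      if (any(noisy))
        arr[noisy] <- vapply(arr[noisy], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      maxoff <- size - alen
      off <- if (maxoff > 0) sample.int(maxoff, 1L) else 0L
      genome[span[(off + 1L):(off + alen)]] <- arr
      repeat_truth <- list(period = rs$period, copies = rs$copies,
                           noise = rs$noise, unit = paste(unit, collapse = ""),
                           start_in_region = off + 1L,
                           start_in_genome = starts[i] + off,
                           length = alen)
    }
  }

  tab <- gene_table(data.frame(
    name = ann$name, start = starts, end = ends, strand = ann$strand,
    category = ann$category, letter_code = ann$letter_code,
    stringsAsFactors = FALSE))
  g <- mitogenome(paste(genome, collapse = ""), tab,
                  species = "synthetic root", accession = "SYN000000")
  ledger <- list(seed = cfg$seed, base_probs = as.list(pi),
                 target_at_content = cfg$target_at_content,
                 target_at_skew = cfg$target_at_skew,
                 target_gc_skew = cfg$target_gc_skew,
                 planted_repeat = repeat_truth)
  list(genome = g, ledger = ledger)
}

# Per-site map of the root layout: 0 for non-coding/RNA sites, else the
# PCG row index; start codons and (possibly incomplete) stops are frozen
# so leaf genomes keep the published start/stop conventions.
.site_map <- function(tab) {
  f <- tab$features
  L <- tab$genome_length
  gene <- integer(L)
  frozen <- logical(L)
  pcg <- which(f$category == "PCG")
  info <- list()
  for (k in seq_along(pcg)) {
    i <- pcg[k]
    span <- f$start[i]:f$end[i]
    gene[span] <- k
    size <- length(span)
    stop_len <- size %% 3L
    if (stop_len == 0L) stop_len <- 3L
    if (f$strand[i] == "H") {
      frozen[f$start[i]:(f$start[i] + 2L)] <- TRUE
      frozen[(f$end[i] - stop_len + 1L):f$end[i]] <- TRUE
    } else {
      frozen[(f$end[i] - 2L):f$end[i]] <- TRUE
      frozen[f$start[i]:(f$start[i] + stop_len - 1L)] <- TRUE
    }
    info[[k]] <- list(name = f$name[i], start = f$start[i], end = f$end[i],
                      strand = f$strand[i])
  }
  list(gene = gene, frozen = frozen, info = info)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")
.transition <- c(A = "G", G = "A", C = "T", T = "C")

# HKY single-base proposal: weight pi_y * kappa for the transition, pi_y
# for transversions.
.propose_base <- function(x, pi, kappa) {
  targets <- setdiff(c("A", "C", "G", "T"), x)
  w <- pi[targets]
  w[.transition[[x]]] <- w[.transition[[x]]] * kappa
  sample(targets, 1L, prob = w)
}

# Evolve one genome character vector along one branch; returns the new
# vector plus per-gene accepted syn/nonsyn counts.
.mutate_branch <- function(ch, t, map, pi, kappa, omega) {
  L <- length(ch)
  code <- mito_code()
  nprop <- stats::rpois(1L, t * L)
  ngene <- length(map$info)
  syn <- integer(ngene); nonsyn <- integer(ngene)
  if (nprop == 0L)
    return(list(ch = ch, syn = syn, nonsyn = nonsyn, proposals = 0L))
  sites <- sample.int(L, nprop, replace = TRUE)
  for (s in sites) {
    if (map$frozen[s]) next
    x <- ch[s]
    y <- .propose_base(x, pi, kappa)
    k <- map$gene[s]
    if (k == 0L) { ch[s] <- y; next }
    gi <- map$info[[k]]
    if (gi$strand == "H") {
      cp <- s - gi$start + 1L
      ci <- (cp - 1L) %/% 3L
      cod_sites <- gi$start + 3L * ci + 0:2
    } else {
      cp <- gi$end - s + 1L
      ci <- (cp - 1L) %/% 3L
      cod_sites <- gi$end - 3L * ci - (0:2)
    }
    old_cod <- ch[cod_sites]
    new_cod <- old_cod
    new_cod[cod_sites == s] <- y
    if (gi$strand == "L") {
      old_cod <- .complement[old_cod]
      new_cod <- .complement[new_cod]
    }
    oc <- paste(old_cod, collapse = ""); nc <- paste(new_cod, collapse = "")
    if (code[[nc]] == "*") next
    if (code[[nc]] == code[[oc]]) {
      ch[s] <- y; syn[k] <- syn[k] + 1L
    } else if (stats::runif(1L) < omega[[gi$name]]) {
      ch[s] <- y; nonsyn[k] <- nonsyn[k] + 1L
    }
  }
  list(ch = ch, syn = syn, nonsyn = nonsyn, proposals = nprop)
}

#' Evolve a root genome along a tree
#'
#' Codon-level rejection sampling: single-base HKY proposals arrive as a
#' Poisson process at `branch_length * genome_length` per branch;
#' proposals inside PCGs are accepted if synonymous, accepted with
#' probability the gene's dN/dS if nonsynonymous, and always rejected if
#' they would create a stop codon; non-coding and RNA sites accept every
#' proposal. Start and stop codons are invariant. Every accepted coding
#' event is recorded per branch and per gene in the ledger. Each branch
#' uses a deterministic substream seed derived from the configuration
#' seed, so runs are exactly reproducible.
#'
#' @param root result of [generate_root_genome()] (or its `$genome`).
#' @param cfg the [simulation_config()] used to generate it.
#' @return A list: `genomes` (named list of leaf [mitogenome()]s),
#'   `tree` (the `ape::phylo` used) and `ledger` (ground truth incl.
#'   per-branch realized substitution counts).
#' @export
evolve_on_tree <- function(root, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base_ledger <- NULL
  if (!inherits(root, "mitogenome")) {
    base_ledger <- root$ledger
    root <- root$genome
  }
  tr <- if (inherits(cfg$tree, "phylo")) cfg$tree
        else ape::read.tree(text = cfg$tree)
  if (is.null(tr) || ape::Ntip(tr) < 2L) stop("tree must have >= 2 leaves")
  pi <- .base_probs(cfg)
  map <- .site_map(root$table)
  gene_names <- vapply(map$info, `[[`, "", "name")

  tr <- ape::reorder.phylo(tr, "cladewise")
  nnode <- ape::Ntip(tr) + tr$Nnode
  seqs <- vector("list", nnode)
  rootnode <- ape::Ntip(tr) + 1L
  seqs[[rootnode]] <- strsplit(root$sequence, "")[[1]]
  branch_records <- list()
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; chd <- tr$edge[e, 2L]
    set.seed(as.integer((as.numeric(cfg$seed) * 1009 + 97 * e) %% 2147483647))
    res <- .mutate_branch(seqs[[par]], tr$edge.length[e], map, pi,
                          cfg$kappa, cfg$omega)
    seqs[[chd]] <- res$ch
    branch_records[[e]] <- list(
      edge = e, parent = par, child = chd, length = tr$edge.length[e],
      proposals = res$proposals,
      syn = stats::setNames(as.list(res$syn), gene_names),
      nonsyn = stats::setNames(as.list(res$nonsyn), gene_names))
  }
  leaves <- stats::setNames(lapply(seq_len(ape::Ntip(tr)), function(i)
    mitogenome(paste(seqs[[i]], collapse = ""), root$table,
               species = tr$tip.label[i],
               accession = sprintf("SYN%06d", i))), tr$tip.label)
  ledger <- c(base_ledger,
              list(tree = ape::write.tree(tr), branches = branch_records))
  list(genomes = leaves, tree = tr, ledger = ledger)
}

#' Evolve a bare codon sequence under rejection sampling
#'
#' The same codon-level process as [evolve_on_tree()] restricted to one
#' coding sequence: Poisson(`t * 3 * codons`) HKY proposals, synonymous
#' changes accepted, nonsynonymous accepted with probability `omega`,
#' stop-creating changes rejected.
#'
#' @param codons character vector of sense codons.
#' @param t branch length (proposed substitutions/site).
#' @param omega dN/dS acceptance probability.
#' @param kappa transition/transversion ratio of the proposal process.
#' @param pi stationary base probabilities (named A/C/G/T).
#' @return A list: `codons` (evolved), `n_syn`, `n_nonsyn` (accepted
#'   counts).
#' @export
evolve_codon_sequence <- function(codons, t, omega, kappa = 1,
                                  pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  code <- mito_code()
  ch <- strsplit(paste(codons, collapse = ""), "")[[1]]
  L <- length(ch)
  nprop <- stats::rpois(1L, t * L)
  n_syn <- 0L; n_nonsyn <- 0L
  if (nprop > 0L) for (s in sample.int(L, nprop, replace = TRUE)) {
    y <- .propose_base(ch[s], pi, kappa)
    ci <- (s - 1L) %/% 3L
    cs <- 3L * ci + 1:3
    oldc <- paste(ch[cs], collapse = "")
    newv <- ch[cs]; newv[cs == s] <- y
    newc <- paste(newv, collapse = "")
    if (code[[newc]] == "*") next
    if (code[[newc]] == code[[oldc]]) {
      ch[s] <- y; n_syn <- n_syn + 1L
    } else if (stats::runif(1L) < omega) {
      ch[s] <- y; n_nonsyn <- n_nonsyn + 1L
    }
  }
  list(codons = split_codons(paste(ch, collapse = "")),
       n_syn = n_syn, n_nonsyn = n_nonsyn)
}

#' Simulate a full synthetic dataset
#'
#' [generate_root_genome()] followed by [evolve_on_tree()].
#'
#' @param cfg a [simulation_config()].
#' @return A list: `root`, `genomes`, `tree`, `ledger`.
#' @export
simulate_dataset <- function(cfg) {
  root <- generate_root_genome(cfg)
  ev <- evolve_on_tree(root, cfg)
  list(root = root$genome, genomes = ev$genomes, tree = ev$tree,
       ledger = ev$ledger)
}

#' Write a simulated dataset to disk
#'
#' Emits, per leaf taxon, a FASTA, a feature TSV and a GenBank flat file,
#' plus `ledger.json` with the full ground truth. Re-reading the files
#' reproduces the in-memory objects.
#'
#' @param dataset result of [simulate_dataset()] (or of
#'   [evolve_on_tree()]).
#' @param outdir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
emit_dataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(dataset$genomes)) {
    g <- dataset$genomes[[nm]]
    fa <- file.path(outdir, paste0(nm, ".fasta"))
    write_fasta(stats::setNames(g$sequence, nm), fa)
    tsv <- file.path(outdir, paste0(nm, "_features.tsv"))
    write_feature_table(g$table, tsv)
    gb <- file.path(outdir, paste0(nm, ".gb"))
    write_genbank(g, gb)
    paths[[nm]] <- c(fasta = fa, tsv = tsv, genbank = gb)
  }
  lj <- file.path(outdir, "ledger.json")
  jsonlite::write_json(dataset$ledger, lj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$ledger <- lj
  invisible(paths)
}
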