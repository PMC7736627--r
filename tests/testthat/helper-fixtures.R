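# Shared fixtures. Simulated datasets are memoized so the expensive
# generator runs once per test session.

.fix <- new.env()

# three congeners on the published topology
get_sim3 <- function() {
  if (is.null(.fix$ds3)) {
    cfg <- simulation_config(seed = 2024L)
    .fix$ds3 <- simulate_dataset(cfg)
  }
  .fix$ds3
}

# three congeners plus an outgroup, for tree-stage tests
get_sim4 <- function() {
  if (is.null(.fix$ds4)) {
    cfg <- simulation_config(
      seed = 4048L,
      tree = "(((tertius:0.04,albofasciatus:0.04):0.02,marmoratus:0.06):0.02,outgroup:0.3);")
    .fix$ds4 <- simulate_dataset(cfg)
  }
  .fix$ds4
}

# tiny single-PCG genome with an internal stop planted at codon 2
toy_internal_stop_genome <- function() {
  tab <- gene_table(data.frame(
    name = "ND1", start = 1L, end = 12L, strand = "H", category = "PCG",
    stringsAsFactors = FALSE))
  mitogenome("ATGTAAAAATAG", tab, species = "toy")
}

# random sense-codon sequences under transl_table 2
random_sense_codons <- function(n) {
  code <- Biostrings::getGeneticCode("2")
  sense <- names(code)[code != "*"]
  sample(sense, n, replace = TRUE)
}

# Independent NG86 oracle used by the divergence tests: fates of all
# single-base changes for site counts, and recursive enumeration of all
# minimal pathways for difference counts. Deliberately written against
# Biostrings' genetic-code table, not against the package internals.
oracle_syn_sites <- function(codon) {
  code <- Biostrings::getGeneticCode("2")
  bases <- c("A", "C", "G", "T")
  s <- 0
  ch <- strsplit(codon, "")[[1]]
  for (p in 1:3) for (b in setdiff(bases, ch[p])) {
    alt <- ch; alt[p] <- b
    ac <- paste(alt, collapse = "")
    if (code[[ac]] != "*" && code[[ac]] == code[[codon]]) s <- s + 1 / 3
  }
  s
}

oracle_pathways <- function(a, b) {
  code <- Biostrings::getGeneticCode("2")
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd, blocked = blocked)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(b, "")[[1]][p]
      nxtc <- paste(nxt, collapse = "")
      recurse(nxtc, setdiff(remaining, p),
              sd + (code[[cur]] == code[[nxtc]]),
              nd + (code[[cur]] != code[[nxtc]]),
              blocked || code[[nxtc]] == "*")
    }
  }
  if (!length(diffpos)) return(c(sd = 0, nd = 0))
  recurse(a, diffpos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- !m[, "blocked"]
  if (!any(ok)) ok <- rep(TRUE, nrow(m))
  c(sd = mean(m[ok, "sd"]), nd = mean(m[ok, "nd"]))
}
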