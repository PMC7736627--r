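#' Detect tandem repeats by lag-seeded consensus extension
#'
#' Candidate periods are seeded by self-match runs at lag `p`: positions
#' where `seq[i] == seq[i + p]`. Runs of matches (tolerating mismatch gaps
#' up to `max(3, p/10)`) define candidate arrays spanning
#' `[i1, i2 + p]`, with copy number `(span + p) / p`. Each candidate is
#' scored against a majority-rule consensus unit (ties broken towards the
#' alphabetically first base, so output is deterministic). Chance
#' self-matches are controlled by a binomial E-value: the probability of
#' the observed number of lag matches under an i.i.d. null with
#' self-match probability estimated from base frequencies (clamped to
#' [0.25, 0.6]), Bonferroni-scaled by the number of (start, period)
#' candidates. Overlapping calls are resolved greedily by highest
#' `copies * identity`, then smallest period, then smallest start.
#'
#' The detector models substitution noise only; copies are assumed
#' length-preserving (no indel handling), which matches slipped-strand
#' products that are near-perfect.
#'
#' @param seq nucleotide string, length at least `2 * min_period`.
#' @param min_period,max_period candidate unit lengths (bp).
#' @param min_copies minimum real-valued copy number.
#' @param min_identity minimum mean per-copy match fraction to the
#'   consensus, in (0, 1].
#' @param max_evalue significance cutoff for chance self-matches; set to
#'   `Inf` to disable (useful for tiny toy sequences).
#' @return Data frame with columns `start`, `end` (1-based inclusive span
#'   of the array), `period`, `copies`, `identity`, `consensus`,
#'   `evalue`, sorted by start. Zero rows when nothing qualifies.
#' @export
find_tandem_repeats <- function(seq, min_period = 10L, max_period = 600L,
                                min_copies = 1.8, min_identity = 0.8,
                                max_evalue = 0.01) {
  seq <- toupper(as.character(seq))
  if (min_period < 1L || max_period < min_period)
    stop("need 1 <= min_period <= max_period")
  if (min_copies <= 1) stop("min_copies must exceed 1")
  if (min_identity <= 0 || min_identity > 1) stop("min_identity must be in (0,1]")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2L * min_period) stop("sequence shorter than 2 * min_period")
  pmax_eff <- min(max_period, n %/% 2L)
  freqs <- table(factor(ch, levels = c("A", "C", "G", "T"))) / n
  p0 <- min(max(sum(freqs^2), 0.25), 0.6)
  n_cand <- as.numeric(n) * (pmax_eff - min_period + 1L)

  cands <- list()
  for (p in min_period:pmax_eff) {
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    idx <- which(m)
    if (length(idx) < 2L) next
    gap <- max(3L, ceiling(p / 10))
    brk <- which(diff(idx) > gap + 1L)
    starts <- c(1L, brk + 1L); ends <- c(brk, length(idx))
    # mismatch penalty such that a segment at exactly min_identity scores 0;
    # clusters are trimmed to their maximum-scoring subsegment so chance
    # matches in the flanks do not inflate the array span
    mu <- min_identity / (1 - min(min_identity, 0.999))
    for (k in seq_along(starts)) {
      i1 <- idx[starts[k]]; i2 <- idx[ends[k]]
      sc <- ifelse(m[i1:i2], 1, -mu)
      best <- 0; cur <- 0; b1 <- 1L; c1 <- 1L; b2 <- 0L
      for (q in seq_along(sc)) {
        if (cur <= 0) { cur <- 0; c1 <- q }
        cur <- cur + sc[q]
        if (cur > best) { best <- cur; b1 <- c1; b2 <- q }
      }
      if (b2 < b1) next
      i2 <- i1 + b2 - 1L; i1 <- i1 + b1 - 1L
      span <- i2 - i1 + 1L
      copies <- (span + p) / p
      if (copies < min_copies) next
      matches <- sum(m[i1:i2])
      if (matches / span < min_identity) next
      ev <- stats::pbinom(matches - 1L, span, p0, lower.tail = FALSE) * n_cand
      if (ev > max_evalue) next
      reg <- ch[i1:(i2 + p)]
      consensus_at <- function(per) {
        col <- (seq_along(reg) - 1L) %% per + 1L
        vapply(seq_len(per), function(cix) {
          tb <- sort(table(reg[col == cix]), decreasing = TRUE)
          nm <- names(tb)[tb == max(tb)]
          sort(nm)[1]
        }, "")
      }
      cons <- consensus_at(p)
      # collapse to the fundamental period: a run seeded at lag p whose
      # consensus is itself periodic with divisor d is a d-bp repeat
      p_eff <- p
      divs <- seq_len(p %/% 2)
      for (d in divs[p %% divs == 0L & divs >= min_period]) {
        if (mean(cons == cons[(seq_len(p) - 1L) %% d + 1L]) >= min_identity) {
          p_eff <- d
          cons <- consensus_at(d)
          break
        }
      }
      copies <- length(reg) / p_eff
      ncopy <- ceiling(copies)
      perc <- vapply(seq_len(ncopy), function(ci) {
        seg <- reg[((ci - 1L) * p_eff + 1L):min(ci * p_eff, length(reg))]
        mean(seg == cons[seq_along(seg)])
      }, 0)
      ident <- mean(perc)
      if (ident < min_identity) next
      cands[[length(cands) + 1L]] <- data.frame(
        start = i1, end = i2 + p, period = p_eff, copies = copies,
        identity = ident, consensus = paste(cons, collapse = ""),
        evalue = ev, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(start = integer(0), end = integer(0),
                      period = integer(0), copies = numeric(0),
                      identity = numeric(0), consensus = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (!length(cands)) return(empty)
  cd <- do.call(rbind, cands)
  cd <- cd[order(-cd$copies * cd$identity, cd$period, cd$start), , drop = FALSE]
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    ov <- keep & pmin(cd$end[i], cd$end) - pmax(cd$start[i], cd$start) >= 0
    if (!any(ov)) keep[i] <- TRUE
  }
  out <- cd[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tandem-repeat report for the control region
#'
#' Runs [find_tandem_repeats()] on the annotated control region (D-loop)
#' of a mitogenome and reports each call in genome coordinates together
#' with the fraction of the control region it spans.
#'
#' @param g a [mitogenome()] with sequence and an annotated D-loop.
#' @param ... passed to [find_tandem_repeats()].
#' @return Data frame with columns `region`, `start`, `end` (genome
#'   coordinates), `period`, `copies`, `identity`, `consensus`,
#'   `span`, `share` (span / control-region length).
#' @export
repeat_report <- function(g, ...) {
  f <- g$table$features
  i <- match("D-loop", f$name)
  if (is.na(i)) stop("genome lacks an annotated D-loop feature")
  dl <- f[i, , drop = FALSE]
  reg <- extract_region(g, dl, orient = "h-strand")
  hits <- find_tandem_repeats(reg, ...)
  if (!nrow(hits))
    return(data.frame(region = character(0), start = integer(0),
                      end = integer(0), period = integer(0),
                      copies = numeric(0), identity = numeric(0),
                      consensus = character(0), span = integer(0),
                      share = numeric(0), stringsAsFactors = FALSE))
  data.frame(region = "D-loop",
             start = hits$start + dl$start - 1L,
             end = hits$end + dl$start - 1L,
             period = hits$period, copies = hits$copies,
             identity = hits$identity, consensus = hits$consensus,
             span = hits$end - hits$start + 1L,
             share = (hits$end - hits$start + 1L) / feature_size(dl)[[1]],
             stringsAsFactors = FALSE)
}
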