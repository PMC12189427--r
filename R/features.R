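# Per-interval genomic feature tracks: GC content, CpG islands, gene density.
#
# CpG islands are called directly from sequence under Gardiner-Garden-style
# criteria: length strictly greater than 200 bp, GC fraction >= 0.5, and
# observed/expected CpG >= 0.6, where obs/exp = N_CpG * L / (N_C * N_G).

VALID_BASES <- "ACGTNacgtn"

# uppercase raw bytes + validity check with 1-based position of the first
# illegal character
.seq_bytes <- function(seq) {
  if (inherits(seq, "DNAString") || inherits(seq, "DNAStringSet"))
    seq <- as.character(seq)
  stopifnot(is.character(seq), length(seq) == 1L)
  bad <- regexpr(sprintf("[^%s]", VALID_BASES), seq)
  if (bad != -1L)
    stop(sprintf("illegal character '%s' at position %d",
                 substr(seq, bad, bad), bad))
  charToRaw(toupper(seq))
}

# cumulative counts (with leading 0) of C, G, N and CG dinucleotides
# (pair position i covers bases i, i+1)
.cum_counts <- function(bytes) {
  isC <- bytes == as.raw(67L)
  isG <- bytes == as.raw(71L)
  isN <- bytes == as.raw(78L)
  n <- length(bytes)
  cg <- if (n >= 2L) isC[-n] & isG[-1L] else logical(0)
  list(n = n,
       C = cumsum(c(0, isC)),
       G = cumsum(c(0, isG)),
       N = cumsum(c(0, isN)),
       CG = cumsum(c(0, cg)))
}

# counts over 1-based inclusive ranges [s, e] from cumulative arrays;
# CG pairs counted only when fully inside the range
.range_stats <- function(cc, s, e) {
  len <- e - s + 1
  nC <- cc$C[e + 1] - cc$C[s]
  nG <- cc$G[e + 1] - cc$G[s]
  nN <- cc$N[e + 1] - cc$N[s]
  nCG <- ifelse(e > s, cc$CG[e] - cc$CG[s], 0)
  eff <- len - nN
  gc <- ifelse(eff > 0, (nC + nG) / eff, NA_real_)
  oe <- ifelse(nC > 0 & nG > 0, nCG * eff / (nC * nG), 0)
  list(len = len, nC = nC, nG = nG, nN = nN, nCG = nCG,
       eff = eff, gc = gc, oe = oe)
}

#' GC fraction of a nucleotide sequence
#'
#' `(C + G) / (A + C + G + T)`, case-insensitive; `N` bases are excluded
#' from numerator and denominator.  An all-`N` (or empty) sequence returns
#' `NA` as the missing-value flag.
#'
#' @param seq A single nucleotide string (or `DNAString`) over
#'   `A,C,G,T,N`, either case.
#' @return GC fraction in `[0, 1]`, or `NA` if no unambiguous bases.
#' @examples
#' gc_content("ATGC")    # 0.5
#' gc_content("ATGCNN")  # 0.5 (Ns excluded)
#' @export
gc_content <- function(seq) {
  bytes <- .seq_bytes(seq)
  if (length(bytes) == 0L) return(NA_real_)
  nC <- sum(bytes == as.raw(67L))
  nG <- sum(bytes == as.raw(71L))
  nN <- sum(bytes == as.raw(78L))
  eff <- length(bytes) - nN
  if (eff == 0L) return(NA_real_)
  (nC + nG) / eff
}

#' Observed/expected CpG ratio of a sequence
#'
#' `N_CpG * L / (N_C * N_G)`, with `L` the number of unambiguous (non-N)
#' bases and `N_CpG` the count of `CG` dinucleotides.  Sequences with no C
#' or no G return 0 by convention.
#'
#' @param seq A single nucleotide string over `A,C,G,T,N`, either case.
#' @return Non-negative obs/exp CpG ratio.
#' @examples
#' obs_exp_cpg("CCGG")  # 1.0
#' @export
obs_exp_cpg <- function(seq) {
  bytes <- .seq_bytes(seq)
  if (length(bytes) == 0L) stop("empty sequence")
  cc <- .cum_counts(bytes)
  st <- .range_stats(cc, 1L, cc$n)
  st$oe
}

#' Call CpG islands from sequence
#'
#' Sliding-window caller: every `window`-bp window (step 1 bp) is tested
#' against GC >= `min_gc` and obs/exp CpG >= `min_oe` (windows containing
#' `N` are disqualified); runs of qualifying window starts are merged into
#' candidate spans; within each span, maximal regions satisfying all three
#' criteria -- length strictly greater than `min_len`, GC >= `min_gc`,
#' obs/exp >= `min_oe` -- are extracted by a leftmost-longest greedy search.
#' Returned islands are disjoint, sorted, and each re-satisfies the three
#' criteria.  This is a Gardiner-Garden-style caller, not a re-implementation
#' of any particular genome-browser dialect.
#'
#' @param seq A single nucleotide string over `A,C,G,T,N`, either case.
#' @param chrom Chromosome name for the output table.
#' @param min_len Minimum length, exclusive (island length > `min_len`).
#' @param min_gc Minimum GC fraction, inclusive.
#' @param min_oe Minimum obs/exp CpG, inclusive.
#' @param window Seed window width in bp.
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `length`, `gc_fraction`, `obs_exp_cpg`.
#' @export
call_cpg_islands <- function(seq, chrom = "chr", min_len = 200L,
                             min_gc = 0.5, min_oe = 0.6, window = 200L) {
  bytes <- .seq_bytes(seq)
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      gc_fraction = numeric(0), obs_exp_cpg = numeric(0))
  n <- length(bytes)
  if (n <= min_len) return(empty)
  cc <- .cum_counts(bytes)

  # qualifying seed windows
  w <- as.integer(window)
  starts <- seq_len(n - w + 1L)
  st <- .range_stats(cc, starts, starts + w - 1L)
  ok <- st$nN == 0L & !is.na(st$gc) & st$gc >= min_gc & st$oe >= min_oe
  if (!any(ok)) return(empty)

  # merge runs of qualifying starts into candidate spans; spans are the
  # window-extended runs, so nearby runs can overlap once extended and are
  # merged again to keep the emitted islands disjoint
  r <- rle(ok)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  span_a <- run_start[r$values]
  span_b <- run_end[r$values] + w - 1L
  if (length(span_a) > 1L) {
    ma <- span_a[1L]; mb <- span_b[1L]
    for (j in 2L:length(span_a)) {
      last <- length(mb)
      if (span_a[j] <= mb[last] + 1L) {
        mb[last] <- max(mb[last], span_b[j])
      } else {
        ma <- c(ma, span_a[j]); mb <- c(mb, span_b[j])
      }
    }
    span_a <- ma; span_b <- mb
  }

  out <- vector("list", length(span_a))
  k <- 0L
  for (j in seq_along(span_a)) {
    a <- span_a[j]; b <- span_b[j]
    s <- a
    while (s + min_len <= b) {
      ends <- (s + min_len):b            # lengths strictly > min_len
      es <- .range_stats(cc, s, ends)
      good <- es$nN == 0L & !is.na(es$gc) & es$gc >= min_gc & es$oe >= min_oe
      if (any(good)) {
        e <- ends[max(which(good))]
        i <- which(ends == e)
        k <- k + 1L
        out[[k]] <- data.frame(chrom = chrom, start = s - 1, end = e,
                               length = e - s + 1,
                               gc_fraction = es$gc[i],
                               obs_exp_cpg = es$oe[i])
        s <- e + 1L
      } else {
        s <- s + 1L
      }
    }
  }
  if (k == 0L) return(empty)
  do.call(rbind, out[seq_len(k)])
}

# per-interval GC over a grid (NA where the interval has no unambiguous
# bases), from one sequence's cumulative counts
.interval_gc <- function(cc, grid) {
  s <- grid$intervals$start + 1L
  e <- pmin(grid$intervals$end, cc$n)
  gc <- rep(NA_real_, grid$n_intervals)
  valid <- s <= e
  if (any(valid)) {
    st <- .range_stats(cc, s[valid], e[valid])
    gc[valid] <- st$gc
  }
  gc
}

#' Per-interval feature track: GC, CpG-island count, gene density
#'
#' For each grid interval: GC fraction of the interval's sequence (N
#' excluded, `NA` when all-N); the number of called CpG islands whose start
#' lies in the interval; the number of gene starts in the interval (a
#' gene's start is its lower genomic coordinate, strand ignored); and the
#' gene percentage, `100 * count / chromosome total` (`NA` with a warning
#' when the chromosome has no annotated genes).
#'
#' @param seq The chromosome sequence (string or `DNAString`).
#' @param genes Data frame of gene annotations with columns `chrom` and
#'   `start` (0-based lower coordinate), e.g. from [read_gene_annotation];
#'   `NULL` for no annotation.
#' @param grid An [build_interval_grid] result.
#' @param chrom The matching [chromosome_model].
#' @param islands Optional precomputed [call_cpg_islands] table for this
#'   sequence (saves recomputation); called internally when `NULL`.
#' @return A `feature_track` data frame with columns `chrom`, `start`,
#'   `end`, `gc`, `cgi_count`, `gene_count`, `gene_pct`.
#' @export
feature_profile <- function(seq, genes, grid, chrom, islands = NULL) {
  stopifnot(inherits(grid, "interval_grid"),
            inherits(chrom, "chromosome_model"))
  bytes <- .seq_bytes(seq)
  if (length(bytes) != chrom$assembly_length)
    warning(sprintf(
      "sequence length %d differs from assembly_length %s for '%s'",
      length(bytes), format(chrom$assembly_length), chrom$name))
  cc <- .cum_counts(bytes)
  gc <- .interval_gc(cc, grid)

  if (is.null(islands))
    islands <- call_cpg_islands(rawToChar(bytes), chrom = chrom$name)
  cgi_count <- integer(grid$n_intervals)
  if (nrow(islands) > 0L) {
    idx <- bp_to_interval_index(islands$start, grid)
    cgi_count <- tabulate(idx, nbins = grid$n_intervals)
  }

  gene_count <- integer(grid$n_intervals)
  gene_pct <- rep(NA_real_, grid$n_intervals)
  if (!is.null(genes) && nrow(genes) > 0L) {
    g <- genes[genes$chrom == chrom$name, , drop = FALSE]
    if (nrow(g) > 0L) {
      if (any(g$start < 0 | g$start > chrom$assembly_length))
        stop("gene start positions outside [0, assembly_length] on '",
             chrom$name, "'")
      idx <- bp_to_interval_index(g$start, grid)
      gene_count <- tabulate(idx, nbins = grid$n_intervals)
      gene_pct <- 100 * gene_count / sum(gene_count)
    } else {
      warning("no genes annotated on '", chrom$name,
              "': gene_pct undefined")
    }
  } else {
    warning("no gene annotation supplied for '", chrom$name,
            "': gene_pct undefined")
  }

  out <- data.frame(chrom = chrom$name,
                    start = grid$intervals$start,
                    end = grid$intervals$end,
                    gc = gc,
                    cgi_count = cgi_count,
                    gene_count = gene_count,
                    gene_pct = gene_pct)
  structure(out, class = c("feature_track", "data.frame"),
            interval_size = grid$interval_size)
}
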