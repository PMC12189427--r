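# Independent brute-force oracles used by the test suite.  These recompute
# the package's definitions from scratch (character vectors, explicit
# per-window sums, exhaustive region enumeration) without sharing code with
# the implementation under test.

# GC fraction by explicit counting over a character vector
oracle_gc <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch != "N"]
  if (!length(ch)) return(NA_real_)
  sum(ch %in% c("G", "C")) / length(ch)
}

# obs/exp CpG by explicit dinucleotide scan
oracle_oe <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  ncg <- if (n >= 2) sum(ch[-n] == "C" & ch[-1] == "G") else 0
  nc <- sum(ch == "C"); ng <- sum(ch == "G")
  eff <- sum(ch != "N")
  if (nc == 0 || ng == 0) return(0)
  ncg * eff / (nc * ng)
}

# Brute-force CpG-island search under the package's two-phase definition:
# (1) every 200-bp window (step 1) is tested naively (explicit sums; any N
#     disqualifies); runs of qualifying starts extend to window extent and
#     overlapping extents merge into candidate spans;
# (2) within each span, ALL (start, end) regions are enumerated and tested
#     naively, and the leftmost-longest disjoint decomposition of the
#     qualifying set is emitted (length strictly > min_len).
oracle_islands <- function(seq, window = 200L, min_len = 200L,
                           min_gc = 0.5, min_oe = 0.6) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  empty <- data.frame(start = numeric(0), end = numeric(0))
  if (n <= min_len) return(empty)

  isC <- ch == "C"; isG <- ch == "G"; isN <- ch == "N"
  cgp <- c(isC[-n] & isG[-1], FALSE)

  win_ok <- vapply(seq_len(n - window + 1L), function(s) {
    e <- s + window - 1L
    if (any(isN[s:e])) return(FALSE)
    nc <- sum(isC[s:e]); ng <- sum(isG[s:e])
    ncg <- sum(cgp[s:(e - 1L)])
    gc <- (nc + ng) / window
    oe <- if (nc == 0 || ng == 0) 0 else ncg * window / (nc * ng)
    gc >= min_gc && oe >= min_oe
  }, logical(1))
  if (!any(win_ok)) return(empty)

  r <- rle(win_ok)
  re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
  spans <- cbind(rs[r$values], re[r$values] + window - 1L)
  merged <- spans[1, , drop = FALSE]
  for (j in seq_len(nrow(spans))[-1]) {
    last <- nrow(merged)
    if (spans[j, 1] <= merged[last, 2] + 1L)
      merged[last, 2] <- max(merged[last, 2], spans[j, 2])
    else merged <- rbind(merged, spans[j, , drop = FALSE])
  }

  out <- list()
  for (j in seq_len(nrow(merged))) {
    a <- merged[j, 1]; b <- merged[j, 2]
    # exhaustive enumeration of qualifying regions inside the span
    Cc <- c(0, cumsum(isC[a:b])); Gg <- c(0, cumsum(isG[a:b]))
    Nn <- c(0, cumsum(isN[a:b]))
    Pp <- c(0, cumsum(c(cgp[a:(b - 1L)], FALSE)))
    m <- b - a + 1L
    if (m <= min_len) next  # span too short for a strictly-longer region
    # for every start, the largest qualifying end (NA when none)
    maxe <- rep(NA_integer_, m)
    for (s in seq_len(m - min_len)) {
      e <- (s + min_len):m
      len <- e - s + 1
      nc <- Cc[e + 1] - Cc[s]; ng <- Gg[e + 1] - Gg[s]
      nn <- Nn[e + 1] - Nn[s]; np <- Pp[e] - Pp[s]
      gc <- (nc + ng) / (len - nn)
      oe <- ifelse(nc > 0 & ng > 0, np * (len - nn) / (nc * ng), 0)
      ok <- nn == 0 & gc >= min_gc & oe >= min_oe
      if (any(ok)) maxe[s] <- e[max(which(ok))]
    }
    cursor <- 1L
    repeat {
      cand <- which(!is.na(maxe) & seq_len(m) >= cursor)
      if (!length(cand)) break
      s0 <- cand[1L]
      e0 <- maxe[s0]
      out[[length(out) + 1L]] <- c(a + s0 - 2L, a + e0 - 1L)  # 0-based
      cursor <- e0 + 1L
    }
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# random test sequences of mixed composition for oracle comparisons
random_sequence <- function(n, kind) {
  switch(as.character(kind %% 4),
    "0" = paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
    "1" = paste(sample(c("A", "C", "G", "T"), n, TRUE,
                       prob = c(.3, .2, .2, .3)), collapse = ""),
    "2" = paste(sample(c("A", "C", "G", "T", "N"), n, TRUE,
                       prob = c(.24, .24, .24, .24, .04)), collapse = ""),
    "3" = paste(sample(c("A", "C", "G", "T", "CG"), n, TRUE,
                       prob = c(.3, .15, .15, .3, .1)), collapse = ""))
}
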