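# Rank correlation of recombination rate with genomic features, per
# chromosome and pooled, with optional exclusion of zero-recombination
# intervals (zero-inflation guard for polarized landscapes).

#' Spearman rank correlation with a two-sided p-value
#'
#' Average ranks for ties.  The p-value uses the exact permutation
#' distribution for n <= 10 with tie-free data (full enumeration up to
#' n = 8, the exact algorithm of [stats::cor.test] for n = 9, 10) and the
#' t-distribution approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite values.
#' @return List with `rho`, `p_value`, `n`, `method`.  A constant vector
#'   makes rho undefined: `rho` and `p_value` are `NA` and `method` is
#'   `"undefined (constant input)"`.
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in input")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p_value = NA_real_, n = n,
                method = "undefined (constant input)"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L

  if (n <= 8L && !ties) {
    # full permutation enumeration of the null distribution of |rho|
    perms <- .permutations(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    return(list(rho = rho, p_value = p, n = n, method = "exact permutation"))
  }
  if (n <= 10L && !ties) {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE))
    return(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
                method = "exact (cor.test)"))
  }
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(rho = rho, p_value = min(p, 1), n = n, method = "t approximation")
}

# all permutations of 1..n as rows (n <= 8)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Drop zero-recombination intervals before correlating
#'
#' Removes pairs whose rate is exactly zero, the guard against zero
#' inflation in strongly polarized landscapes where central intervals carry
#' no crossovers at all.  Surviving values are untouched.
#'
#' @param rates Numeric vector of recombination rates.
#' @param features Numeric vector aligned with `rates`.
#' @return List with filtered `rates`, `features`, and `n_dropped`.
#' @export
exclude_zero_intervals <- function(rates, features) {
  if (length(rates) != length(features))
    stop("'rates' and 'features' must be aligned")
  keep <- rates != 0
  if (!any(keep))
    stop("no recombining intervals: all rates are zero")
  list(rates = rates[keep], features = features[keep],
       n_dropped = sum(!keep))
}

#' Correlate recombination rate with feature tracks
#'
#' One Spearman correlation per (scope, feature).  Scopes are the
#' individual chromosomes plus, optionally, a pooled scope concatenating
#' interval pairs across the chromosomes named in `pooled`.  Intervals with
#' missing feature values (e.g. all-N GC) are excluded pairwise;
#' `mode = "nonzero_only"` additionally applies [exclude_zero_intervals].
#' An optional bp-range `mask` per chromosome restricts the analysis to an
#' arm segment.
#'
#' @param rec A `recombination_track` or named list of them (one per
#'   chromosome).
#' @param feat A `feature_track` or named list, on the same grids.
#' @param mode `"all"` or `"nonzero_only"`.
#' @param features Which feature columns to correlate: any of
#'   `"gc"`, `"cgi"`, `"gene"` (gene density as percentage).
#' @param pooled Character vector of chromosome names to pool into an
#'   additional scope, or `NULL`.
#' @param masks Optional named list of logical interval masks per
#'   chromosome (see [mask_intervals]).
#' @param alpha Significance level for the `significant` flag.
#' @param p_adjust `"none"` (default, per-test significance as in the
#'   source analyses) or `"BH"` for Benjamini-Hochberg across all reported
#'   tests.
#' @return An `association_result` data frame: `scope`, `feature`, `rho`,
#'   `p_value`, `n_pairs`, `zero_excluded`, `significant`, `stars`.
#' @export
correlate_tracks <- function(rec, feat, mode = c("all", "nonzero_only"),
                             features = c("gc", "cgi", "gene"),
                             pooled = NULL, masks = NULL, alpha = 0.05,
                             p_adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  p_adjust <- match.arg(p_adjust)
  features <- match.arg(features, several.ok = TRUE)
  if (inherits(rec, "recombination_track")) rec <- list(rec)
  if (inherits(feat, "feature_track")) feat <- list(feat)
  names(rec) <- vapply(rec, function(t) t$chrom[1], character(1))
  names(feat) <- vapply(feat, function(t) t$chrom[1], character(1))
  if (!setequal(names(rec), names(feat)))
    stop("recombination and feature tracks cover different chromosomes")

  col_of <- c(gc = "gc", cgi = "cgi_count", gene = "gene_pct")

  # aligned per-chromosome pair vectors, mask applied
  pair_vectors <- function(ch, fe) {
    r <- rec[[ch]]; f <- feat[[ch]]
    if (nrow(r) != nrow(f) || any(r$start != f$start) ||
        any(r$end != f$end))
      stop("grid mismatch between recombination and feature tracks on '",
           ch, "'")
    keep <- rep(TRUE, nrow(r))
    if (!is.null(masks) && !is.null(masks[[ch]])) {
      if (length(masks[[ch]]) != nrow(r))
        stop("mask length mismatch on '", ch, "'")
      keep <- masks[[ch]]
    }
    x <- r$rate_cM_per_Mb[keep]
    y <- f[[col_of[[fe]]]][keep]
    ok <- is.finite(y)
    list(rate = x[ok], feature = y[ok])
  }

  scopes <- as.list(names(rec))
  names(scopes) <- names(rec)
  if (!is.null(pooled)) {
    if (!all(pooled %in% names(rec)))
      stop("pooled scope names unknown chromosomes: ",
           paste(setdiff(pooled, names(rec)), collapse = ", "))
    scopes <- c(scopes, list(pooled = pooled))
    names(scopes)[length(scopes)] <-
      paste0("pooled_", paste(pooled, collapse = "_"))
  }

  rows <- list()
  for (si in seq_along(scopes)) {
    scope_name <- names(scopes)[si]
    chs <- scopes[[si]]
    for (fe in features) {
      pv <- lapply(chs, pair_vectors, fe = fe)
      x <- unlist(lapply(pv, `[[`, "rate"), use.names = FALSE)
      y <- unlist(lapply(pv, `[[`, "feature"), use.names = FALSE)
      dropped <- 0L
      if (mode == "nonzero_only") {
        flt <- tryCatch(exclude_zero_intervals(x, y), error = identity)
        if (inherits(flt, "error")) {
          warning("scope '", scope_name, "', feature '", fe, "': ",
                  conditionMessage(flt))
          next
        }
        x <- flt$rates; y <- flt$features; dropped <- flt$n_dropped
      }
      if (length(x) < 3L) {
        warning("scope '", scope_name, "', feature '", fe,
                "': fewer than 3 pairs, skipped")
        next
      }
      sp <- spearman(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope_name, feature = fe, rho = sp$rho,
        p_value = sp$p_value, n_pairs = sp$n,
        zero_excluded = mode == "nonzero_only", n_dropped = dropped)
    }
  }
  if (!length(rows)) stop("no correlations could be computed")
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out$stars <- significance_stars(out$p_value)
  structure(out, class = c("association_result", "data.frame"),
            alpha = alpha)
}

#' Map p-values to significance stars
#' @param p Numeric vector of p-values.
#' @return `"***"` (< 0.001), `"**"` (< 0.01), `"*"` (< 0.05), else `""`.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Format association results as a scope-by-feature matrix
#'
#' Mirrors the usual correlation-matrix figure: cells show the Spearman
#' coefficient with significance stars, and non-significant cells are left
#' blank.  A feature whose every cell is blank is dropped with a warning.
#'
#' @param results An `association_result` data frame.
#' @param alpha Significance threshold for displaying a cell.
#' @param digits Digits for the coefficient.
#' @return Character matrix, scopes as rows and features as columns.
#' @export
format_matrix <- function(results, alpha = 0.05, digits = 2) {
  stopifnot(nrow(results) > 0L)
  scopes <- unique(results$scope)
  feats <- unique(results$feature)
  m <- matrix("", length(scopes), length(feats),
              dimnames = list(scopes, feats))
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    if (!is.na(r$p_value) && r$p_value < alpha)
      m[r$scope, r$feature] <-
        trimws(paste(format(round(r$rho, digits), nsmall = digits),
                     significance_stars(r$p_value)))
  }
  blank <- apply(m, 2L, function(col) all(col == ""))
  if (any(blank)) {
    warning("dropping feature column(s) with no significant cells: ",
            paste(colnames(m)[blank], collapse = ", "))
    m <- m[, !blank, drop = FALSE]
  }
  m
}
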