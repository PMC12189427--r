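# From MLH1 focus positions to cM and cM/Mb interval maps.
#
# Each MLH1 focus marks one crossover on one bivalent of one cell.  With N
# cells scored, a focus observed in an interval contributes 50/N cM there,
# so interval genetic length is cM_i = 50 * f_i / N and the rate is
# cM_i divided by the interval's true length in Mb.

#' Build a focus table from per-focus records
#'
#' One row per MLH1 focus.  Positions are either fractions of the cell's
#' own SC axis length (`position_unit = "fraction"`) or micrometres from the
#' short-arm tip (`"um"`, requiring `sc_length_um` for that row).
#' Micrometre positions are normalized per cell by that cell's own SC
#' length, not the species mean, since axis length varies between cells.
#'
#' @param df Data frame with columns `cell_id`, `chromosome`, `position`,
#'   `position_unit`, and optionally `sc_length_um`.
#' @param n_cells Optional named integer vector giving the total number of
#'   SCs scored per chromosome (the denominator N).  Defaults to the number
#'   of distinct `cell_id`s observed per chromosome; supply it explicitly
#'   when some scored cells carried zero foci on a bivalent.
#' @return A `focus_table` data frame with a normalized `fraction` column.
#' @export
focus_table <- function(df, n_cells = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("cell_id", "chromosome", "position")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("focus table lacks required columns: ", paste(miss, collapse = ", "))
  if (is.null(df$position_unit))
    df$position_unit <- rep("fraction", nrow(df))
  if (is.null(df$sc_length_um)) df$sc_length_um <- rep(NA_real_, nrow(df))
  df$position <- as.numeric(df$position)
  df$sc_length_um <- as.numeric(df$sc_length_um)
  if (!all(df$position_unit %in% c("fraction", "um")))
    stop("position_unit must be 'fraction' or 'um'")

  frac <- df$position
  um <- df$position_unit == "um"
  if (any(um)) {
    no_len <- um & (!is.finite(df$sc_length_um) | df$sc_length_um <= 0)
    if (any(no_len))
      stop("micrometre positions without a valid sc_length_um for cell(s): ",
           paste(unique(df$cell_id[no_len]), collapse = ", "))
    over <- um & df$position > df$sc_length_um
    if (any(over))
      stop("focus position exceeds SC length for cell(s): ",
           paste(unique(df$cell_id[over]), collapse = ", "))
    frac[um] <- df$position[um] / df$sc_length_um[um]
  }
  bad <- !is.finite(frac) | frac < 0 | frac > 1
  if (any(bad))
    stop("focus fraction outside [0, 1] for cell(s): ",
         paste(unique(df$cell_id[bad]), collapse = ", "))
  df$fraction <- frac

  if (is.null(n_cells)) {
    tab <- tapply(df$cell_id, df$chromosome,
                  function(x) length(unique(x)))
    n_cells <- stats::setNames(as.integer(tab), names(tab))
  } else {
    n_cells <- stats::setNames(as.integer(n_cells), names(n_cells))
    if (any(n_cells < 1L)) stop("n_cells must be >= 1 per chromosome")
  }
  structure(df, class = c("focus_table", "data.frame"), n_cells = n_cells)
}

#' Number of SCs scored per chromosome in a focus table
#' @param table A [focus_table].
#' @param chromosome Chromosome name.
#' @return Integer N.
#' @export
n_cells_scored <- function(table, chromosome) {
  n_cells <- attr(table, "n_cells")
  if (is.null(n_cells) || is.na(n_cells[chromosome]))
    stop("number of scored cells unknown for chromosome '", chromosome, "'")
  unname(n_cells[chromosome])
}

#' Bin MLH1 foci of one chromosome into grid intervals
#'
#' Each focus fraction is converted to a genomic coordinate with
#' [sc_fraction_to_bp] (applying any orientation inversion) and assigned to
#' its half-open interval with [bp_to_interval_index]; a focus at fraction
#' 1 closes into the last interval.  Counts are conserved: the returned
#' vector sums to the number of foci supplied.
#'
#' @param table A [focus_table].
#' @param grid An [build_interval_grid] result for `chrom`.
#' @param chrom The matching [chromosome_model].
#' @return Integer vector `f_i` of per-interval focus counts.
#' @export
bin_foci <- function(table, grid, chrom) {
  stopifnot(inherits(table, "focus_table"), inherits(grid, "interval_grid"),
            inherits(chrom, "chromosome_model"))
  rows <- table$chromosome == chrom$name
  f <- integer(grid$n_intervals)
  if (!any(rows)) return(f)
  bp <- sc_fraction_to_bp(table$fraction[rows], chrom)
  idx <- bp_to_interval_index(bp, grid)
  counts <- tabulate(idx, nbins = grid$n_intervals)
  stopifnot(sum(counts) == sum(rows))
  counts
}

#' Convert per-interval focus counts to centimorgans
#'
#' `cM_i = 50 * f_i / N`: each focus is one crossover in one of N scored
#' cells, i.e. 50 cM spread over the cells.
#'
#' @param f_i Integer vector of focus counts (>= 0).
#' @param n_cells Total number of SCs scored, N (>= 1).
#' @return Numeric vector of cM per interval.
#' @export
counts_to_cM <- function(f_i, n_cells) {
  if (length(n_cells) != 1L || !is.finite(n_cells) || n_cells < 1)
    stop("'n_cells' must be a single integer >= 1")
  if (any(f_i < 0)) stop("focus counts must be non-negative")
  50 * f_i / n_cells
}

#' Convert interval genetic length to recombination rate
#'
#' Divides by the interval's true physical length in Mb, so a trailing
#' partial interval uses its own length rather than the nominal grid size.
#'
#' @param cM Numeric vector of interval genetic lengths in cM.
#' @param interval_length Interval lengths in bp (> 0), recycled.
#' @return Recombination rate in cM/Mb.
#' @export
cM_to_rate <- function(cM, interval_length) {
  if (any(!is.finite(interval_length) | interval_length <= 0))
    stop("'interval_length' must be positive")
  cM / (interval_length / 1e6)
}

#' Total genetic map length implied by a focus table
#'
#' `50 * (total foci) / N` cM for one chromosome, the grid-independent sum
#' of all interval cM values.  With `chromosome = NULL` the per-chromosome
#' map lengths are summed.
#'
#' @param table A [focus_table].
#' @param chromosome Chromosome name, or `NULL` for the whole-karyotype sum.
#' @return Map length in cM.
#' @export
map_length <- function(table, chromosome = NULL) {
  stopifnot(inherits(table, "focus_table"))
  if (nrow(table) == 0L) stop("empty focus table")
  chroms <- if (is.null(chromosome)) unique(table$chromosome) else chromosome
  total <- 0
  for (ch in chroms) {
    n_foci <- sum(table$chromosome == ch)
    total <- total + 50 * n_foci / n_cells_scored(table, ch)
  }
  total
}

#' Recombination track: foci, cM and cM/Mb per grid interval
#'
#' Runs the full count-to-rate chain for one chromosome.
#'
#' @param table A [focus_table].
#' @param grid An [build_interval_grid] result.
#' @param chrom The matching [chromosome_model].
#' @return A `recombination_track` data frame with columns `chrom`, `start`,
#'   `end`, `n_foci`, `cM`, `rate_cM_per_Mb`; attribute `n_cells` records N.
#' @export
recombination_track <- function(table, grid, chrom) {
  f <- bin_foci(table, grid, chrom)
  n <- n_cells_scored(table, chrom$name)
  cm <- counts_to_cM(f, n)
  len <- grid$intervals$end - grid$intervals$start
  out <- data.frame(chrom = chrom$name,
                    start = grid$intervals$start,
                    end = grid$intervals$end,
                    n_foci = f,
                    cM = cm,
                    rate_cM_per_Mb = cM_to_rate(cm, len))
  structure(out, class = c("recombination_track", "data.frame"),
            n_cells = n, interval_size = grid$interval_size)
}

#' Summarize interval recombination rates
#'
#' Minimum, maximum, mean and sample (n-1) standard deviation of the
#' per-interval rates, over one track or a list of per-chromosome tracks.
#'
#' @param track A `recombination_track` or list of them.
#' @return Named numeric vector `(min, max, mean, sd)`.
#' @export
track_summary <- function(track) {
  if (inherits(track, "recombination_track")) track <- list(track)
  rates <- unlist(lapply(track, function(t) {
    stopifnot(inherits(t, "recombination_track"))
    t$rate_cM_per_Mb
  }), use.names = FALSE)
  if (length(rates) == 0L) stop("no intervals to summarize")
  c(min = min(rates), max = max(rates), mean = mean(rates),
    sd = if (length(rates) > 1L) stats::sd(rates) else 0)
}
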