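# Interval grids and synaptonemal-complex (SC) coordinate conversion.
#
# All genomic coordinates inside the package are 0-based, half-open
# [start, end), with the tip of the short arm at position 0.  A position
# exactly equal to the assembly length closes into the final interval.

#' Describe a chromosome for cytological-to-genomic conversion
#'
#' A `chromosome_model` carries everything needed to translate positions
#' measured along the synaptonemal complex (SC) axis of a pachytene bivalent
#' into genomic base pairs: the assembly length, the mean SC axis length in
#' micrometres, and the orientation of the cytological axis relative to the
#' assembly.  Orientation `"inverted"` means the assembly runs
#' telomere-to-centromere opposite to the scored axis, so axis fractions are
#' reflected (`f -> 1 - f`) before scaling; this matches the convention of
#' inverting physical coordinates on one chromosome so that the short-arm
#' tip sits at 0 in both species of a comparison.
#'
#' @param name Chromosome identifier (e.g. `"chr1"`, `"GGA1"`).
#' @param assembly_length Assembly length in base pairs (> 0).
#' @param mean_sc_length Mean SC axis length in micrometres, or `NULL` if
#'   unknown.
#' @param centromere_position Centromere position in bp within
#'   `[0, assembly_length]`, or `NULL`.
#' @param orientation `"forward"` or `"inverted"`.
#' @return An object of class `chromosome_model`.
#' @examples
#' chromosome_model("NME1", 194400000, mean_sc_length = 24.5)
#' @export
chromosome_model <- function(name, assembly_length, mean_sc_length = NULL,
                             centromere_position = NULL,
                             orientation = c("forward", "inverted")) {
  orientation <- match.arg(orientation)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a single non-empty string")
  assembly_length <- as.numeric(assembly_length)
  if (length(assembly_length) != 1L || !is.finite(assembly_length) ||
      assembly_length <= 0)
    stop("'assembly_length' must be a single positive number of base pairs")
  if (!is.null(mean_sc_length)) {
    mean_sc_length <- as.numeric(mean_sc_length)
    if (length(mean_sc_length) != 1L || !is.finite(mean_sc_length) ||
        mean_sc_length <= 0)
      stop("'mean_sc_length' must be a single positive number (micrometres)")
  }
  if (!is.null(centromere_position)) {
    centromere_position <- as.numeric(centromere_position)
    if (length(centromere_position) != 1L || !is.finite(centromere_position) ||
        centromere_position < 0 || centromere_position > assembly_length)
      stop("'centromere_position' must lie in [0, assembly_length]")
  }
  structure(
    list(name = name,
         assembly_length = assembly_length,
         mean_sc_length = mean_sc_length,
         centromere_position = centromere_position,
         orientation = orientation),
    class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf("<chromosome_model> %s: %s bp, SC %s um, orientation %s\n",
              x$name, format(x$assembly_length, big.mark = ","),
              if (is.null(x$mean_sc_length)) "?" else x$mean_sc_length,
              x$orientation))
  invisible(x)
}

#' Partition a chromosome into fixed-size genomic intervals
#'
#' Tiles `[0, assembly_length)` with half-open intervals of `interval_size`
#' base pairs.  The number of intervals is `ceiling(length / size)`: a
#' trailing partial interval is kept, so e.g. a 194.4 Mb chromosome cut into
#' 2.5 Mb pieces yields 78 intervals, the last one shorter.
#'
#' @param chrom A [chromosome_model], or a single positive number taken as
#'   the assembly length in bp.
#' @param interval_size Interval size in bp (default 2.5 Mb).
#' @return An object of class `interval_grid`: a list with `chromosome`,
#'   `interval_size`, `n_intervals` and a data frame `intervals` with
#'   0-based half-open `start`/`end` columns.
#' @examples
#' g <- build_interval_grid(chromosome_model("NME1", 194400000), 2.5e6)
#' g$n_intervals  # 78
#' @export
build_interval_grid <- function(chrom, interval_size = 2.5e6) {
  if (inherits(chrom, "chromosome_model")) {
    name <- chrom$name
    len <- chrom$assembly_length
  } else {
    name <- "chr"
    len <- as.numeric(chrom)
    if (length(len) != 1L || !is.finite(len) || len <= 0)
      stop("'chrom' (assembly_length) must be a single positive number")
  }
  interval_size <- as.numeric(interval_size)
  if (length(interval_size) != 1L || !is.finite(interval_size) ||
      interval_size <= 0)
    stop("'interval_size' must be a single positive number of base pairs")
  n <- as.integer(ceiling(len / interval_size))
  start <- (seq_len(n) - 1) * interval_size
  end <- pmin(start + interval_size, len)
  structure(
    list(chromosome = name,
         assembly_length = len,
         interval_size = interval_size,
         n_intervals = n,
         intervals = data.frame(start = start, end = end)),
    class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  cat(sprintf("<interval_grid> %s: %d intervals of %s bp over %s bp\n",
              x$chromosome, x$n_intervals,
              format(x$interval_size, big.mark = ","),
              format(x$assembly_length, big.mark = ",")))
  invisible(x)
}

#' Physical (SC-axis) length represented by one grid interval
#'
#' Under the pachytene proportionality between genomic and axis distance,
#' each of the `n` intervals corresponds to `mean_sc_length / n` micrometres
#' of SC axis.  For a 24.5 um axis cut into 78 intervals this is about
#' 0.3 um, the resolution limit of focus scoring.
#'
#' @param chrom A [chromosome_model] with `mean_sc_length` set.
#' @param grid The [build_interval_grid] result for the same chromosome.
#' @return Physical interval length in micrometres.
#' @export
interval_physical_length <- function(chrom, grid) {
  stopifnot(inherits(chrom, "chromosome_model"),
            inherits(grid, "interval_grid"))
  if (is.null(chrom$mean_sc_length))
    stop(sprintf("SC length unavailable for chromosome '%s'", chrom$name))
  chrom$mean_sc_length / grid$n_intervals
}

#' Convert an SC-axis fraction to a genomic coordinate
#'
#' Positions along the SC axis, expressed as fractions of the axis length
#' (0 = short-arm tip), map proportionally onto the assembly:
#' `bp = round(f * assembly_length)`.  For an `"inverted"` chromosome the
#' fraction is reflected to `1 - f` first.
#'
#' @param fraction Numeric vector of fractions in `[0, 1]`.
#' @param chrom A [chromosome_model].
#' @return Numeric vector of base-pair positions.
#' @examples
#' sc_fraction_to_bp(0.5, chromosome_model("NME1", 194400000))
#' @export
sc_fraction_to_bp <- function(fraction, chrom) {
  stopifnot(inherits(chrom, "chromosome_model"))
  fraction <- as.numeric(fraction)
  bad <- !is.finite(fraction) | fraction < 0 | fraction > 1
  if (any(bad))
    stop(sprintf("fraction outside [0, 1]: %s",
                 paste(utils::head(fraction[bad], 3), collapse = ", ")))
  if (chrom$orientation == "inverted") fraction <- 1 - fraction
  round(fraction * chrom$assembly_length)
}

#' Locate a genomic position on an interval grid
#'
#' Returns the 1-based index of the half-open interval containing `pos`.
#' A position exactly at the assembly length closes into the last interval.
#'
#' @param pos Numeric vector of base-pair positions in
#'   `[0, assembly_length]`.
#' @param grid An [build_interval_grid] result.
#' @return Integer vector of interval indices in `1..n_intervals`.
#' @export
bp_to_interval_index <- function(pos, grid) {
  stopifnot(inherits(grid, "interval_grid"))
  pos <- as.numeric(pos)
  bad <- !is.finite(pos) | pos < 0 | pos > grid$assembly_length
  if (any(bad))
    stop(sprintf("position outside [0, %s]: %s",
                 format(grid$assembly_length),
                 paste(utils::head(pos[bad], 3), collapse = ", ")))
  idx <- floor(pos / grid$interval_size) + 1L
  pmin(as.integer(idx), grid$n_intervals)
}

#' Mask grid intervals to a base-pair range
#'
#' Used for arm-restricted analyses (e.g. limiting a cross-species
#' comparison to the long arm): an interval is kept when its midpoint lies
#' in `[start, end)`.
#'
#' @param grid An [build_interval_grid] result.
#' @param start,end Base-pair range, half-open.
#' @return Logical vector over intervals.
#' @export
mask_intervals <- function(grid, start, end) {
  stopifnot(inherits(grid, "interval_grid"), start < end)
  mid <- (grid$intervals$start + grid$intervals$end) / 2
  mid >= start & mid < end
}

#' Assemble a homology map between two karyotypes
#'
#' Records which chromosome (or bp-delimited arm segment) of dataset A
#' corresponds to which of dataset B, and whether the orientation is
#' inverted between the two.  Segment bounds `NA` mean the whole
#' chromosome.
#'
#' @param pairs A data frame with columns `chrom_a`, `chrom_b`, and
#'   optionally `start_a`, `end_a`, `start_b`, `end_b`, `inverted`.
#' @param chroms_a,chroms_b Optional character vectors of known chromosome
#'   names to validate against.
#' @return A `homology_map` data frame.
#' @export
homology_map <- function(pairs, chroms_a = NULL, chroms_b = NULL) {
  stopifnot(is.data.frame(pairs),
            all(c("chrom_a", "chrom_b") %in% names(pairs)))
  for (col in c("start_a", "end_a", "start_b", "end_b"))
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  if (is.null(pairs$inverted)) pairs$inverted <- FALSE
  if (!is.null(chroms_a) && !all(pairs$chrom_a %in% chroms_a))
    stop("homology map names unknown chromosomes in dataset A: ",
         paste(setdiff(pairs$chrom_a, chroms_a), collapse = ", "))
  if (!is.null(chroms_b) && !all(pairs$chrom_b %in% chroms_b))
    stop("homology map names unknown chromosomes in dataset B: ",
         paste(setdiff(pairs$chrom_b, chroms_b), collapse = ", "))
  class(pairs) <- c("homology_map", "data.frame")
  pairs
}

#' Export an interval grid as BED3
#'
#' @param grid An [build_interval_grid] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
grid_to_bed <- function(grid, path) {
  stopifnot(inherits(grid, "interval_grid"))
  df <- data.frame(chrom = grid$chromosome,
                   start = format(grid$intervals$start, scientific = FALSE,
                                  trim = TRUE),
                   end = format(grid$intervals$end, scientific = FALSE,
                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
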