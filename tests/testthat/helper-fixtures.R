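# Shared fixture builders: everything is generated in code at test time.

# focus table with one row per (cell, position); n_cells defaults to the
# number of cells supplied
toy_focus_table <- function(positions_per_cell, chromosome = "chr1",
                            n_cells = NULL) {
  rows <- do.call(rbind, lapply(seq_along(positions_per_cell), function(i) {
    pos <- positions_per_cell[[i]]
    if (!length(pos)) return(NULL)
    data.frame(cell_id = sprintf("c%03d", i), chromosome = chromosome,
               sc_length_um = NA_real_, position = pos,
               position_unit = "fraction")
  }))
  if (is.null(n_cells))
    n_cells <- stats::setNames(length(positions_per_cell), chromosome)
  focus_table(rows, n_cells = n_cells)
}

# hand-built feature track aligned to a grid
toy_feature_track <- function(grid, chrom_name, gc = NULL, cgi = NULL,
                              gene_pct = NULL) {
  n <- grid$n_intervals
  structure(
    data.frame(chrom = chrom_name,
               start = grid$intervals$start, end = grid$intervals$end,
               gc = gc %||% rep(0.45, n),
               cgi_count = cgi %||% rep(1L, n),
               gene_count = rep(1L, n),
               gene_pct = gene_pct %||% rep(100 / n, n)),
    class = c("feature_track", "data.frame"),
    interval_size = grid$interval_size)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
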