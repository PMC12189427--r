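# Synthetic genomes and MLH1 focus datasets with planted structure.
#
# The focus simulator encodes the two crossover landscapes under study:
# "homogeneous_terminal" (chicken-like: elevated rates near the ends over a
# substantial uniform background) and "polarized" (guinea-fowl-like: most
# crossovers packed into the distal fifth of the chromosome, recombination
# deserts in the middle).  The genome simulator plants a smooth GC
# landscape, CpG islands on a CpG-depleted background, and gene starts, and
# can couple the GC landscape to the crossover placement intensity with a
# chosen Spearman correlation, giving the association module a known
# recovery target.

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the crossover (MLH1 focus) simulator
#'
#' Crossover counts per cell and bivalent are Poisson(`co_mean`), optionally
#' resampled to at least 1 (`obligate_co`, the obligate chiasma).  Each
#' crossover position along the axis (fraction of axis length, short-arm
#' tip at 0) is drawn from a two-component mixture: with probability
#' `terminal_weight` from a terminal component — a Beta(1, 8) variate scaled
#' to `[0, terminal_span]` and assigned to either end with equal
#' probability, so the terminal component's support is exactly the two
#' terminal spans — and otherwise uniform on (0, 1).
#'
#' Regime defaults: `homogeneous_terminal` uses `terminal_weight = 0.4`
#' (end-elevated but substantial interstitial recombination);
#' `polarized` uses `terminal_weight = 0.8` (about 80% of crossovers within
#' the distal fifth of the chromosome).  Both default to
#' `terminal_span = 0.2`.
#'
#' @param regime `"homogeneous_terminal"` or `"polarized"`.
#' @param n_cells Number of cells scored per chromosome.
#' @param co_mean Mean crossovers per bivalent (>= 0).
#' @param obligate_co Enforce at least one crossover per bivalent.
#' @param terminal_weight Mixture weight of the terminal component, in
#'   `[0, 1]`; defaults by regime.
#' @param terminal_span Fraction of axis length per end defining "terminal",
#'   in `(0, 0.5)`.
#' @param seed Integer seed.
#' @return A `focus_sim_params` list.
#' @export
focus_sim_params <- function(regime = c("homogeneous_terminal", "polarized"),
                             n_cells = 135L, co_mean = 2, obligate_co = TRUE,
                             terminal_weight = NULL, terminal_span = 0.2,
                             seed = 1L) {
  regime <- match.arg(regime)
  if (is.null(terminal_weight))
    terminal_weight <- if (regime == "polarized") 0.8 else 0.4
  stopifnot(n_cells >= 1, co_mean >= 0, is.logical(obligate_co),
            terminal_weight >= 0, terminal_weight <= 1,
            terminal_span > 0, terminal_span < 0.5)
  structure(list(regime = regime, n_cells = as.integer(n_cells),
                 co_mean = co_mean, obligate_co = obligate_co,
                 terminal_weight = terminal_weight,
                 terminal_span = terminal_span, seed = as.integer(seed)),
            class = "focus_sim_params")
}

# mixture positions for one batch of crossovers
.draw_positions <- function(k, terminal_weight, terminal_span) {
  if (k == 0L) return(numeric(0))
  terminal <- stats::runif(k) < terminal_weight
  pos <- stats::runif(k)
  nt <- sum(terminal)
  if (nt > 0L) {
    x <- terminal_span * stats::rbeta(nt, 1, 8)
    right <- stats::runif(nt) < 0.5
    pos[terminal] <- ifelse(right, 1 - x, x)
  }
  pos
}

#' Simulate an MLH1 focus dataset
#'
#' For each chromosome model and each of `n_cells` cells, draws a crossover
#' count and positions per [focus_sim_params]; emits one row per focus.
#' When a per-interval placement `intensity` is supplied for a chromosome
#' (as produced by [simulate_genome]), positions are instead drawn by
#' sampling an interval proportional to its intensity and then uniformly
#' within it — this is how a planted feature-recombination coupling is
#' realized.  Deterministic given `params$seed`.
#'
#' @param params A [focus_sim_params] object.
#' @param chroms List of [chromosome_model]s.
#' @param intensity Optional named list (by chromosome) with elements
#'   `grid` (an `interval_grid`) and `weights` (per-interval non-negative
#'   placement weights).
#' @param position_unit `"fraction"` (default) or `"um"`; micrometre output
#'   uses a per-cell SC length drawn around the chromosome's
#'   `mean_sc_length` (cv 8%), mimicking between-cell axis variation.
#' @return A [focus_table] with `n_cells` set per chromosome.
#' @export
simulate_focus_dataset <- function(params, chroms, intensity = NULL,
                                   position_unit = c("fraction", "um")) {
  stopifnot(inherits(params, "focus_sim_params"))
  position_unit <- match.arg(position_unit)
  if (inherits(chroms, "chromosome_model")) chroms <- list(chroms)
  .with_seed(params$seed, {
    rows <- list()
    for (chrom in chroms) {
      stopifnot(inherits(chrom, "chromosome_model"))
      n <- params$n_cells
      counts <- stats::rpois(n, params$co_mean)
      if (params$obligate_co) {
        while (any(counts == 0L))
          counts[counts == 0L] <- stats::rpois(sum(counts == 0L),
                                               params$co_mean)
      }
      sc_len <- if (!is.null(chrom$mean_sc_length)) {
        pmax(stats::rnorm(n, chrom$mean_sc_length,
                          0.08 * chrom$mean_sc_length),
             0.5 * chrom$mean_sc_length)
      } else rep(NA_real_, n)

      total <- sum(counts)
      if (total == 0L) next
      iw <- if (!is.null(intensity)) intensity[[chrom$name]] else NULL
      if (!is.null(iw)) {
        g <- iw$grid
        w <- iw$weights
        stopifnot(inherits(g, "interval_grid"), length(w) == g$n_intervals,
                  all(w >= 0), sum(w) > 0)
        idx <- sample.int(g$n_intervals, total, replace = TRUE, prob = w)
        lo <- g$intervals$start[idx] / g$assembly_length
        hi <- g$intervals$end[idx] / g$assembly_length
        pos <- stats::runif(total, lo, hi)
      } else {
        pos <- .draw_positions(total, params$terminal_weight,
                               params$terminal_span)
      }
      cell <- rep(seq_len(n), counts)
      df <- data.frame(
        cell_id = sprintf("cell%04d", cell),
        chromosome = chrom$name,
        sc_length_um = sc_len[cell],
        position = if (position_unit == "um") pos * sc_len[cell] else pos,
        position_unit = position_unit)
      rows[[length(rows) + 1L]] <- df
    }
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(cell_id = character(0), chromosome = character(0),
                 sc_length_um = numeric(0), position = numeric(0),
                 position_unit = character(0))
    n_cells <- stats::setNames(
      rep(params$n_cells, length(chroms)),
      vapply(chroms, `[[`, character(1), "name"))
    focus_table(df, n_cells = n_cells)
  })
}

#' Parameters for the genome simulator
#'
#' @param lengths Chromosome lengths in bp (named vector names become
#'   chromosome names; otherwise `simchr1..k`).
#' @param gc_baseline Genome-wide mean GC (default 0.42, typical of avian
#'   macrochromosomes).
#' @param gc_amplitude Half-range of the planted interval-scale GC
#'   landscape; `gc_baseline +- gc_amplitude` must stay inside (0, 1).
#' @param cgi_rate Planted CpG islands per Mb.
#' @param genes_per_Mb Gene starts per Mb (Poisson process).
#' @param coupling_rho Planted Spearman correlation between the GC
#'   landscape and the crossover placement intensity, in `[-1, 1]`.
#' @param cpg_depletion Probability that a background CpG dinucleotide is
#'   dissolved (swapped to GpC), giving the island caller contrast.  The
#'   default (0.98) depletes the background more strongly than real
#'   vertebrate genomes (obs/exp about 0.2) so that planted islands are the
#'   only island-calling signal.
#' @param seed Integer seed.
#' @return A `genome_sim_params` list.
#' @export
genome_sim_params <- function(lengths, gc_baseline = 0.42,
                              gc_amplitude = 0.05, cgi_rate = 8,
                              genes_per_Mb = 12, coupling_rho = 0,
                              cpg_depletion = 0.98, seed = 1L) {
  stopifnot(length(lengths) >= 1, all(lengths > 0),
            gc_baseline - gc_amplitude > 0,
            gc_baseline + gc_amplitude < 1, gc_amplitude >= 0,
            cgi_rate >= 0, genes_per_Mb >= 0,
            coupling_rho >= -1, coupling_rho <= 1,
            cpg_depletion >= 0, cpg_depletion <= 1)
  if (is.null(names(lengths)))
    names(lengths) <- sprintf("simchr%d", seq_along(lengths))
  structure(list(lengths = lengths, gc_baseline = gc_baseline,
                 gc_amplitude = gc_amplitude, cgi_rate = cgi_rate,
                 genes_per_Mb = genes_per_Mb, coupling_rho = coupling_rho,
                 cpg_depletion = cpg_depletion, seed = as.integer(seed)),
            class = "genome_sim_params")
}

# CpG-enriched, GC-rich island sequence of exactly len bases
.island_seq <- function(len) {
  tok <- sample(c("CG", "A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.25, 0.1125, 0.2625, 0.2625, 0.1125))
  v <- strsplit(paste(tok, collapse = ""), "")[[1]]
  v[seq_len(len)]
}

#' Simulate a genome with planted GC landscape, CpG islands and genes
#'
#' Per chromosome: a per-interval GC landscape
#' `gc_i = gc_baseline + gc_amplitude * (2 * pnorm(z_i) - 1)` is planted
#' from standard normal deviates `z_i`; a crossover placement intensity is
#' planted from deviates coupled to the `z_i` by a Gaussian copula tuned so
#' that the Spearman correlation between GC and intensity equals
#' `coupling_rho` in expectation (`r = 2 sin(pi * rho / 6)` on the normal
#' scale; exact equality of deviates for `|rho| = 1`).  Bases are sampled
#' i.i.d. at each interval's GC target, background CpGs are depleted by
#' GpC swaps, and CpG islands (> 200 bp, GC-rich, CpG-enriched) are planted
#' at `cgi_rate` per Mb without overlap.  Gene starts follow a uniform
#' Poisson process at `genes_per_Mb`.
#'
#' @param params A [genome_sim_params] object.
#' @param interval_size Grid interval size in bp for the planted tracks.
#' @param realize_sequence If `FALSE`, skip base-level sequence sampling
#'   and return only the planted tracks, island coordinates and genes
#'   (`sequences` empty).  Used by fast statistical checks where only the
#'   planted landscape matters; the RNG stream differs from a realized run.
#' @return List with `sequences` (named character vector), `genes` (data
#'   frame `chrom`, `start`, `end`, `strand`, `gene_id`), and `truth`: per
#'   chromosome the `grid`, planted `gc` and `intensity` tracks, and the
#'   planted `islands` table.
#' @export
simulate_genome <- function(params, interval_size = 2.5e6,
                            realize_sequence = TRUE) {
  stopifnot(inherits(params, "genome_sim_params"))
  .with_seed(params$seed, {
    sequences <- character(0)
    gene_rows <- list()
    truth <- list()
    rho <- params$coupling_rho
    r <- if (abs(rho) == 1) rho else 2 * sin(pi * rho / 6)

    for (ci in seq_along(params$lengths)) {
      name <- names(params$lengths)[ci]
      len <- as.numeric(params$lengths[[ci]])
      grid <- build_interval_grid(
        chromosome_model(name, len), interval_size)
      k <- grid$n_intervals

      z_g <- stats::rnorm(k)
      z_e <- if (abs(rho) == 1) sign(rho) * z_g else
        r * z_g + sqrt(1 - r^2) * stats::rnorm(k)
      gc_i <- params$gc_baseline +
        params$gc_amplitude * (2 * stats::pnorm(z_g) - 1)
      intensity <- exp(0.6 * z_e)
      intensity <- intensity / mean(intensity)

      if (realize_sequence) {
        # background sequence, interval by interval at the planted GC
        chunks <- vector("list", k)
        for (i in seq_len(k)) {
          m <- grid$intervals$end[i] - grid$intervals$start[i]
          p <- c((1 - gc_i[i]) / 2, gc_i[i] / 2, gc_i[i] / 2,
                 (1 - gc_i[i]) / 2)
          chunks[[i]] <- sample(c("A", "C", "G", "T"), m, replace = TRUE,
                                prob = p)
        }
        v <- unlist(chunks, use.names = FALSE)

        # CpG depletion: dissolve background CpGs by swapping to GpC.
        # Swapping can create new CpGs at the junctions, so iterate a few
        # passes; the residual obs/exp drops well below the island
        # threshold.
        if (params$cpg_depletion > 0) {
          for (pass in 1:4) {
            cg <- which(v[-length(v)] == "C" & v[-1L] == "G")
            if (!length(cg)) break
            swap <- cg[stats::runif(length(cg)) < params$cpg_depletion]
            # avoid adjacent swaps clobbering each other within a pass
            swap <- swap[c(TRUE, diff(swap) > 1L)]
            if (!length(swap)) break
            v[swap] <- "G"; v[swap + 1L] <- "C"
          }
        }
      }

      # plant non-overlapping islands
      n_isl <- stats::rpois(1L, params$cgi_rate * len / 1e6)
      isl <- data.frame(start = numeric(0), end = numeric(0))
      if (n_isl > 0L) {
        taken <- integer(0)
        tries <- 0L
        while (nrow(isl) < n_isl && tries < 50L * n_isl) {
          tries <- tries + 1L
          ilen <- 250L + round(stats::rexp(1L, 1 / 400))
          if (ilen >= len) next
          s <- floor(stats::runif(1L, 0, len - ilen))  # 0-based
          if (any(taken >= s - 1 & taken < s + ilen + 1)) next
          if (realize_sequence) v[(s + 1):(s + ilen)] <- .island_seq(ilen)
          isl <- rbind(isl, data.frame(start = s, end = s + ilen))
          taken <- c(taken, seq(s, s + ilen - 1, by = 50), s + ilen - 1)
        }
        isl <- isl[order(isl$start), , drop = FALSE]
      }

      # gene starts: uniform Poisson process
      n_genes <- stats::rpois(1L, params$genes_per_Mb * len / 1e6)
      if (n_genes > 0L) {
        starts <- sort(floor(stats::runif(n_genes, 0, len)))
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = name, start = starts,
          end = pmin(starts + 1000, len), strand = "+",
          gene_id = sprintf("%s_g%04d", name, seq_len(n_genes)))
      }

      if (realize_sequence) sequences[name] <- paste(v, collapse = "")
      truth[[name]] <- list(grid = grid, gc = gc_i, intensity = intensity,
                            islands = isl, n_genes = n_genes)
    }
    genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(chrom = character(0), start = numeric(0),
                 end = numeric(0), strand = character(0),
                 gene_id = character(0))
    list(sequences = sequences, genes = genes, truth = truth,
         params = params, interval_size = interval_size)
  })
}

#' Run the full pipeline on simulated data and report parameter recovery
#'
#' Simulates a genome and a focus dataset whose placement follows the
#' genome's planted intensity, runs binning, cM conversion, feature
#' profiling and pooled correlation, and reports the quantities the
#' simulation controls: total map length against `50 * co_mean` per
#' chromosome, the fraction of foci in the terminal regions (both the
#' distal 10%-per-end and 20%-per-end definitions), the mean rate over the
#' central third, and the recovered pooled Spearman rho between rate and GC
#' against the planted `coupling_rho`.
#'
#' @param focus_params A [focus_sim_params] object.
#' @param genome_params A [genome_sim_params] object.
#' @param interval_size Grid interval size in bp.
#' @param use_sequence If `TRUE`, feature tracks are measured from the
#'   realized sequence via [feature_profile]; if `FALSE`, the planted
#'   per-interval tracks are used directly (fast path — skips only the
#'   base-sampling noise).
#' @param mode Correlation mode, `"all"` or `"nonzero_only"`.
#' @return A list of class `recovery_report`.
#' @export
end_to_end_recovery <- function(focus_params, genome_params,
                                interval_size = 2.5e6, use_sequence = TRUE,
                                mode = "all") {
  genome <- simulate_genome(genome_params, interval_size,
                            realize_sequence = use_sequence)
  chrom_names <- names(genome_params$lengths)
  chroms <- lapply(chrom_names, function(nm)
    chromosome_model(nm, genome_params$lengths[[nm]],
                     mean_sc_length = genome_params$lengths[[nm]] / 7.9e6))
  names(chroms) <- chrom_names
  intensity <- lapply(genome$truth, function(t)
    list(grid = t$grid, weights = t$intensity))

  foci <- simulate_focus_dataset(focus_params, chroms,
                                 intensity = intensity)

  rec <- list(); feat <- list(); central <- numeric(0)
  for (nm in chrom_names) {
    grid <- genome$truth[[nm]]$grid
    rec[[nm]] <- recombination_track(foci, grid, chroms[[nm]])
    if (use_sequence) {
      feat[[nm]] <- suppressWarnings(
        feature_profile(genome$sequences[[nm]], genome$genes, grid,
                        chroms[[nm]]))
    } else {
      t <- genome$truth[[nm]]
      idx <- if (nrow(t$islands)) bp_to_interval_index(t$islands$start, grid)
             else integer(0)
      g <- genome$genes[genome$genes$chrom == nm, , drop = FALSE]
      gidx <- if (nrow(g)) bp_to_interval_index(g$start, grid) else integer(0)
      gene_count <- tabulate(gidx, nbins = grid$n_intervals)
      feat[[nm]] <- structure(
        data.frame(chrom = nm, start = grid$intervals$start,
                   end = grid$intervals$end, gc = t$gc,
                   cgi_count = tabulate(idx, nbins = grid$n_intervals),
                   gene_count = gene_count,
                   gene_pct = if (sum(gene_count) > 0)
                     100 * gene_count / sum(gene_count) else NA_real_),
        class = c("feature_track", "data.frame"),
        interval_size = grid$interval_size)
    }
    mid <- (grid$intervals$start + grid$intervals$end) / 2
    ctr <- mid >= grid$assembly_length / 3 &
      mid < 2 * grid$assembly_length / 3
    central <- c(central, rec[[nm]]$rate_cM_per_Mb[ctr])
  }

  assoc <- suppressWarnings(
    correlate_tracks(rec, feat, mode = mode, features = "gc",
                     pooled = chrom_names))
  pooled_row <- assoc[grepl("^pooled_", assoc$scope), , drop = FALSE]

  obs_map <- map_length(foci) / length(chrom_names)
  structure(list(
    map_length_per_chrom_cM = obs_map,
    expected_map_length_cM = 50 * focus_params$co_mean,
    terminal_fraction_10pct = mean(foci$fraction <= 0.1 |
                                     foci$fraction >= 0.9),
    terminal_fraction_20pct = mean(foci$fraction <= 0.2 |
                                     foci$fraction >= 0.8),
    central_third_mean_rate = mean(central),
    pooled_rho_gc = pooled_row$rho[1],
    pooled_p_gc = pooled_row$p_value[1],
    planted_coupling_rho = genome_params$coupling_rho,
    n_foci = nrow(foci),
    associations = assoc), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  map length/chrom: %.2f cM (expected %.2f)\n",
              x$map_length_per_chrom_cM, x$expected_map_length_cM))
  cat(sprintf("  terminal focus fraction: %.3f (10%%/end), %.3f (20%%/end)\n",
              x$terminal_fraction_10pct, x$terminal_fraction_20pct))
  cat(sprintf("  central-third mean rate: %.3f cM/Mb\n",
              x$central_third_mean_rate))
  cat(sprintf("  pooled rho(rate, GC): %.3f (p = %.3g; planted %.2f)\n",
              x$pooled_rho_gc, x$pooled_p_gc, x$planted_coupling_rho))
  invisible(x)
}
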