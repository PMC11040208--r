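# Windowed nucleotide diversity, pi-ratio tracks, empirical thresholds and
# sweep-interval calling.

#' Per-site nucleotide diversity from allele counts
#'
#' Nei's frequency-based estimator with the small-sample correction:
#' \deqn{\pi = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)}
#' with `n` called alleles and allele frequencies `p_i`.  This equals the
#' fraction of differing pairs among all `choose(n, 2)` allele pairs at the
#' site; for biallelic counts `(c, n-c)` it reduces to `2c(n-c)/(n(n-1))`.
#'
#' @param counts integer vector of per-allele called counts at one site
#'   (any number of alleles; missing alleles simply do not count).
#' @return per-site diversity in `[0, 1]`, or `NA` when fewer than 2 called
#'   alleles are available (the site is skipped, not an error).
#' @export
site_pi <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# Vectorised per-site pi for one sample subset: returns numeric vector over
# records (NA where < 2 called alleles).
site_pi_vec <- function(tab, sample_idx) {
  A1 <- tab$a1[, sample_idx, drop = FALSE]
  A2 <- tab$a2[, sample_idx, drop = FALSE]
  n <- rowSums(!is.na(A1)) + rowSums(!is.na(A2))
  kmax <- max(1L, lengths(tab$alt))
  sumsq <- numeric(length(n))
  for (j in 0:kmax) {
    cj <- rowSums(A1 == j, na.rm = TRUE) + rowSums(A2 == j, na.rm = TRUE)
    sumsq <- sumsq + cj^2
  }
  pi <- ifelse(n >= 2, n / (n - 1) * (1 - sumsq / n^2), NA_real_)
  pi
}

#' Tile a chromosome with sliding windows
#'
#' @param chrom chromosome id.
#' @param chrom_length chromosome length in bp.
#' @param window window size in bp (default 100 kb).
#' @param step step between window starts in bp (default 10 kb).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).  When
#'   `chrom_length < window` a single `[0, chrom_length)` window is returned.
#' @export
make_windows <- function(chrom, chrom_length, window = 1e5, step = 1e4) {
  stopifnot(window >= 1, step >= 1, chrom_length >= 1)
  if (chrom_length < window)
    return(data.frame(chrom = chrom, start = 0, end = as.numeric(chrom_length)))
  starts <- seq(0, chrom_length - window, by = step)
  data.frame(chrom = chrom, start = starts, end = starts + window)
}

#' Sliding-window nucleotide diversity per population group
#'
#' Window diversity is the sum of per-site [site_pi()] over polymorphic sites
#' in the window, divided by the window length in bp: positions absent from
#' the VCF are assumed invariant and contribute zero.  Missing genotypes are
#' excluded per site (reducing `n`); sites with fewer than 2 called alleles
#' in a group are skipped.  InDels count as single sites at their VCF
#' position regardless of length.
#'
#' @param tab a [variant_table()].
#' @param panel a [pop_panel()] mapping accessions to groups.
#' @param groups group labels to scan (default: all groups in the panel).
#'   Each must have at least 2 accessions present in the table.
#' @param chrom chromosome to scan (default: the single chromosome in `tab`).
#' @param chrom_length length used to tile windows; defaults to the VCF
#'   contig header, falling back to the maximum variant position.
#' @param window,step window and step size in bp.  The scan defaults (100 kb
#'   windows, 10 kb step) are conventional for tomato resequencing sweep
#'   scans and fully configurable.
#' @param windows optional pre-built window data.frame (`chrom,start,end`,
#'   0-based half-open), overriding `window`/`step`.
#' @return data.frame of class `diversity_track`: `chrom`, `start`, `end`,
#'   one `pi_<group>` and one `n_sites_<group>` column per group.
#' @export
window_pi <- function(tab, panel, groups = NULL, chrom = NULL,
                      chrom_length = NULL, window = 1e5, step = 1e4,
                      windows = NULL) {
  groups <- groups %||% unique(panel$group)
  if (is.null(chrom)) {
    chrom <- unique(tab$chrom)
    if (length(chrom) != 1)
      stop2("table spans several chromosomes; pass `chrom`")
  }
  on_chr <- tab$chrom == chrom
  if (is.null(windows)) {
    chrom_length <- chrom_length %||%
      (if (!is.null(tab$contig_lengths) && chrom %in% names(tab$contig_lengths))
        as.numeric(tab$contig_lengths[[chrom]])
       else if (any(on_chr)) max(tab$pos[on_chr]) else 1)
    windows <- make_windows(chrom, chrom_length, window, step)
  }
  sub <- subset_variants(tab, on_chr)
  pos0 <- sub$pos - 1          # already sorted
  res <- windows
  for (g in groups) {
    acc <- panel$accession[panel$group == g]
    idx <- which(sub$samples %in% acc)
    if (length(idx) < 2)
      stop2("group '", g, "' has fewer than 2 accessions in the table")
    spi <- site_pi_vec(sub, idx)
    used <- !is.na(spi) & spi > 0
    cum_pi <- cumsum(ifelse(is.na(spi), 0, spi))
    cum_n <- cumsum(as.integer(used))
    lo <- findInterval(windows$start - 0.5, pos0)
    hi <- findInterval(windows$end - 0.5, pos0)
    at <- function(cs, i) ifelse(i > 0, cs[pmax(i, 1)], 0)
    res[[paste0("pi_", g)]] <-
      (at(cum_pi, hi) - at(cum_pi, lo)) / (windows$end - windows$start)
    res[[paste0("n_sites_", g)]] <- as.integer(at(cum_n, hi) - at(cum_n, lo))
  }
  structure(res, class = c("diversity_track", "data.frame"),
            groups = groups, window = window, step = step)
}

#' Per-window pi ratio between two groups
#'
#' Windows where the denominator diversity is zero are masked (`ratio = NA`,
#' `defined = FALSE`) rather than given a pseudocount: pseudocounts would
#' distort the empirical quantile that defines the sweep threshold.
#'
#' @param track a `diversity_track` from [window_pi()].
#' @param num,den numerator and denominator group labels (e.g. `"CER"`,
#'   `"BIG"` for the improvement contrast).
#' @return data.frame of class `ratio_track`: `chrom`, `start`, `end`,
#'   `ratio`, `defined`; attribute `contrast` is `"num/den"`.
#' @export
pi_ratio <- function(track, num, den) {
  cn <- paste0("pi_", num); cd <- paste0("pi_", den)
  if (!all(c(cn, cd) %in% names(track)))
    stop2("groups '", num, "' and '", den, "' must both be present in the track")
  defined <- track[[cd]] > 0
  ratio <- ifelse(defined, track[[cn]] / track[[cd]], NA_real_)
  structure(data.frame(chrom = track$chrom, start = track$start,
                       end = track$end, ratio = ratio, defined = defined),
            class = c("ratio_track", "data.frame"),
            contrast = paste0(num, "/", den))
}

#' Empirical nearest-rank quantile of a ratio track
#'
#' The threshold is the k-th smallest defined ratio with `k = ceiling(q * m)`
#' (`m` defined windows) — the interpolation-free nearest-rank quantile, for
#' bit-reproducibility across numeric libraries.
#'
#' @param x a `ratio_track` or a numeric vector of ratios.
#' @param q quantile level (default 0.95 = "top 5%" threshold).
#' @return the threshold value.
#' @export
empirical_threshold <- function(x, q = 0.95) {
  vals <- if (is.data.frame(x)) x$ratio[x$defined] else x[!is.na(x)]
  m <- length(vals)
  if (m == 0) stop2("no defined windows: cannot take a quantile")
  if (m * (1 - q) < 1)
    warn2("only ", m, " defined windows for q = ", q,
          "; the empirical quantile is poorly resolved")
  sort(vals)[ceiling(q * m)]
}

#' Call sweep intervals from a ratio track
#'
#' Windows with `ratio >= threshold` qualify (masked windows never do);
#' adjacent or overlapping qualifying windows are merged into intervals.  A
#' gap tolerance of `max_gap` windows may optionally bridge short
#' non-qualifying runs (default 0: no bridging).
#'
#' @param x a `ratio_track`.
#' @param threshold ratio threshold, typically from [empirical_threshold()].
#' @param max_gap number of consecutive non-qualifying windows allowed inside
#'   one merged interval.
#' @return data.frame of class `sweep_calls`: `chrom`, `start`, `end`,
#'   `n_windows`, `max_ratio`; attributes `threshold` and `contrast`.
#' @export
call_sweeps <- function(x, threshold, max_gap = 0) {
  qual <- which(!is.na(x$ratio) & x$ratio >= threshold)
  if (!length(qual)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      max_ratio = numeric(0))
  } else {
    run <- cumsum(c(1, diff(qual) > max_gap + 1))
    out <- do.call(rbind, lapply(split(qual, run), function(i)
      data.frame(chrom = x$chrom[i[1]], start = min(x$start[i]),
                 end = max(x$end[i]), n_windows = length(i),
                 max_ratio = max(x$ratio[i]))))
    rownames(out) <- NULL
    # merge genomically if runs still touch (possible when step > window)
    if (nrow(out) > 1) {
      keep <- list(out[1, ])
      for (r in 2:nrow(out)) {
        last <- keep[[length(keep)]]
        if (out$start[r] <= last$end) {
          last$end <- max(last$end, out$end[r])
          last$n_windows <- last$n_windows + out$n_windows[r]
          last$max_ratio <- max(last$max_ratio, out$max_ratio[r])
          keep[[length(keep)]] <- last
        } else keep <- c(keep, list(out[r, ]))
      }
      out <- do.call(rbind, keep)
      rownames(out) <- NULL
    }
  }
  structure(out, class = c("sweep_calls", "data.frame"),
            threshold = threshold, contrast = attr(x, "contrast"))
}

#' Classify a gene relative to a sweep call set
#'
#' @param calls a `sweep_calls` data.frame (0-based half-open intervals).
#' @param gene one row of a `gene_models` data.frame (1-based `start`/`end`).
#' @return `"within_sweep"` if the gene span overlaps any sweep interval
#'   (half-open overlap), else `"outside_sweep"`.  A chromosome mismatch
#'   yields `"outside_sweep"` with a warning.
#' @export
locate_locus <- function(calls, gene) {
  g_start <- gene$start - 1
  g_end <- as.numeric(gene$end)
  if (nrow(calls) && !any(calls$chrom == gene$chrom)) {
    warn2("gene '", gene$gene_id, "' is on ", gene$chrom,
          " but sweep calls are not")
    return("outside_sweep")
  }
  hit <- calls$chrom == gene$chrom & calls$start < g_end & g_start < calls$end
  if (any(hit)) "within_sweep" else "outside_sweep"
}
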