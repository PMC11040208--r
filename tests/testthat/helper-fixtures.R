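# Shared fixture builders: all fixtures are generated in code at test time.

options(sweephap.verbose = FALSE)

toy_vcf <- function(path, body, samples = c("S1", "S2"), contig = "chr8",
                    contig_len = 100000, extra_header = character(0)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, contig_len),
           extra_header,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

vrow <- function(pos, ref = "A", alt = "G", gts, chrom = "chr8", info = ".")
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", info, "GT", gts),
        collapse = "\t")

# Random variant table built directly in memory (multiallelics, InDels and
# missing genotypes included), for oracle comparisons.
rand_table <- function(n_samples = 6, n_sites = 30, L = 1000, miss = 0.1,
                       p_multi = 0.15, p_indel = 0.1, chrom = "chrT") {
  pos <- sort(sample.int(L, n_sites))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, TRUE)
  alt <- lapply(seq_len(n_sites), function(i) {
    a <- sample(setdiff(bases, ref[i]), 1 + rbinom(1, 1, p_multi))
    if (runif(1) < p_indel) a[1] <- paste0(a[1], "T")
    a
  })
  nalt <- lengths(alt)
  draw <- function() {
    m <- matrix(NA_integer_, n_sites, n_samples)
    for (i in seq_len(n_sites))
      m[i, ] <- sample(0:nalt[i], n_samples, replace = TRUE)
    m[matrix(runif(n_sites * n_samples) < miss, n_sites)] <- NA_integer_
    m
  }
  variant_table(rep(chrom, n_sites), pos, ref, alt, draw(), draw(),
                sprintf("S%02d", seq_len(n_samples)),
                contig_lengths = setNames(as.integer(L), chrom))
}

# Exhaustive pairwise oracle: per site, enumerate every pair of called
# alleles and count differing pairs; sum over in-window sites / length.
oracle_window_pi <- function(tab, sample_idx, start, end) {
  tot <- 0
  for (i in seq_along(tab$pos)) {
    p0 <- tab$pos[i] - 1
    if (p0 < start || p0 >= end) next
    v <- c(tab$a1[i, sample_idx], tab$a2[i, sample_idx])
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 2) next
    d <- 0
    for (x in 1:(n - 1)) for (y in (x + 1):n) if (v[x] != v[y]) d <- d + 1
    tot <- tot + d / choose(n, 2)
  }
  tot / (end - start)
}

gene_row <- function(id = "g1", chrom = "chr8", strand = "+", start, end, atg)
  structure(data.frame(gene_id = id, chrom = chrom, strand = strand,
                       start = start, end = end, atg_pos = atg,
                       stringsAsFactors = FALSE),
            class = c("gene_models", "data.frame"))

# Promoter fixture: 8 SNPs (one at rel -1903) + 1 InDel inside the 3-kb
# window, 2 variants outside (one exactly at the ATG first base).  The -
# strand version mirrors the + strand geometry.
promoter_fixture <- function(strand = "+") {
  rel <- c(-2900, -2501, -2001, -1903, -1401, -1001, -501, -101)
  if (strand == "+") {
    atg <- 10001
    snp_pos <- atg + rel
    indel_pos <- atg - 1201
    out_pos <- c(6950, atg)        # upstream of window; at the ATG itself
    gene <- gene_row(strand = "+", start = atg, end = atg + 1500, atg = atg)
  } else {
    atg <- 10000
    snp_pos <- atg - rel
    indel_pos <- atg + 1201
    out_pos <- c(13050, atg)
    gene <- gene_row(strand = "-", start = atg - 1500, end = atg, atg = atg)
  }
  pos <- c(snp_pos, indel_pos, out_pos)
  ref <- c(rep("A", 8), "G", "C", "C")
  alt <- as.list(c(rep("G", 8), "GTT", "T", "T"))
  n <- length(pos)
  a1 <- matrix(0L, n, 2); a2 <- matrix(1L, n, 2)
  tab <- variant_table(rep("chr8", n), pos, ref, alt, a1, a2, c("S1", "S2"),
                       contig_lengths = c(chr8 = 20000L))
  list(tab = tab, gene = gene)
}

# Per-site pi vector computed through the public estimator from raw counts.
site_pi_for_test <- function(tab) {
  vapply(seq_along(tab$pos), function(i) {
    v <- c(tab$a1[i, ], tab$a2[i, ])
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    site_pi(tabulate(v + 1, nbins = max(v) + 1))
  }, numeric(1))
}

jaccard_calls <- function(calls, a, b) {
  if (!nrow(calls)) return(0)
  inter <- sum(pmax(0, pmin(calls$end, b) - pmax(calls$start, a)))
  len <- sum(calls$end - calls$start)
  inter / (len + (b - a) - inter)
}

# Small ratio track for threshold / sweep-call unit tests.
ratio_track_fixture <- function(ratio, win = 10) {
  n <- length(ratio)
  structure(data.frame(chrom = "chrT", start = (0:(n - 1)) * win,
                       end = (1:n) * win, ratio = ratio,
                       defined = !is.na(ratio)),
            class = c("ratio_track", "data.frame"), contrast = "A/B")
}
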