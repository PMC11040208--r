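# Variant container and VCF I/O.
#
# Coordinate convention: VCF and GFF3 are 1-based inclusive on disk; every
# internal interval (windows, sweep intervals, promoter windows) is 0-based
# half-open.  Conversion happens only at the I/O boundary.

#' Construct a variant table
#'
#' The central in-memory container: position-sorted variant records with a
#' diploid genotype matrix over an ordered set of accessions.  Genotypes are
#' stored as two allele-index matrices (`a1`, `a2`; 0 = REF, 1.. = ALT,
#' `NA` = missing).  Phase is not retained: every downstream statistic is
#' allele-frequency based.
#'
#' @param chrom character vector of chromosome ids, one per record.
#' @param pos integer vector of 1-based reference positions.
#' @param ref character vector of reference alleles (`A/C/G/T`, `N` tolerated).
#' @param alt list of character vectors of alternate alleles, one per record.
#' @param a1,a2 integer matrices (records x accessions) of allele indices.
#' @param samples character vector of accession ids (column order of `a1`/`a2`).
#' @param contig_lengths optional named integer vector of chromosome lengths.
#' @return An object of class `variant_table` with elements `chrom`, `pos`,
#'   `ref`, `alt`, `vtype` (`"SNP"` or `"InDel"`), `a1`, `a2`, `samples`,
#'   `contig_lengths`.  Records are sorted by (chrom, pos).
#' @export
variant_table <- function(chrom, pos, ref, alt, a1, a2, samples,
                          contig_lengths = NULL) {
  n <- length(pos)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            nrow(a1) == n, nrow(a2) == n,
            ncol(a1) == length(samples), ncol(a2) == length(samples))
  pos <- as.integer(pos)
  if (n && any(pos < 1L)) stop2("variant positions must be >= 1")
  alt <- unname(lapply(alt, function(a) unname(as.character(a))))
  colnames(a1) <- colnames(a2) <- as.character(samples)
  ok_allele <- function(x) grepl("^[ACGTNacgtn]+$", x)
  if (n && (!all(ok_allele(ref)) || !all(ok_allele(unlist(alt)))))
    stop2("alleles must be non-empty strings over {A,C,G,T} (N tolerated)")
  n_alt <- lengths(alt)
  amax <- suppressWarnings(pmax(apply(a1, 1, max, na.rm = TRUE),
                                apply(a2, 1, max, na.rm = TRUE)))
  amax[!is.finite(amax)] <- 0
  if (n && any(amax > n_alt))
    stop2("genotype allele index exceeds number of ALT alleles")
  vtype <- ifelse(vapply(seq_len(max(n, 0L)), function(i)
    any(nchar(alt[[i]]) != nchar(ref[i])), logical(1)), "InDel", "SNP")
  if (n == 0L) vtype <- character(0)
  o <- order(chrom, pos)
  structure(list(chrom = chrom[o], pos = pos[o], ref = as.character(ref)[o],
                 alt = alt[o], vtype = vtype[o],
                 a1 = a1[o, , drop = FALSE], a2 = a2[o, , drop = FALSE],
                 samples = as.character(samples),
                 contig_lengths = contig_lengths),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d records (%d SNP, %d InDel), %d accessions\n",
              length(x$pos), sum(x$vtype == "SNP"), sum(x$vtype == "InDel"),
              length(x$samples)))
  for (ch in unique(x$chrom)) {
    i <- x$chrom == ch
    cat(sprintf("  %s: %d records, pos %d..%d\n", ch, sum(i),
                min(x$pos[i]), max(x$pos[i])))
  }
  invisible(x)
}

#' Number of records in a variant table
#' @param x a `variant_table`.
#' @return integer record count.
#' @export
n_variants <- function(x) length(x$pos)

#' Subset a variant table by record index
#' @param x a `variant_table`.
#' @param i integer or logical index over records.
#' @return a `variant_table` with the selected records.
#' @export
subset_variants <- function(x, i) {
  variant_table(x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
                x$samples, x$contig_lengths)
}

parse_region <- function(region) {
  if (is.list(region)) return(region)
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (!length(m)) stop2("cannot parse region '", region, "'")
  list(chrom = m[2],
       start = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
       end   = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_)
}

#' Read a multi-sample VCF into a variant table
#'
#' Reads SNP and InDel records with a `GT` FORMAT field.  Structural variants
#' (symbolic ALT alleles or an `SVTYPE` INFO value) and records lacking GT are
#' skipped; the counts are logged and attached as attributes `n_sv_skipped`
#' and `n_nogt_skipped`.  Phased (`|`) and unphased (`/`) separators are
#' treated identically and `./.` becomes missing.
#'
#' @param path path to a VCF v4.x file (plain or bgzipped).
#' @param region optional `"chrom"` or `"chrom:start-end"` restriction,
#'   1-based inclusive.  An unknown chromosome yields an empty table with a
#'   warning.  Filtering is applied in memory (no index required).
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop2("VCF not found: ", path)
  v <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop2("VCF has no GT FORMAT field: ", path)
  rr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  refs <- as.character(VariantAnnotation::ref(v))
  alts <- as.list(VariantAnnotation::alt(v))
  alts <- lapply(alts, as.character)

  symbolic <- vapply(alts, function(a)
    any(grepl("[<>\\[\\]]", a) | a == "*"), logical(1))
  svtype <- rep(FALSE, length(pos))
  inf <- tryCatch(VariantAnnotation::info(v), error = function(e) NULL)
  if (!is.null(inf) && "SVTYPE" %in% names(inf))
    svtype <- !is.na(inf$SVTYPE) & nzchar(as.character(inf$SVTYPE))
  is_sv <- symbolic | svtype
  no_gt <- apply(is.na(gt), 1, all)
  keep <- !is_sv & !no_gt
  if (any(is_sv)) sh_log("skipped ", sum(is_sv), " SV record(s)")
  if (any(no_gt & !is_sv))
    sh_log("skipped ", sum(no_gt & !is_sv), " record(s) without GT")

  gt <- gt[keep, , drop = FALSE]
  f1 <- sub("[/|].*$", "", gt)
  f2 <- sub("^[^/|]*", "", gt)
  has_sep <- grepl("^[/|]", f2)
  f2 <- sub("^[/|]", "", f2)
  a1 <- suppressWarnings(matrix(as.integer(f1), nrow(gt), ncol(gt)))
  a2 <- suppressWarnings(matrix(as.integer(f2), nrow(gt), ncol(gt)))
  a2[!has_sep] <- NA_integer_   # haploid / malformed calls -> missing
  a1[!has_sep] <- NA_integer_

  cl <- GenomeInfoDb::seqlengths(v)
  cl <- cl[!is.na(cl)]
  tab <- variant_table(chrom[keep], pos[keep], refs[keep], alts[keep],
                       a1, a2, colnames(gt),
                       contig_lengths = if (length(cl)) cl else NULL)
  attr(tab, "n_sv_skipped") <- sum(is_sv)
  attr(tab, "n_nogt_skipped") <- sum(no_gt & !is_sv)
  if (!is.null(region)) {
    rg <- parse_region(region)
    if (!rg$chrom %in% tab$chrom) {
      warn2("region chromosome '", rg$chrom, "' not present in VCF")
      tab2 <- subset_variants(tab, rep(FALSE, n_variants(tab)))
    } else {
      i <- tab$chrom == rg$chrom
      if (!is.na(rg$start)) i <- i & tab$pos >= rg$start & tab$pos <= rg$end
      tab2 <- subset_variants(tab, i)
    }
    attr(tab2, "n_sv_skipped") <- attr(tab, "n_sv_skipped")
    attr(tab2, "n_nogt_skipped") <- attr(tab, "n_nogt_skipped")
    tab <- tab2
  }
  tab
}

#' Write a variant table as VCF v4.2
#'
#' Used by the fixture generator; emits a minimal, deterministic VCF (contig
#' header lines, GT-only FORMAT, unphased genotypes) that [read_vcf()]
#' round-trips exactly.
#'
#' @param x a [variant_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=sweephap %s",
                   as.character(utils::packageVersion("sweephap"))))
  if (!is.null(x$contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(x$contig_lengths),
                          as.integer(x$contig_lengths)))
  else
    hdr <- c(hdr, sprintf("##contig=<ID=%s>", unique(x$chrom)))
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  gstr <- matrix(paste0(ifelse(is.na(x$a1), ".", x$a1), "/",
                        ifelse(is.na(x$a2), ".", x$a2)),
                 nrow = n_variants(x))
  body <- paste(x$chrom, x$pos, ".", x$ref,
                vapply(x$alt, paste, "", collapse = ","),
                ".", "PASS", ".", "GT",
                apply(gstr, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
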