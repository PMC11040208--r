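# Promoter-window variant extraction, tag-SNP haplotype classification and
# group-wise haplotype distributions.

#' Strand-aware promoter window upstream of the ATG
#'
#' The promoter is the `upstream_len` bp immediately upstream of the first
#' base of the start codon (default 3 kb, the convention used for the
#' *SlSCaBP8* locus).  On the + strand that is the interval ending just
#' before the ATG; on the - strand it is the interval starting just after it
#' (in genome coordinates).  The window is clipped at the chromosome start.
#'
#' @param gene one row of a `gene_models` data.frame (`chrom`, `strand`,
#'   `atg_pos` 1-based).
#' @param upstream_len promoter length in bp (>= 1).
#' @param chrom_length optional chromosome length used to clip on the
#'   - strand.
#' @return list with `chrom`, `start`, `end` (0-based half-open).
#' @export
promoter_window <- function(gene, upstream_len = 3000, chrom_length = NULL) {
  stopifnot(upstream_len >= 1)
  atg0 <- gene$atg_pos - 1          # 0-based first base of ATG
  if (gene$strand == "+") {
    start <- max(0, atg0 - upstream_len)
    end <- atg0
  } else {
    start <- atg0 + 1
    end <- start + upstream_len
    if (!is.null(chrom_length)) end <- min(end, chrom_length)
  }
  if (end <= start)
    stop2("promoter window of gene '", gene$gene_id,
          "' lies entirely off the chromosome")
  list(chrom = gene$chrom, start = start, end = end)
}

#' Extract promoter variants relative to the ATG
#'
#' Returns every variant inside the promoter window with its signed distance
#' from the start codon (`rel_pos`; negative = upstream, e.g. -1903 for a
#' site 1903 bp upstream of the ATG).  SNPs are labelled `SNP1..SNPk` from
#' most-upstream to closest-to-ATG; InDels are labelled `InDel1..` in the
#' same order.  The labelling is a convention of this package, consistent
#' with a tag SNP at -1903 bp sitting 7th among 8 promoter SNPs.
#'
#' @param tab a [variant_table()].
#' @param gene one row of a `gene_models` data.frame.
#' @param upstream_len promoter length in bp (default 3000).
#' @return data.frame of class `promoter_variants`: `label`, `chrom`, `pos`,
#'   `rel_pos`, `ref`, `alt`, `vtype`; attributes `gene_id` and `window`.
#' @export
extract_promoter_variants <- function(tab, gene, upstream_len = 3000) {
  win <- promoter_window(gene, upstream_len,
                         chrom_length = if (!is.null(tab$contig_lengths))
                           tab$contig_lengths[[gene$chrom]] else NULL)
  pos0 <- tab$pos - 1
  sel <- which(tab$chrom == win$chrom & pos0 >= win$start & pos0 < win$end)
  rel <- if (gene$strand == "+") tab$pos[sel] - gene$atg_pos
         else gene$atg_pos - tab$pos[sel]
  o <- order(rel)                   # most upstream (most negative) first
  sel <- sel[o]; rel <- rel[o]
  vtype <- tab$vtype[sel]
  label <- character(length(sel))
  label[vtype == "SNP"] <- paste0("SNP", seq_len(sum(vtype == "SNP")))
  label[vtype == "InDel"] <- paste0("InDel", seq_len(sum(vtype == "InDel")))
  structure(data.frame(label = label, chrom = tab$chrom[sel],
                       pos = tab$pos[sel], rel_pos = rel,
                       ref = tab$ref[sel],
                       alt = vapply(tab$alt[sel], paste, "", collapse = ","),
                       vtype = vtype, stringsAsFactors = FALSE),
            class = c("promoter_variants", "data.frame"),
            gene_id = gene$gene_id, window = win)
}

#' Classify accessions into haplotypes at a tag SNP
#'
#' Classification keys on nucleotide identity, not on REF/ALT index: with a
#' cultivar-derived reference genome the wild allele is typically the ALT, so
#' keying on bases keeps the rule build-agnostic.  Homozygotes for the two
#' configured bases become `Hap1`/`Hap2`; anything else called is `Het`;
#' genotypes with a missing allele are `Missing`.
#'
#' @param tab a [variant_table()].
#' @param chrom,pos tag-SNP coordinates (1-based).
#' @param alleles named character vector mapping haplotype labels to bases,
#'   default `c(Hap1 = "G", Hap2 = "A")` (the SNP7 convention: wild G,
#'   cultivated A).  Both bases must occur among the site's alleles.
#' @return data.frame of class `hap_assignment`: `accession`, `genotype`
#'   (e.g. `"G/A"`), `haplotype`; attributes `tag` (site summary) and
#'   `alleles`.
#' @export
classify_haplotypes <- function(tab, chrom, pos,
                                alleles = c(Hap1 = "G", Hap2 = "A")) {
  i <- which(tab$chrom == chrom & tab$pos == pos)
  if (!length(i)) stop2("tag site ", chrom, ":", pos, " absent from table")
  i <- i[1]
  bases <- c(tab$ref[i], tab$alt[[i]])
  idx <- match(alleles, bases) - 1L   # allele index of each configured base
  if (anyNA(idx))
    stop2("base(s) ", paste(alleles[is.na(idx)], collapse = ", "),
          " not among site alleles (", paste(bases, collapse = "/"), ")")
  a1 <- tab$a1[i, ]; a2 <- tab$a2[i, ]
  miss <- is.na(a1) | is.na(a2)
  hap <- rep("Het", length(a1))
  hap[a1 == idx[1] & a2 == idx[1]] <- names(alleles)[1]
  hap[a1 == idx[2] & a2 == idx[2]] <- names(alleles)[2]
  hap[miss] <- "Missing"
  geno <- paste0(ifelse(is.na(a1), ".", bases[a1 + 1]), "/",
                 ifelse(is.na(a2), ".", bases[a2 + 1]))
  structure(data.frame(accession = tab$samples, genotype = geno,
                       haplotype = hap, stringsAsFactors = FALSE),
            class = c("hap_assignment", "data.frame"),
            tag = list(chrom = chrom, pos = pos, ref = tab$ref[i],
                       alt = tab$alt[[i]]),
            alleles = alleles)
}

#' Group-wise haplotype distribution
#'
#' Counts and fractions of each haplotype class per population group.
#' Heterozygous accessions are reported in their own class and `Missing`
#' separately; fractions are taken over non-missing calls, mirroring how
#' published haplotype tallies exclude unclassifiable accessions.
#'
#' @param assignment a `hap_assignment` from [classify_haplotypes()].
#' @param panel a [pop_panel()].
#' @return data.frame of class `hap_freq_table` with one row per group:
#'   `group`, `n`, one count and one `frac_` column per haplotype class, and
#'   `Missing`.
#' @export
haplotype_distribution <- function(assignment, panel) {
  m <- merge(assignment, panel, by = "accession")
  if (!nrow(m)) stop2("no accessions shared between assignment and panel")
  dropped <- nrow(assignment) - nrow(m)
  if (dropped > 0)
    sh_log(dropped, " assigned accession(s) absent from panel")
  haps <- c(names(attr(assignment, "alleles")), "Het")
  groups <- unique(panel$group)
  rows <- lapply(groups, function(g) {
    sub <- m[m$group == g, ]
    if (!nrow(sub)) warn2("group '", g, "' has no classified accessions")
    cnt <- vapply(haps, function(h) sum(sub$haplotype == h), integer(1))
    nm <- sum(cnt)
    out <- data.frame(group = g, n = nrow(sub), stringsAsFactors = FALSE)
    for (h in haps) out[[h]] <- sum(sub$haplotype == h)
    for (h in haps)
      out[[paste0("frac_", h)]] <- if (nm > 0) out[[h]] / nm else 0
    out$Missing <- sum(sub$haplotype == "Missing")
    out
  })
  structure(do.call(rbind, rows),
            class = c("hap_freq_table", "data.frame"), haplotypes = haps)
}
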