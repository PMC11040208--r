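# End-to-end pipeline: diversity scan -> sweep calls -> locus classification
# -> promoter variants -> haplotype distribution -> phenotype comparison,
# with a combined JSON/Markdown report.

#' Run the full sweep/haplotype analysis
#'
#' Orchestrates the stages on a variant set, population panel and gene model:
#' windowed diversity per group, pi-ratio tracks with empirical top-quantile
#' thresholds and sweep calls per contrast, classification of the focal gene
#' against each call set, promoter variant extraction, tag-SNP haplotype
#' classification and group-wise distribution, and (when phenotypes are
#' supplied) a permutation one-way comparison between the two haplotype
#' classes.  Deterministic given `seed`.
#'
#' @param vcf path to a VCF, or a [variant_table()].
#' @param panel path to a panel TSV, or a [pop_panel()].
#' @param gff3 path to a GFF3 file, or a `gene_models` data.frame.
#' @param pheno optional path to a phenotype TSV, or a phenotype data.frame.
#' @param gene_id focal gene (default: the first gene model).
#' @param window,step scan window and step in bp.
#' @param q quantile level for the sweep threshold (default 0.95).
#' @param contrasts list of `c(numerator, denominator)` group pairs; the
#'   defaults are the domestication (PIM/CER) and improvement (CER/BIG)
#'   contrasts.
#' @param upstream promoter length in bp (default 3000).
#' @param tag optional `list(chrom =, pos =)` tag-SNP site.  When `NULL`, the
#'   unique biallelic promoter SNP whose alleles are exactly the two
#'   `hap_alleles` bases is used.
#' @param hap_alleles named base map for [classify_haplotypes()].
#' @param measure phenotype column to compare (default `"survival_rate"`).
#' @param n_perm permutations for the comparison.
#' @param seed integer seed for the permutation test.
#' @param out_dir optional directory; when given, stage TSVs plus
#'   `report.json` and `report.md` are written there.
#' @return object of class `sweep_report`: list with `scan` (track,
#'   per-contrast thresholds/calls/classification), `promoter` (variants,
#'   assignment, distribution, comparison), and `provenance`.
#' @export
run_pipeline <- function(vcf, panel, gff3, pheno = NULL, gene_id = NULL,
                         window = 1e5, step = 1e4, q = 0.95,
                         contrasts = list(c("PIM", "CER"), c("CER", "BIG")),
                         upstream = 3000, tag = NULL,
                         hap_alleles = c(Hap1 = "G", Hap2 = "A"),
                         measure = "survival_rate", n_perm = 1000,
                         seed = 1, out_dir = NULL) {
  inputs <- list(vcf = vcf, panel = panel, gff3 = gff3, pheno = pheno)
  paths <- Filter(is.character, inputs)
  for (p in paths) if (!file.exists(p)) stop2("input file not found: ", p)

  tab <- if (is.character(vcf)) read_vcf(vcf) else vcf
  pan <- if (is.character(panel)) read_panel(panel) else panel
  genes <- if (is.character(gff3)) read_gene_models(gff3) else gff3
  phen <- if (is.character(pheno)) read_phenotypes(pheno) else pheno
  if (!nrow(genes)) stop2("no gene models available")
  gene <- if (is.null(gene_id)) genes[1, ]
          else genes[genes$gene_id == gene_id, ]
  if (!nrow(gene)) stop2("gene '", gene_id, "' not in gene models")

  sh_log("stage scan: windowed diversity (window ", window, ", step ", step, ")")
  track <- window_pi(tab, pan, chrom = gene$chrom,
                     window = window, step = step)
  scan <- list(track = track, contrasts = list())
  for (ct in contrasts) {
    lab <- paste0(ct[1], "/", ct[2])
    rt <- pi_ratio(track, ct[1], ct[2])
    thr <- empirical_threshold(rt, q)
    calls <- call_sweeps(rt, thr)
    scan$contrasts[[lab]] <- list(
      ratio = rt, threshold = thr, q = q, calls = calls,
      classification = locate_locus(calls, gene))
  }

  sh_log("stage haplotype: promoter variants and tag-SNP classes")
  pv <- extract_promoter_variants(tab, gene, upstream)
  if (is.null(tag)) {
    cand <- which(pv$vtype == "SNP" &
                    vapply(seq_len(nrow(pv)), function(i) {
                      al <- sort(c(pv$ref[i], strsplit(pv$alt[i], ",")[[1]]))
                      identical(al, sort(unname(hap_alleles)))
                    }, logical(1)))
    if (length(cand) != 1)
      stop2("tag SNP not given and ", length(cand),
            " promoter SNPs match the haplotype alleles; pass `tag`")
    tag <- list(chrom = pv$chrom[cand], pos = pv$pos[cand])
  }
  assignment <- classify_haplotypes(tab, tag$chrom, tag$pos, hap_alleles)
  distribution <- haplotype_distribution(assignment, pan)
  comparison <- NULL
  if (!is.null(phen)) {
    grouping <- setNames(assignment$haplotype, assignment$accession)
    grouping <- grouping[grouping %in% names(hap_alleles)]
    comparison <- compare_groups(phen, grouping, measure = measure,
                                 n_perm = n_perm, seed = seed)
  }

  prov <- list(package = "sweephap",
               version = as.character(utils::packageVersion("sweephap")),
               seed = seed, window = window, step = step, q = q,
               upstream = upstream, tag = tag,
               hap_alleles = as.list(hap_alleles),
               inputs = if (length(paths))
                 as.list(tools::md5sum(unlist(paths))) else list())
  report <- structure(list(gene = gene, scan = scan,
                           promoter = list(variants = pv,
                                           assignment = assignment,
                                           distribution = distribution,
                                           comparison = comparison),
                           provenance = prov),
                      class = "sweep_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

report_json_payload <- function(x) {
  contrasts <- lapply(x$scan$contrasts, function(ct)
    list(threshold = ct$threshold, q = ct$q,
         classification = ct$classification,
         intervals = as.data.frame(ct$calls)))
  cmp <- x$promoter$comparison
  list(gene = as.list(x$gene),
       contrasts = contrasts,
       promoter_variants = as.data.frame(x$promoter$variants),
       haplotype_distribution = as.data.frame(x$promoter$distribution),
       comparison = if (is.null(cmp)) NULL else
         list(F = cmp$statistic, p = cmp$p.value, df = cmp$df,
              n_perm = cmp$n_perm, groups = cmp$table),
       provenance = x$provenance)
}

#' Write a pipeline report to disk
#'
#' Emits the per-window diversity TSV, per-contrast ratio TSVs, sweep-call
#' BED files (0-based half-open), the promoter and haplotype tables, and a
#' combined `report.json` + `report.md`.
#'
#' @param x a `sweep_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_result_tsv(x$scan$track, file.path(dir, "diversity_windows.tsv"))
  for (lab in names(x$scan$contrasts)) {
    ct <- x$scan$contrasts[[lab]]
    slug <- gsub("/", "_", lab)
    write_result_tsv(ct$ratio, file.path(dir, paste0("ratio_", slug, ".tsv")))
    bed <- as.data.frame(ct$calls)
    if (nrow(bed))
      write.table(bed[, c("chrom", "start", "end")],
                  file.path(dir, paste0("sweeps_", slug, ".bed")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    else file.create(file.path(dir, paste0("sweeps_", slug, ".bed")))
  }
  write_result_tsv(x$promoter$variants, file.path(dir, "promoter_variants.tsv"))
  write_result_tsv(x$promoter$assignment, file.path(dir, "haplotypes.tsv"))
  write_result_tsv(x$promoter$distribution,
                   file.path(dir, "haplotype_distribution.tsv"))
  write_result_json(report_json_payload(x), file.path(dir, "report.json"))

  md <- c(sprintf("# Sweep/haplotype report: %s", x$gene$gene_id), "")
  for (lab in names(x$scan$contrasts)) {
    ct <- x$scan$contrasts[[lab]]
    md <- c(md, sprintf("- contrast **%s**: top-%d%% threshold %.4g, %d sweep interval(s); locus **%s**",
                        lab, round(100 * (1 - ct$q)), ct$threshold,
                        nrow(ct$calls), ct$classification))
  }
  dist <- x$promoter$distribution
  md <- c(md, "", "## Haplotype distribution", "",
          paste(capture_md_table(as.data.frame(dist)), collapse = "\n"))
  cmp <- x$promoter$comparison
  if (!is.null(cmp))
    md <- c(md, "", sprintf(
      "Haplotype phenotype comparison: F(%d, %d) = %.4g, permutation p = %.4g.",
      cmp$df[1], cmp$df[2], cmp$statistic, cmp$p.value))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

capture_md_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("sweep_report for gene '%s' (%s:%d-%d)\n", x$gene$gene_id,
              x$gene$chrom, x$gene$start, x$gene$end))
  for (lab in names(x$scan$contrasts)) {
    ct <- x$scan$contrasts[[lab]]
    cat(sprintf("  %s: threshold %.4g, %d interval(s), locus %s\n",
                lab, ct$threshold, nrow(ct$calls), ct$classification))
  }
  cat(sprintf("  promoter variants: %d; haplotype classes: %s\n",
              nrow(x$promoter$variants),
              paste(names(attr(x$promoter$assignment, "alleles")),
                    collapse = "/")))
  if (!is.null(x$promoter$comparison))
    cat(sprintf("  phenotype comparison: F = %.4g, p = %.4g\n",
                x$promoter$comparison$statistic,
                x$promoter$comparison$p.value))
  invisible(x)
}
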