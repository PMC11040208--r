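# Synthetic cohort generator: three serially bottlenecked populations with
# declining diversity, an injected improvement sweep, a promoter tag SNP with
# a declining wild-allele frequency, and an associated phenotype.  Forward
# binomial (Wright-Fisher) drift on independent sites -- transparent and
# dependency-free; no recombination model is needed to create the rank
# structure the scan must detect.

#' Simulation configuration
#'
#' Defaults define the stated world of the generator: a 2-Mb chromosome with
#' 4000 segregating sites; panel sizes 20/40/60 (wild PIM, domesticated CER,
#' improved BIG); two serial bottlenecks (N = 200 for 30 generations into
#' CER, then N = 100 for 30 generations into BIG) giving the PIM > CER > BIG
#' diversity ranking; a 200-kb improvement sweep over [900 kb, 1.1 Mb) where
#' BIG heterozygosity is scaled to `lambda = 0.05`; a tag SNP 1903 bp
#' upstream of a toy gene's ATG inside the sweep, wild base G (ALT, the
#' reference being cultivar-derived) and cultivar base A (REF), with
#' wild-allele frequencies 0.95/0.45/0.10 across PIM/CER/BIG; and a survival
#' phenotype (percent) mu + beta * (wild alleles) + N(0, sigma).
#'
#' @param L chromosome length (bp).
#' @param S number of segregating sites.
#' @param n named integer vector of per-group sample sizes.
#' @param N_cer,g_cer,N_big,g_big bottleneck population sizes and generation
#'   counts for the two transitions.
#' @param sweep_start,sweep_end sweep interval, 0-based half-open.
#' @param lambda in-sweep heterozygosity retention factor in `[0, 1]`.
#' @param chrom chromosome id used in all emitted files.
#' @param tag_pos 1-based tag-SNP position; must sit `1903` bp upstream of
#'   `gene_atg` to reproduce the promoter geometry.
#' @param tag_wild,tag_cult wild (ALT) and cultivar (REF) bases at the tag.
#' @param tag_freq named vector of target wild-allele frequencies per group.
#' @param gene_id,gene_atg,gene_end toy gene model (+ strand, 1-based ATG).
#' @param pheno_mu,pheno_beta,pheno_sigma phenotype model: baseline percent,
#'   additive effect per wild allele, residual sd.
#' @param indel_frac fraction of simulated sites emitted as InDels.
#' @param seed optional integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(L = 2e6, S = 4000,
                       n = c(PIM = 20, CER = 40, BIG = 60),
                       N_cer = 200, g_cer = 30, N_big = 100, g_big = 30,
                       sweep_start = 9e5, sweep_end = 1.1e6, lambda = 0.05,
                       chrom = "chr8",
                       tag_pos = 998097, tag_wild = "G", tag_cult = "A",
                       tag_freq = c(PIM = 0.95, CER = 0.45, BIG = 0.10),
                       gene_id = "ScaBP8like", gene_atg = 1000000,
                       gene_end = 1002500,
                       pheno_mu = 40, pheno_beta = 15, pheno_sigma = 10,
                       indel_frac = 0.02, seed = NULL) {
  cfg <- list(L = L, S = S, n = n, N_cer = N_cer, g_cer = g_cer,
              N_big = N_big, g_big = g_big, sweep_start = sweep_start,
              sweep_end = sweep_end, lambda = lambda, chrom = chrom,
              tag_pos = tag_pos, tag_wild = tag_wild, tag_cult = tag_cult,
              tag_freq = tag_freq, gene_id = gene_id, gene_atg = gene_atg,
              gene_end = gene_end, pheno_mu = pheno_mu,
              pheno_beta = pheno_beta, pheno_sigma = pheno_sigma,
              indel_frac = indel_frac, seed = seed)
  stopifnot(lambda >= 0, lambda <= 1,
            sweep_start >= 0, sweep_end <= L, sweep_end > sweep_start,
            all(tag_freq >= 0), all(tag_freq <= 1), all(n >= 1),
            S >= 1, names(n) %in% names(tag_freq))
  if (S > L) stop2("more segregating sites than base pairs (S > L)")
  structure(cfg, class = "sim_config")
}

#' Draw ancestral segregating sites and frequencies
#'
#' Positions are uniform without replacement on `[0, L)`; derived-allele
#' frequencies follow the neutral site-frequency spectrum,
#' `P(count = i) proportional to 1/i` over `i = 1..2n-1` copies among the
#' `2n` wild haplotypes.
#'
#' @param config a [sim_config()].
#' @return list with `pos0` (sorted 0-based positions) and `freq`.
#' @export
simulate_base_population <- function(config) {
  if (config$S > config$L) stop2("S > L")
  two_n <- 2 * config$n[["PIM"]]
  pos0 <- sort(sample.int(config$L, config$S) - 1L)
  i <- sample.int(two_n - 1, config$S, replace = TRUE,
                  prob = 1 / seq_len(two_n - 1))
  list(pos0 = pos0, freq = i / two_n)
}

#' Wright-Fisher binomial drift
#'
#' `g` rounds of binomial resampling of each allele frequency in a
#' population of `N` diploids: `p' = Binomial(2N, p) / 2N`.  Fixation and
#' loss are absorbing; `g = 0` is the identity.
#'
#' @param freq vector of allele frequencies.
#' @param N diploid population size (>= 1).
#' @param g number of generations (>= 0).
#' @return drifted frequency vector.
#' @export
apply_bottleneck <- function(freq, N, g) {
  stopifnot(N >= 1, g >= 0)
  for (r in seq_len(g)) freq <- rbinom(length(freq), 2 * N, freq) / (2 * N)
  freq
}

#' Inject a diversity-reduction sweep
#'
#' For sites inside `[a, b)` the heterozygosity is scaled by `lambda`:
#' `2 p'(1-p') = lambda * 2 p(1-p)`, with `p'` moved toward its nearer
#' boundary (ties at `p = 0.5` move toward 0, for determinism).  Sites
#' outside the interval are untouched.
#'
#' @param freq vector of allele frequencies.
#' @param pos0 parallel vector of 0-based site positions.
#' @param a,b sweep interval, 0-based half-open.
#' @param lambda heterozygosity retention factor in `[0, 1]`.
#' @return modified frequency vector.
#' @export
inject_sweep <- function(freq, pos0, a, b, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  inside <- pos0 >= a & pos0 < b
  p <- freq[inside]
  hp <- lambda * 2 * p * (1 - p)
  disc <- sqrt(pmax(0, 1 - 2 * hp))
  freq[inside] <- ifelse(p <= 0.5, (1 - disc) / 2, (1 + disc) / 2)
  freq
}

draw_genotypes <- function(freq, n) {
  S <- length(freq)
  a1 <- matrix(as.integer(matrix(runif(S * n), S, n) < freq), S, n)
  a2 <- matrix(as.integer(matrix(runif(S * n), S, n) < freq), S, n)
  list(a1 = a1, a2 = a2)
}

#' Simulate a full cohort in memory
#'
#' Runs the generator end to end: ancestral PIM frequencies, two serial
#' bottlenecks, the BIG-restricted sweep, tag-SNP insertion, diploid
#' genotype sampling, phenotype draw, and the matching toy gene model --
#' returning the same objects the file fixture would parse to.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (overrides `config$seed`).
#' @return list of class `sim_cohort`: `table` ([variant_table()]), `panel`,
#'   `genes`, `pheno`, `truth` (realized per-group allele frequencies, sweep
#'   interval, per-accession haplotype and phenotype mean), `config`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = NULL) {
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(seed)
  groups <- names(config$n)

  base <- simulate_base_population(config)
  pos0 <- base$pos0
  # tag position is reserved: a colliding simulated site is resampled
  tag0 <- config$tag_pos - 1L
  while (any(pos0 == tag0)) {
    sh_log("simulated site collides with tag position; resampled")
    free <- integer(0)
    while (!length(free))
      free <- setdiff(sample.int(config$L, 20) - 1L, c(pos0, tag0))
    pos0[pos0 == tag0] <- free[1]
    o <- order(pos0); pos0 <- sort(pos0)
    base$freq <- base$freq[o]
  }
  fr <- list(PIM = base$freq)
  fr$CER <- apply_bottleneck(fr$PIM, config$N_cer, config$g_cer)
  fr$BIG <- inject_sweep(apply_bottleneck(fr$CER, config$N_big, config$g_big),
                         pos0, config$sweep_start, config$sweep_end,
                         config$lambda)

  # insert the tag SNP at its sorted position with configured frequencies
  ins <- findInterval(tag0, pos0)
  pos0 <- append(pos0, tag0, after = ins)
  for (g in groups) fr[[g]] <- append(fr[[g]], config$tag_freq[[g]], after = ins)
  S <- length(pos0)
  tag_row <- ins + 1L

  # alleles: REF/ALT bases; a configurable fraction of sites are InDels
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, S, replace = TRUE)
  alt_base <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  is_indel <- runif(S) < config$indel_frac
  ref_out <- ref
  alt_out <- alt_base
  ext <- vapply(seq_len(S), function(i)
    paste(sample(bases, 1 + (i %% 3), replace = TRUE), collapse = ""), "")
  del <- runif(S) < 0.5
  ref_out[is_indel & del] <- paste0(ref[is_indel & del], ext[is_indel & del])
  alt_out[is_indel & del] <- ref[is_indel & del]
  alt_out[is_indel & !del] <- paste0(ref[is_indel & !del], ext[is_indel & !del])
  ref_out[tag_row] <- config$tag_cult      # cultivar-derived reference
  alt_out[tag_row] <- config$tag_wild      # wild allele is the ALT
  is_indel[tag_row] <- FALSE

  gt <- lapply(groups, function(g) draw_genotypes(fr[[g]], config$n[[g]]))
  a1 <- do.call(cbind, lapply(gt, `[[`, "a1"))
  a2 <- do.call(cbind, lapply(gt, `[[`, "a2"))
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_%03d", g, seq_len(config$n[[g]]))))
  colnames(a1) <- colnames(a2) <- samples

  tab <- variant_table(rep(config$chrom, S), pos0 + 1L, ref_out,
                       as.list(alt_out), a1, a2, samples,
                       contig_lengths = setNames(as.integer(config$L),
                                                 config$chrom))
  panel <- pop_panel(samples, rep(groups, config$n[groups]))
  genes <- structure(
    data.frame(gene_id = config$gene_id, chrom = config$chrom, strand = "+",
               start = config$gene_atg, end = config$gene_end,
               atg_pos = config$gene_atg, stringsAsFactors = FALSE),
    class = c("gene_models", "data.frame"))

  w <- a1[tag_row, ] + a2[tag_row, ]       # wild-allele dosage (ALT copies)
  pheno_mean <- config$pheno_mu + config$pheno_beta * w
  survival <- pmin(100, pmax(0, pheno_mean + rnorm(length(w), 0,
                                                   config$pheno_sigma)))
  pheno <- data.frame(accession = samples,
                      survival_rate = as.numeric(survival),
                      stringsAsFactors = FALSE)

  # realized (sample) ALT-allele frequencies, recomputable from the VCF
  realized <- lapply(groups, function(g) {
    idx <- which(panel$group == g)
    rowMeans((a1[, idx, drop = FALSE] + a2[, idx, drop = FALSE]) / 2)
  })
  names(realized) <- groups
  hap <- ifelse(w == 2, "Hap1", ifelse(w == 0, "Hap2", "Het"))
  truth <- list(pos = pos0 + 1L, freq = realized,
                sweep = list(chrom = config$chrom,
                             start = config$sweep_start,
                             end = config$sweep_end),
                tag = list(chrom = config$chrom, pos = config$tag_pos,
                           wild = config$tag_wild, cult = config$tag_cult),
                haplotype = setNames(hap, samples),
                pheno_mean = setNames(pheno_mean, samples))
  structure(list(table = tab, panel = panel, genes = genes, pheno = pheno,
                 truth = truth, config = config, seed = seed),
            class = "sim_cohort")
}

#' Emit a synthetic fixture as files
#'
#' Serialises a [simulate_cohort()] draw into the standard formats: a VCF, a
#' panel TSV, a GFF3 gene model, a phenotype TSV, a small synthetic aligned
#' protein FASTA, and a truth JSON.  Byte-identical for a fixed seed.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @param seed optional integer seed (overrides `config$seed`).
#' @return named character vector of the six file paths; the cohort is
#'   attached as attribute `cohort`.
#' @export
emit_fixture <- function(config = sim_config(), dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config, seed = seed)
  paths <- c(vcf = file.path(dir, "cohort.vcf"),
             panel = file.path(dir, "panel.tsv"),
             gff3 = file.path(dir, "genes.gff3"),
             pheno = file.path(dir, "phenotypes.tsv"),
             aln = file.path(dir, "scabp_like_synthetic.faa"),
             truth = file.path(dir, "truth.json"))
  write_vcf(cohort$table, paths[["vcf"]])
  write.table(cohort$panel, paths[["panel"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_gff3(cohort$genes, paths[["gff3"]])
  write.table(cohort$pheno, paths[["pheno"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  aln <- simulate_alignment(n_taxa = 12, n_sites = 120)
  writeLines(paste0(">", names(aln), "\n", aln), paths[["aln"]])
  write_result_json(cohort$truth, paths[["truth"]])
  structure(paths, cohort = cohort)
}

#' Simulate a small aligned protein family
#'
#' Evolves a random root sequence along a random tree (one substitution
#' process, probability `1 - exp(-rate * branch)` per site per branch) and
#' returns the aligned tips -- a stand-in for a calcineurin-B-like protein
#' family alignment, synthetic by construction.
#'
#' @param n_taxa number of sequences.
#' @param n_sites alignment length.
#' @param rate substitution rate per unit branch length.
#' @param gap_block if `TRUE`, a short gap block is written into a third of
#'   the taxa to exercise pairwise deletion.
#' @param seed optional integer seed.
#' @return named character vector of aligned sequences.
#' @export
simulate_alignment <- function(n_taxa = 12, n_sites = 120, rate = 0.4,
                               gap_block = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tree <- ape::rtree(n_taxa, br = function(n) runif(n, 0.05, 0.5))
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[ntip + 1L]] <- sample(aa, n_sites, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    s <- seqs[[par]]
    mut <- runif(n_sites) < 1 - exp(-rate * tree$edge.length[e])
    if (any(mut)) s[mut] <- vapply(s[mut], function(x)
      sample(setdiff(aa, x), 1), "")
    seqs[[child]] <- s
  }
  out <- vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), "")
  names(out) <- tree$tip.label
  if (gap_block && n_sites >= 20) {
    gi <- seq_len(max(1, n_taxa %/% 3))
    blk <- (n_sites %/% 2):(n_sites %/% 2 + 4)
    for (i in gi) {
      s <- strsplit(out[i], "")[[1]]
      s[blk] <- "-"
      out[i] <- paste(s, collapse = "")
    }
  }
  out
}
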