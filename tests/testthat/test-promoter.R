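test_that("promoter_window does strand-aware coordinate arithmetic", {
  gp <- gene_row(strand = "+", start = 10001, end = 11000, atg = 10001)
  expect_equal(promoter_window(gp)[c("start", "end")],
               list(start = 7000, end = 10000))
  gm <- gene_row(strand = "-", start = 9000, end = 10000, atg = 10000)
  expect_equal(promoter_window(gm)[c("start", "end")],
               list(start = 10000, end = 13000))
  gclip <- gene_row(strand = "+", start = 2001, end = 3000, atg = 2001)
  expect_equal(promoter_window(gclip)[c("start", "end")],
               list(start = 0, end = 2000))
  gm2 <- gene_row(strand = "-", start = 9000, end = 10000, atg = 10000)
  expect_equal(promoter_window(gm2, chrom_length = 11000)$end, 11000)
})

test_that("promoter variants carry rel_pos and labels, mirrored across strands", {
  for (strand in c("+", "-")) {
    fx <- promoter_fixture(strand)
    pv <- extract_promoter_variants(fx$tab, fx$gene)
    expect_equal(nrow(pv), 9)                      # 8 SNPs + 1 InDel in-window
    expect_equal(sum(pv$vtype == "SNP"), 8)
    expect_equal(sum(pv$vtype == "InDel"), 1)
    expect_true(all(pv$rel_pos < 0 & pv$rel_pos >= -3000))
    # the tag SNP sits 1903 bp upstream of the ATG on either strand
    expect_equal(pv$rel_pos[pv$label == "SNP4"], -1903)
    # labels run most-upstream -> closest-to-ATG
    expect_equal(pv$rel_pos[pv$vtype == "SNP"],
                 sort(pv$rel_pos[pv$vtype == "SNP"]))
    expect_equal(pv$label[pv$vtype == "SNP"], paste0("SNP", 1:8))
  }
  # rel_pos and labels identical between the mirrored fixtures
  pvp <- extract_promoter_variants(promoter_fixture("+")$tab,
                                   promoter_fixture("+")$gene)
  pvm <- extract_promoter_variants(promoter_fixture("-")$tab,
                                   promoter_fixture("-")$gene)
  expect_equal(pvp$rel_pos, pvm$rel_pos)
  expect_equal(pvp$label, pvm$label)
})

test_that("a variant at the ATG first base is excluded (half-open edge)", {
  fx <- promoter_fixture("+")
  pv <- extract_promoter_variants(fx$tab, fx$gene)
  expect_false(fx$gene$atg_pos %in% pv$pos)
  expect_false(any(pv$rel_pos == 0))
})

test_that("classify_haplotypes keys on bases, not REF/ALT index", {
  # cultivar-derived reference: REF = A (Hap2 base), ALT = G (Hap1 base)
  tab <- variant_table("chr8", 8098, "A", list("G"),
                       matrix(c(1L, 0L, 0L, NA), 1),
                       matrix(c(1L, 0L, 1L, NA), 1),
                       c("w", "c", "h", "m"))
  asg <- classify_haplotypes(tab, "chr8", 8098, c(Hap1 = "G", Hap2 = "A"))
  expect_equal(asg$haplotype, c("Hap1", "Hap2", "Het", "Missing"))
  expect_equal(asg$genotype, c("G/G", "A/A", "A/G", "./."))
  expect_error(classify_haplotypes(tab, "chr8", 9999), "absent")
  expect_error(classify_haplotypes(tab, "chr8", 8098, c(Hap1 = "T", Hap2 = "A")),
               "not among")
})

test_that("haplotype_distribution tallies per group and conserves counts", {
  n <- 14
  hap <- c(rep("Hap1", 8), rep("Hap2", 2), rep("Hap1", 2), rep("Het", 1),
           "Missing")
  tab <- variant_table("chr8", 100, "A", list("G"),
                       matrix(ifelse(hap == "Hap1", 1L,
                                     ifelse(hap == "Missing", NA, 0L)), 1),
                       matrix(ifelse(hap == "Hap1", 1L,
                                     ifelse(hap == "Hap2", 0L,
                                            ifelse(hap == "Missing", NA, 1L))), 1),
                       sprintf("a%02d", 1:n))
  asg <- classify_haplotypes(tab, "chr8", 100)
  expect_equal(asg$haplotype, hap)
  panel <- pop_panel(sprintf("a%02d", 1:n),
                     c(rep("PIM", 10), rep("CER", 4)))
  dist <- haplotype_distribution(asg, panel)
  pim <- dist[dist$group == "PIM", ]
  expect_equal(c(pim$Hap1, pim$Hap2), c(8L, 2L))
  expect_equal(c(pim$frac_Hap1, pim$frac_Hap2), c(0.8, 0.2))
  # conservation: group x class counts sum to the classified accessions
  expect_equal(sum(dist$Hap1 + dist$Hap2 + dist$Het + dist$Missing), n)
  # a group with no classified accessions yields a zero row plus warning
  panel2 <- pop_panel(c(sprintf("a%02d", 1:n), "zz"),
                      c(rep("PIM", 10), rep("CER", 4), "BIG"))
  expect_warning(dist2 <- haplotype_distribution(asg, panel2), "BIG")
  expect_equal(dist2$n[dist2$group == "BIG"], 0L)
  expect_error(haplotype_distribution(asg, pop_panel("other", "PIM")),
               "no accessions")
})

test_that("compare_groups reproduces the closed-form F decomposition", {
  cmp <- compare_groups(c(1, 2, 3, 4, 5, 6),
                        c("A", "A", "A", "B", "B", "B"),
                        n_perm = 100, seed = 1)
  expect_equal(cmp$statistic, 13.5)      # SSB 13.5, MSW 1
  same <- compare_groups(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3),
                         n_perm = 50, seed = 1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1.0)
  # cross-check against the standard linear-model ANOVA on random instances
  set.seed(99)
  for (r in 1:5) {
    y <- rnorm(18)
    g <- sample(rep(c("x", "y", "z"), 6))
    cmp <- compare_groups(y, g, n_perm = 10, seed = 1)
    expect_equal(cmp$statistic,
                 anova(lm(y ~ factor(g)))$`F value`[1], tolerance = 1e-10)
  }
})

test_that("permutation p matches exhaustive enumeration for a small instance", {
  y <- c(1, 2, 3, 4, 5, 6)
  g <- c("A", "A", "A", "B", "B", "B")
  f_of <- function(lab) {
    m <- tapply(y, lab, mean); n <- tapply(y, lab, length)
    ssb <- sum(n * (m - mean(y))^2)
    ssw <- sum((y - m[lab])^2)
    (ssb / 1) / (ssw / 4)
  }
  f_obs <- f_of(g)
  splits <- combn(6, 3)
  fs <- apply(splits, 2, function(i) {
    lab <- rep("B", 6); lab[i] <- "A"; f_of(lab)
  })
  exact <- mean(fs >= f_obs - 1e-12)
  cmp <- compare_groups(y, g, n_perm = 4000, seed = 42)
  expect_lt(abs(cmp$p.value - exact), 0.02)
})

test_that("compare_groups validates its inputs", {
  expect_error(compare_groups(1:4, rep("A", 4)), "2 groups")
  expect_error(compare_groups(1:3, c("A", "A", "B")), "2 observations")
  expect_error(compare_groups(c(1, 1, 2, 2), c("A", "A", "B", "B"),
                              n_perm = 10),
               "within-group variance")
  ph <- data.frame(accession = c("a", "b", "c", "d"),
                   survival_rate = c(10, 20, 70, 80))
  cmp <- compare_groups(ph, c(a = "Hap2", b = "Hap2", c = "Hap1", d = "Hap1"),
                        measure = "survival_rate", n_perm = 100, seed = 2)
  expect_equal(cmp$table$n, c(2L, 2L))
  expect_error(compare_groups(ph, c(a = "x"), measure = "nope"), "measure")
})
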