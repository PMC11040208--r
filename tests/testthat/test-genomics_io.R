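test_that("read_vcf recovers records, alleles and genotypes in header order", {
  f <- withr::local_tempfile(fileext = ".vcf")
  toy_vcf(f, c(vrow(100, "A", "G", c("0/0", "0/1")),
               vrow(200, "C", "T,G", c("0/2", "./.")),
               vrow(300, "AT", "A", c("1|1", "0/1"))))
  tab <- read_vcf(f)
  expect_equal(n_variants(tab), 3)
  expect_equal(tab$samples, c("S1", "S2"))
  expect_equal(tab$pos, c(100L, 200L, 300L))
  expect_equal(tab$ref, c("A", "C", "AT"))
  expect_equal(tab$alt[[2]], c("T", "G"))
  expect_equal(tab$vtype, c("SNP", "SNP", "InDel"))
  expect_equal(tab$a1[, "S1"], c(0L, 0L, 1L))   # phase ignored
  expect_equal(tab$a2[, "S1"], c(0L, 2L, 1L))
  expect_true(is.na(tab$a1[2, "S2"]) && is.na(tab$a2[2, "S2"]))
  expect_equal(tab$contig_lengths[["chr8"]], 100000)
})

test_that("region queries are 1-based inclusive and consistent under union", {
  f <- withr::local_tempfile(fileext = ".vcf")
  toy_vcf(f, c(vrow(100, gts = c("0/0", "0/1")),
               vrow(200, gts = c("0/1", "0/1")),
               vrow(300, gts = c("1/1", "0/0"))))
  expect_equal(read_vcf(f, "chr8:150-250")$pos, 200L)
  expect_warning(empty <- read_vcf(f, "chr9:1-100"), "chr9")
  expect_equal(n_variants(empty), 0)
  whole <- read_vcf(f)
  parts <- c(read_vcf(f, "chr8:1-150")$pos, read_vcf(f, "chr8:151-100000")$pos)
  expect_equal(sort(parts), whole$pos)
})

test_that("SV and GT-less records are skipped with logged counts", {
  f <- withr::local_tempfile(fileext = ".vcf")
  toy_vcf(f, c(vrow(100, gts = c("0/0", "0/1")),
               vrow(150, "N", "<DEL>", c("0/1", "0/0"), info = "SVTYPE=DEL"),
               vrow(250, gts = c("0/1", "1/1"))),
          extra_header = c(
            "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
            "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">"))
  # append a record carrying only DP (no GT)
  con <- file(f, "a"); writeLines(paste(c("chr8", 400, ".", "A", "C", ".",
    "PASS", ".", "DP", "5", "7"), collapse = "\t"), con); close(con)
  tab <- read_vcf(f)
  expect_equal(n_variants(tab), 2)
  expect_equal(attr(tab, "n_sv_skipped"), 1L)
  expect_equal(attr(tab, "n_nogt_skipped"), 1L)
})

test_that("read_panel validates shape, duplicates and emptiness", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a1\tPIM", "a2\tPIM", "a3\tCER", "a4\tCER", "a5\tBIG", "a6\tBIG"), f)
  p <- read_panel(f)
  expect_s3_class(p, "pop_panel")
  expect_equal(unname(table(p$group)[c("PIM", "CER", "BIG")]),
               rep(2L, 3), ignore_attr = TRUE)

  writeLines(c("accession\tgroup", "a1\tPIM", "a2\tCER"), f)
  expect_equal(nrow(read_panel(f)), 2)  # header detected and dropped

  writeLines(c("a1\tPIM", "a1\tCER"), f)
  expect_error(read_panel(f), "duplicated")
  writeLines(character(0), f)
  expect_error(read_panel(f), "no assignments")
  writeLines(c("a1\tPIM", "a2\tXXX"), f)
  expect_error(read_panel(f, groups = c("PIM", "CER", "BIG")), "XXX")
})

test_that("gene models anchor the ATG on the strand-appropriate CDS edge", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
    "chr8\tx\tgene\t9000\t12000\t.\t+\t.\tID=gp",
    "chr8\tx\tmRNA\t9000\t12000\t.\t+\t.\tID=gp.1;Parent=gp",
    "chr8\tx\tCDS\t10000\t10500\t.\t+\t0\tID=gp.c;Parent=gp.1",
    "chr8\tx\tCDS\t11000\t11500\t.\t+\t0\tID=gp.c;Parent=gp.1",
    "chr8\tx\tgene\t8000\t10500\t.\t-\t.\tID=gm",
    "chr8\tx\tmRNA\t8000\t10500\t.\t-\t.\tID=gm.1;Parent=gm",
    "chr8\tx\tCDS\t9000\t10000\t.\t-\t0\tID=gm.c;Parent=gm.1",
    "chr8\tx\tgene\t30000\t31000\t.\t+\t.\tID=gnone"), f)
  expect_warning(gm <- read_gene_models(f), "gnone")
  expect_equal(nrow(gm), 2)
  expect_equal(gm$atg_pos[gm$gene_id == "gp"], 10000L)  # + strand: min CDS start
  expect_equal(gm$atg_pos[gm$gene_id == "gm"], 10000L)  # - strand: max CDS end
})

test_that("result TSVs use documented column names and round-trip", {
  co <- simulate_cohort(sim_config(L = 1e5, S = 200, sweep_start = 4e4,
                                   sweep_end = 6e4, tag_pos = 48097,
                                   gene_atg = 50000, gene_end = 52000),
                        seed = 11)
  track <- window_pi(co$table, co$panel, window = 2e4, step = 1e4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_result_tsv(track, f)
  back <- read_result_tsv(f)
  expect_true(all(c("chrom", "win_start", "win_end", "pi_PIM", "pi_CER",
                    "pi_BIG") %in% names(back)))
  expect_equal(back$pi_PIM, signif(track$pi_PIM, 6))

  asg <- classify_haplotypes(co$table, "chr8", 48097)
  write_result_tsv(asg, f)
  expect_equal(names(read_result_tsv(f)), c("accession", "genotype", "haplotype"))
})

test_that("VCF written by the simulator round-trips exactly", {
  dir <- withr::local_tempdir()
  paths <- emit_fixture(sim_config(L = 5e4, S = 120, sweep_start = 2e4,
                                   sweep_end = 3e4, tag_pos = 23097,
                                   gene_atg = 25000, gene_end = 26000,
                                   n = c(PIM = 4, CER = 4, BIG = 4)),
                        dir, seed = 5)
  co <- attr(paths, "cohort")
  tab <- read_vcf(paths[["vcf"]])
  expect_equal(tab$pos, co$table$pos)
  expect_equal(tab$ref, co$table$ref)
  expect_equal(tab$alt, co$table$alt)
  expect_equal(unname(tab$a1), unname(co$table$a1))
  expect_equal(unname(tab$a2), unname(co$table$a2))
  expect_equal(tab$samples, co$table$samples)
})
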