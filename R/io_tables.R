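# Panel / phenotype / gene-model readers and result writers.

#' Read a population panel (accession -> group) TSV
#'
#' Two tab-separated columns, accession and group label; a header line is
#' detected by the usual column names (`accession`, `sample`, `id`, `group`).
#'
#' @param path path to the TSV.
#' @param groups optional character vector of allowed group labels; labels
#'   outside this set raise an error.
#' @return data.frame with columns `accession`, `group`
#'   (class `pop_panel`).
#' @export
read_panel <- function(path, groups = NULL) {
  if (!file.exists(path)) stop2("panel file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) stop2("no assignments in panel file: ", path)
  first <- tolower(strsplit(raw[1], "\t", fixed = TRUE)[[1]])
  has_header <- any(first %in% c("accession", "sample", "id", "group"))
  df <- read.table(text = raw, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop2("panel must have two tab-separated columns")
  df <- df[, 1:2]
  names(df) <- c("accession", "group")
  pop_panel(df$accession, df$group, groups = groups)
}

#' Construct a population panel
#'
#' @param accession character vector of accession ids.
#' @param group parallel character vector of group labels (e.g. PIM/CER/BIG).
#' @param groups optional allowed label set.
#' @return data.frame of class `pop_panel`.
#' @export
pop_panel <- function(accession, group, groups = NULL) {
  stopifnot(length(accession) == length(group))
  if (!length(accession)) stop2("no assignments")
  if (anyDuplicated(accession))
    stop2("duplicated accession(s) in panel: ",
          paste(unique(accession[duplicated(accession)]), collapse = ", "))
  if (!is.null(groups) && !all(group %in% groups))
    stop2("unknown group label(s): ",
          paste(setdiff(unique(group), groups), collapse = ", "))
  structure(data.frame(accession = as.character(accession),
                       group = as.character(group),
                       stringsAsFactors = FALSE),
            class = c("pop_panel", "data.frame"))
}

#' Read a phenotype table
#'
#' First column is the accession id; remaining columns are numeric
#' measurements (e.g. `survival_rate` in percent, `chlorophyll`).
#'
#' @param path path to a TSV with a header line.
#' @return data.frame with `accession` plus numeric measurement columns.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(df)[1] <- "accession"
  df$accession <- as.character(df$accession)
  if (anyDuplicated(df$accession)) stop2("duplicated accession in phenotype table")
  for (j in seq_along(df)[-1]) df[[j]] <- as.numeric(df[[j]])
  if ("survival_rate" %in% names(df)) {
    s <- df$survival_rate
    if (any(!is.na(s) & (s < 0 | s > 100)))
      warn2("survival_rate outside [0, 100]")
  }
  df
}

#' Read gene models from GFF3
#'
#' Extracts, per gene, the genomic position of the first base of the ATG
#' start codon: the minimum CDS start on the + strand, the maximum CDS end on
#' the - strand.  CDS features are matched to their gene through the
#' `Parent` chain (CDS -> mRNA -> gene).  Genes without CDS are skipped with
#' a warning.
#'
#' @param path path to a GFF3 file (1-based inclusive coordinates).
#' @return data.frame of class `gene_models` with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `atg_pos` (all 1-based).
#' @export
read_gene_models <- function(path) {
  g <- rtracklayer::import(path)
  df <- as.data.frame(g)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  df$type <- as.character(df$type)
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else rep(NA, nrow(df))
  parents <- if ("Parent" %in% names(df))
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  else rep(NA_character_, nrow(df))
  genes <- df[df$type == "gene", , drop = FALSE]
  gene_ids <- as.character(genes$ID)
  par_map <- setNames(parents, ids)
  to_gene <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !id %in% gene_ids && !id %in% seen) {
      seen <- c(seen, id)
      id <- if (id %in% names(par_map)) par_map[[id]] else NA_character_
    }
    if (is.na(id) || !id %in% gene_ids) NA_character_ else id
  }
  cds <- df[df$type == "CDS", , drop = FALSE]
  cds_gene <- vapply(if (nrow(cds)) parents[df$type == "CDS"] else character(0),
                     to_gene, character(1))
  out <- lapply(seq_len(nrow(genes)), function(i) {
    gid <- gene_ids[i]
    ci <- which(!is.na(cds_gene) & cds_gene == gid)
    if (!length(ci)) {
      warn2("gene '", gid, "' has no CDS; skipped")
      return(NULL)
    }
    strand <- genes$strand[i]
    atg <- if (strand == "+") min(cds$start[ci]) else max(cds$end[ci])
    data.frame(gene_id = gid, chrom = genes$seqnames[i], strand = strand,
               start = genes$start[i], end = genes$end[i],
               atg_pos = as.integer(atg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), atg_pos = integer(0))
  structure(out, class = c("gene_models", "data.frame"))
}

#' Write gene models as GFF3
#' @param genes a `gene_models` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    cds <- if (g$strand == "+") c(g$atg_pos, g$end) else c(g$start, g$atg_pos)
    lines <- c(lines,
      sprintf("%s\tsweephap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id),
      sprintf("%s\tsweephap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g$chrom, g$start, g$end, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\tsweephap\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.cds;Parent=%s.1",
              g$chrom, cds[1], cds[2], g$strand, g$gene_id, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

# Plain data.frame view of a result object, with the documented column order.
result_table <- function(x) UseMethod("result_table")
#' @export
result_table.default <- function(x) as.data.frame(x)
#' @export
result_table.diversity_track <- function(x) {
  df <- as.data.frame(x)
  names(df)[names(df) == "start"] <- "win_start"
  names(df)[names(df) == "end"] <- "win_end"
  df
}
#' @export
result_table.hap_assignment <- function(x) as.data.frame(x)

#' Write a result table as TSV
#'
#' Deterministic column order; numeric columns rounded to 6 significant
#' digits.
#'
#' @param x a pipeline result (data.frame-like); class-specific column naming
#'   is applied (e.g. `win_start`/`win_end` for diversity tracks).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  df <- result_table(x)
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV written by [write_result_tsv()]
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_result_tsv <- function(path)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)

#' Write a result as JSON
#' @param x any pipeline result (coerced by jsonlite).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}
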