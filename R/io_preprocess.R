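## Readers/writers for the plain-text interchange formats and the
## probe-level pre-processing rules (probe collapse, promoter-CpG filter,
## cohort sample alignment).
##
## Internal coordinate convention: 0-based, half-open [start, end).
## BED input is native; VCF/MAF-dialect positions (1-based) are shifted on
## ingestion. A point feature such as a CpG site has end = start + 1.

#' Read a feature-by-sample numeric matrix from TSV
#'
#' The expected layout is a header row of sample identifiers and a first
#' column of feature (probe/gene/miRNA) identifiers. Cells must be numeric
#' or the literal `NA`; missing values are preserved, never silently
#' replaced by zero.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @export
read_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    stop("malformed header in ", path, ": need an id column plus >= 1 sample")
  }
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in header of ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  missing_marker <- is.na(cells) | cells %in% c("NA", "nan", "NaN", "")
  bad <- which(is.na(num) & !missing_marker, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-numeric cell in ", path, " at row '", ids[bad[1L, 1L]],
         "', column '", samples[bad[1L, 2L]], "': '",
         cells[bad[1L, 1L], bad[1L, 2L]], "'")
  }
  dimnames(num) <- list(ids, samples)
  num
}

#' Write a matrix in the TSV dialect read by [read_matrix()]
#'
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the first (id) column.
#' @export
write_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level values to gene level
#'
#' Probes carrying any missing value, or annotated to no gene or to
#' multiple genes (markers `UNKNOWN`/`AMBIGUOUS`, empty, `NA`, or a probe
#' id occurring more than once in the annotation), are removed first;
#' surviving probes are averaged per gene within each sample.
#'
#' @param mat Probe-level numeric matrix (probes x samples).
#' @param probe_gene Data frame with columns `probe_id`, `gene_id`.
#' @return Gene-level numeric matrix.
#' @export
collapse_probes <- function(mat, probe_gene) {
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(probe_gene)))
  ambiguous <- probe_gene$probe_id[duplicated(probe_gene$probe_id)]
  map <- probe_gene[!probe_gene$probe_id %in% ambiguous, , drop = FALSE]
  bad_annot <- is.na(map$gene_id) | map$gene_id %in% c("", "UNKNOWN", "AMBIGUOUS")
  map <- map[!bad_annot, , drop = FALSE]
  keep <- intersect(rownames(mat)[stats::complete.cases(mat)], map$probe_id)
  if (length(keep) == 0L) {
    stop("no probes survive NA/annotation filtering")
  }
  sub <- mat[keep, , drop = FALSE]
  genes <- map$gene_id[match(keep, map$probe_id)]
  sums <- rowsum(sub, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  sums / counts
}

#' Read a UCSC-style chrom.sizes table
#'
#' @param path Two-column TSV (chrom, size in bp), no header.
#' @return Named integer vector of chromosome sizes.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "numeric"))
  stats::setNames(as.integer(df[[2L]]), df[[1L]])
}

#' Read genomic features from BED
#'
#' BED is 0-based half-open, matching the internal convention. Columns
#' beyond the first six are ignored; missing name/score/strand columns get
#' defaults.
#'
#' @param path BED file path.
#' @param feature_class Optional class label attached to every record
#'   (`gene_tss`, `cpg_site`, `mirna_locus`, ...).
#' @return Data frame with columns chrom, start, end, id, strand,
#'   feature_class.
#' @export
read_bed <- function(path, feature_class = NA_character_) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character")
  out <- data.frame(
    chrom = df[[1L]],
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    id = if (ncol(df) >= 4L) df[[4L]] else paste0("feat", seq_len(nrow(df))),
    strand = if (ncol(df) >= 6L) df[[6L]] else ".",
    feature_class = feature_class,
    stringsAsFactors = FALSE
  )
  if (any(out$start >= out$end)) {
    stop("BED records with start >= end in ", path)
  }
  out
}

#' Write genomic features as BED
#'
#' @param features Data frame as returned by [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(features, path) {
  df <- data.frame(features$chrom, features$start, features$end,
                   features$id, 0L,
                   ifelse(is.na(features$strand), ".", features$strand))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read somatic variants (VCF or MAF-dialect TSV)
#'
#' VCF positions are 1-based and converted to the internal 0-based
#' convention; the carrying sample is taken from a `SAMPLE=` key in INFO.
#' The `maf-tsv` dialect expects header columns chrom, pos (1-based), ref,
#' alt, sample_id.
#'
#' @param path Input file.
#' @param format `"vcf"` or `"maf-tsv"`.
#' @return Data frame with columns chrom, pos (0-based), ref, alt,
#'   sample_id.
#' @export
read_variants <- function(path, format = c("vcf", "maf-tsv")) {
  format <- match.arg(format)
  if (format == "vcf") {
    lines <- readLines(path)
    body <- lines[!startsWith(lines, "#")]
    if (length(body) == 0L) {
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        sample_id = character()))
    }
    fields <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
    info <- fields[, 8L]
    sample_id <- sub(".*SAMPLE=([^;]+).*", "\\1", info)
    sample_id[!grepl("SAMPLE=", info)] <- NA_character_
    out <- data.frame(
      chrom = fields[, 1L],
      pos = as.integer(fields[, 2L]) - 1L,
      ref = fields[, 4L],
      alt = fields[, 5L],
      sample_id = sample_id,
      stringsAsFactors = FALSE
    )
  } else {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    out <- data.frame(
      chrom = df$chrom,
      pos = as.integer(df$pos) - 1L,
      ref = df$ref,
      alt = df$alt,
      sample_id = df$sample_id,
      stringsAsFactors = FALSE
    )
  }
  if (any(out$ref == out$alt)) stop("variant with ref == alt in ", path)
  out
}

#' Write variants as minimal VCF
#'
#' @param variants Data frame with chrom, pos (0-based), ref, alt,
#'   sample_id.
#' @param path Output path.
#' @param chrom_sizes Optional named vector; emitted as contig headers.
#' @export
write_variants_vcf <- function(variants, path, chrom_sizes = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Carrying sample\">")
  if (!is.null(chrom_sizes)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_sizes), as.integer(chrom_sizes)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tSAMPLE=%s",
                  variants$chrom, variants$pos + 1L, variants$ref,
                  variants$alt, variants$sample_id)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample sheet (sample_id, group)
#'
#' @param path TSV with header columns `sample_id` and `group`
#'   (tumor/normal).
#' @return Data frame with those two columns.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stopifnot(all(c("sample_id", "group") %in% colnames(df)))
  bad <- setdiff(unique(df$group), c("tumor", "normal"))
  if (length(bad) > 0L) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df[, c("sample_id", "group")]
}

#' Read a generic interaction / prior / annotation table
#'
#' @param path TSV with a header; returned as-is with character columns.
#' @return Data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", check.names = FALSE)
}

#' Write a data frame as TSV
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

features_to_granges <- function(features, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    missing <- setdiff(unique(features$chrom), names(chrom_sizes))
    if (length(missing) > 0L) {
      stop("chromosome(s) absent from size table: ",
           paste(missing, collapse = ", "))
    }
  }
  GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*"),
    id = features$id
  )
}

#' Keep CpG sites lying in promoter windows around TSSs
#'
#' A promoter is the closed interval `[TSS - half_window, TSS + half_window]`
#' around each transcription start site. A CpG overlapping several
#' promoters is assigned to every one of them (flagged by `n_genes > 1`).
#'
#' @param cpg_features CpG site features (chrom, start, end, id), end =
#'   start + 1 for single-base sites.
#' @param tss_table TSS features (chrom, start, end, id = gene id, strand);
#'   the TSS coordinate is `start`.
#' @param chrom_sizes Named chromosome-size vector (validates chroms).
#' @param half_window Promoter half-width in bp (default 2000).
#' @return Data frame of retained (cpg_id, gene_id, chrom, cpg_pos,
#'   tss_pos, distance) assignments; one row per CpG-promoter pair, plus an
#'   `n_genes` column counting promoters hit by that CpG.
#' @export
filter_promoter_cpgs <- function(cpg_features, tss_table, chrom_sizes,
                                 half_window = 2000L) {
  missing <- setdiff(unique(tss_table$chrom), names(chrom_sizes))
  if (length(missing) > 0L) {
    stop("TSS chromosome(s) absent from size table: ",
         paste(missing, collapse = ", "))
  }
  cpg_gr <- features_to_granges(cpg_features, chrom_sizes)
  promoters <- data.frame(
    chrom = tss_table$chrom,
    start = pmax(0L, tss_table$start - half_window),
    # +1 makes the window closed at TSS + half_window in 0-based half-open
    end = tss_table$start + half_window + 1L,
    id = tss_table$id,
    strand = tss_table$strand,
    stringsAsFactors = FALSE
  )
  prom_gr <- features_to_granges(promoters)
  hits <- GenomicRanges::findOverlaps(cpg_gr, prom_gr, ignore.strand = TRUE)
  qi <- S4Vectors_from(hits)
  si <- S4Vectors_to(hits)
  if (length(qi) == 0L) {
    return(data.frame(cpg_id = character(), gene_id = character(),
                      chrom = character(), cpg_pos = integer(),
                      tss_pos = integer(), distance = integer(),
                      n_genes = integer()))
  }
  out <- data.frame(
    cpg_id = cpg_features$id[qi],
    gene_id = tss_table$id[si],
    chrom = cpg_features$chrom[qi],
    cpg_pos = cpg_features$start[qi],
    tss_pos = tss_table$start[si],
    stringsAsFactors = FALSE
  )
  out$distance <- abs(out$cpg_pos - out$tss_pos)
  tab <- table(out$cpg_id)
  out$n_genes <- as.integer(tab[out$cpg_id])
  out[order(out$cpg_id, out$gene_id), , drop = FALSE]
}

# thin wrappers so a future S4Vectors API change is localized
S4Vectors_from <- function(hits) S4Vectors::queryHits(hits)
S4Vectors_to <- function(hits) S4Vectors::subjectHits(hits)

#' Restrict all omics layers to their common samples
#'
#' Only samples present in every supplied layer and in the sample sheet
#' are retained; group labels are attached and retained counts reported.
#' Somatic-variant calls exist only for tumor samples, so the variant
#' table constrains the tumor group only; normal samples are matched
#' across the three molecular layers.
#'
#' @param expr,meth,mirna Numeric matrices (features x samples).
#' @param variants Variant data frame with a `sample_id` column.
#' @param sample_sheet Data frame (sample_id, group).
#' @return An `OmicsCohort` list: expr, meth, mirna, variants, samples,
#'   group (named character vector).
#' @export
align_cohort <- function(expr, meth, mirna, variants, sample_sheet) {
  common <- Reduce(intersect, list(colnames(expr), colnames(meth),
                                   colnames(mirna),
                                   sample_sheet$sample_id))
  grp <- sample_sheet$group[match(common, sample_sheet$sample_id)]
  common <- common[grp == "normal" |
                     common %in% unique(variants$sample_id)]
  if (length(common) == 0L) stop("no samples common to all datasets")
  common <- sample_sheet$sample_id[sample_sheet$sample_id %in% common]
  group <- stats::setNames(
    sample_sheet$group[match(common, sample_sheet$sample_id)], common)
  n_t <- sum(group == "tumor")
  n_n <- sum(group == "normal")
  if (n_t < 3L || n_n < 3L) {
    stop("need >= 3 samples per group after alignment (tumor = ", n_t,
         ", normal = ", n_n, ")")
  }
  cohort <- list(
    expr = expr[, common, drop = FALSE],
    meth = meth[, common, drop = FALSE],
    mirna = mirna[, common, drop = FALSE],
    variants = variants[variants$sample_id %in% common, , drop = FALSE],
    samples = common,
    group = group
  )
  class(cohort) <- "OmicsCohort"
  message("aligned cohort: ", n_t, " tumor / ", n_n, " normal samples")
  cohort
}

#' @export
print.OmicsCohort <- function(x, ...) {
  cat("OmicsCohort:", length(x$samples), "samples (",
      sum(x$group == "tumor"), "tumor /", sum(x$group == "normal"),
      "normal )\n")
  cat("  expression:", nrow(x$expr), "genes\n")
  cat("  methylation:", nrow(x$meth), "genes\n")
  cat("  miRNA:", nrow(x$mirna), "miRNAs\n")
  cat("  variants:", nrow(x$variants), "records\n")
  invisible(x)
}
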