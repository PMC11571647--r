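#' Construct a genotype matrix object
#'
#' Container for biallelic SNP dosages with per-SNP metadata. Dosages count
#' ALT alleles, so values are 0, 1, 2 or `NA` (missing).
#'
#' @param dosage Numeric sample x SNP matrix with sample row names and SNP
#'   column names; entries in `{0, 1, 2, NA}`.
#' @param snp_info data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt` aligned to the dosage columns; `pos` is 1-based.
#' @return A list of class `"genotype_matrix"`.
#' @export
genotype_matrix <- function(dosage, snp_info) {
  stopifnot(is.matrix(dosage), is.data.frame(snp_info))
  req <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(snp_info)))
    stop("snp_info must have columns ", paste(req, collapse = ", "))
  if (ncol(dosage) != nrow(snp_info))
    stop("dosage columns and snp_info rows disagree")
  if (is.null(colnames(dosage))) colnames(dosage) <- snp_info$snp_id
  if (!identical(colnames(dosage), snp_info$snp_id))
    stop("dosage column names must equal snp_info$snp_id")
  if (anyDuplicated(snp_info$snp_id)) stop("duplicated SNP ids")
  if (any(snp_info$pos < 1)) stop("SNP positions must be >= 1")
  bad <- !(dosage %in% c(0, 1, 2) | is.na(dosage))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  structure(list(dosage = dosage, snp_info = snp_info),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Rejects duplicated ids, ragged rows and negative counts with the
#' offending row or column named.
#'
#' @param path TSV file path.
#' @return Numeric gene x sample matrix with dimnames.
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts TSV needs a gene id column plus samples")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in counts matrix")
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative count at gene ", rownames(m)[neg[1, 1]],
         ", sample ", colnames(m)[neg[1, 2]])
  m
}

#' Write a gene x sample matrix as TSV
#'
#' @param mat Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' @param path CSV with columns `sample_id` and any of `LW`, `DW`, `EW`,
#'   `BMW` (grams; empty cells are missing).
#' @return data.frame with `sample_id` as character.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype CSV needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in phenotype table")
  df
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses GT fields into ALT-allele dosages. Multi-allelic records are
#' skipped with a warning; `./.` (and half-calls) become missing.
#'
#' @param path VCF v4.x path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0L) stop("no variant records in ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage = number of '1' alleles; any missing allele -> NA
  count_alt <- function(g) {
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (any(a == "." | is.na(a)) || !length(a)) return(NA_real_)
      sum(a == "1")
    }, numeric(1))
  }
  dos <- apply(gt, 2L, count_alt)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = 1L,
                                       dimnames = list(NULL, colnames(gt)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  dosage <- t(dos)  # rows were variants after apply; transpose to sample x SNP
  dimnames(dosage) <- list(colnames(gt), ids)
  snp_info <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_matrix(dosage, snp_info)
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' Emits GT-only records (unphased) with 1-based positions and contig
#' headers, in deterministic SNP then sample order.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  si <- geno$snp_info
  dos <- geno$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", unique(si$chrom), ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(dos)), collapse = "\t")),
             con)
  for (j in seq_len(nrow(si))) {
    g <- dos[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(si$chrom[j], si$pos[j], si$snp_id[j], si$ref[j],
                       si$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
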