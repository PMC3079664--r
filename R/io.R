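# In-memory containers and readers/writers for the external file formats.
# Coordinates are 1-based inclusive throughout; chromosome labels are
# normalized by stripping a leading "chr" prefix.

#' Construct a genotype matrix
#'
#' The central data container: an n SNP x l sample matrix of allele dosages
#' coded 0/1/2 (copies of the minor/alternate allele), with \code{NA} marking
#' missing genotypes.
#'
#' @param dosages integer matrix, n SNPs (rows) x l samples (columns); entries
#'   must be 0, 1, 2 or \code{NA}.
#' @param snp_ids character vector of unique SNP identifiers, length n.
#' @param sample_ids character vector of unique sample identifiers, length l.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosages}, \code{snp_ids}, \code{sample_ids}.
#' @export
genotype_matrix <- function(dosages, snp_ids, sample_ids) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(dosages) != length(snp_ids))
    stop("number of rows (", nrow(dosages), ") != number of snp_ids (",
         length(snp_ids), ")")
  if (ncol(dosages) != length(sample_ids))
    stop("number of columns (", ncol(dosages), ") != number of sample_ids (",
         length(sample_ids), ")")
  if (nrow(dosages) < 1L) stop("at least one SNP is required")
  if (ncol(dosages) < 2L) stop("at least two samples are required")
  if (anyDuplicated(snp_ids)) stop("duplicate snp_ids")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA; found invalid entries")
  dimnames(dosages) <- list(snp_ids, sample_ids)
  structure(list(dosages = dosages, snp_ids = snp_ids,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$snp_ids), "SNPs x",
      length(x$sample_ids), "samples,",
      sum(is.na(x$dosages)), "missing entries\n")
  invisible(x)
}

#' Number of SNPs / samples in a genotype matrix
#' @param x a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_snps <- function(x) length(x$snp_ids)

#' @rdname n_snps
#' @export
n_samples <- function(x) length(x$sample_ids)

#' Construct phenotype labels
#'
#' Binary case/control status per sample, with an optional control-cohort
#' label used by the control-group concordance QC filter.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param status integer/logical vector: 1/\code{TRUE} = case,
#'   0/\code{FALSE} = control.
#' @param cohort optional character vector naming a control subgroup for each
#'   control sample; must be \code{NA} for cases.
#' @return A data frame of class \code{phenotype_labels} with columns
#'   \code{sample_id}, \code{status}, \code{cohort}.
#' @export
phenotype_labels <- function(sample_ids, status, cohort = NULL) {
  sample_ids <- as.character(sample_ids)
  status <- as.integer(status)
  if (length(status) != length(sample_ids))
    stop("status and sample_ids lengths differ")
  if (anyDuplicated(sample_ids)) stop("duplicate sample_ids")
  if (!all(status %in% c(0L, 1L))) stop("status must be 0 (control) or 1 (case)")
  if (sum(status == 0L) < 1L || sum(status == 1L) < 1L)
    stop("need at least one case and one control")
  if (is.null(cohort)) {
    cohort <- rep(NA_character_, length(sample_ids))
  } else {
    cohort <- as.character(cohort)
    if (length(cohort) != length(sample_ids))
      stop("cohort and sample_ids lengths differ")
    if (any(!is.na(cohort[status == 1L])))
      stop("cohort labels are only defined for control samples")
  }
  structure(data.frame(sample_id = sample_ids, status = status,
                       cohort = cohort, stringsAsFactors = FALSE),
            class = c("phenotype_labels", "data.frame"))
}

# Normalize chromosome labels to a single convention ("1", "X", ...).
normalize_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

read_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines[nzchar(lines)]
}

#' Read a genotype matrix
#'
#' Two dialects are supported. \code{format = "tsv"}: a header row
#' \code{snp_id<TAB>sample1<TAB>...} followed by one row per SNP with codes
#' 0/1/2/NA. \code{format = "plink"}: a classic PLINK text fileset; pass the
#' \code{.ped} path (the matching \code{.map} must sit beside it). For PLINK
#' input the dosage counts copies of the minor allele, where the minor allele
#' of each SNP is the less frequent allele over all samples, ties broken by
#' taking the lexicographically smaller allele; \code{"0 0"} genotypes become
#' \code{NA}.
#'
#' @param path path to the genotype TSV, or to the \code{.ped} file.
#' @param format \code{"tsv"} or \code{"plink"}.
#' @return A \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("tsv", "plink")) {
  format <- match.arg(format)
  if (format == "tsv") read_genotypes_tsv(path) else read_plink(path)$genotypes
}

read_genotypes_tsv <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) < 2L) stop("genotype TSV must have a header and >= 1 SNP row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (header[1L] != "snp_id")
    stop("genotype TSV header must start with 'snp_id'")
  sample_ids <- header[-1L]
  l <- length(sample_ids)
  n <- length(lines) - 1L
  lens <- lengths(fields[-1L])
  if (any(lens != l + 1L)) {
    bad <- which(lens != l + 1L)[1L] + 1L
    stop("malformed genotype row at line ", bad, ": expected ", l + 1L,
         " fields, found ", lens[bad - 1L])
  }
  snp_ids <- vapply(fields[-1L], `[`, character(1L), 1L)
  codes <- unlist(lapply(fields[-1L], `[`, -1L), use.names = FALSE)
  invalid <- !(codes %in% c("0", "1", "2", "NA"))
  dos <- suppressWarnings(as.integer(codes))
  if (any(invalid))
    stop("invalid genotype code(s): ", paste(unique(codes[invalid]), collapse = ", "))
  genotype_matrix(matrix(dos, nrow = n, ncol = l, byrow = TRUE),
                  snp_ids, sample_ids)
}

#' Write a genotype matrix to the TSV dialect
#'
#' @param x a \code{genotype_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("snp_id", x$sample_ids), collapse = "\t"), con)
  body <- apply(x$dosages, 1L, function(r) paste(ifelse(is.na(r), "NA", r),
                                                 collapse = "\t"))
  writeLines(paste(x$snp_ids, body, sep = "\t"), con)
  invisible(path)
}

#' Read a PLINK .ped/.map fileset
#'
#' @param ped_path path to the \code{.ped} file; the \code{.map} file is
#'   located by swapping the extension.
#' @return A list with \code{genotypes} (a \code{\link{genotype_matrix}}),
#'   \code{phenotypes} (a \code{\link{phenotype_labels}} when the phenotype
#'   column codes 1/2, otherwise \code{NULL}) and \code{snp_annotation}.
#' @export
read_plink <- function(ped_path) {
  map_path <- sub("\\.ped$", ".map", ped_path)
  if (map_path == ped_path) map_path <- paste0(ped_path, ".map")
  if (!file.exists(map_path)) stop("matching .map file not found: ", map_path)
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos"))
  ped <- utils::read.table(ped_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  n <- nrow(map)
  if (ncol(ped) != 6L + 2L * n)
    stop(".ped has ", ncol(ped), " columns; expected ", 6L + 2L * n,
         " for ", n, " SNPs")
  sample_ids <- ped[[2L]]
  if (anyDuplicated(sample_ids)) sample_ids <- paste(ped[[1L]], ped[[2L]], sep = "_")
  l <- nrow(ped)
  dos <- matrix(NA_integer_, nrow = n, ncol = l)
  for (i in seq_len(n)) {
    a1 <- ped[[6L + 2L * i - 1L]]
    a2 <- ped[[6L + 2L * i]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) > 2L)
      stop("SNP ", map$snp_id[i], " is not biallelic: alleles ",
           paste(alleles, collapse = "/"))
    if (length(alleles) == 0L) next  # all missing
    if (length(alleles) == 1L) {     # monomorphic: the minor allele is unseen
      dos[i, ] <- 0L
      dos[i, miss] <- NA_integer_
      next
    }
    counts <- table(factor(c(a1[!miss], a2[!miss]), levels = alleles))
    # minor allele: lowest count, ties broken by lexicographic order (sort
    # order of `alleles` makes which.min pick the lexicographically smaller)
    minor <- alleles[which.min(counts)]
    dos[i, ] <- (a1 == minor) + (a2 == minor)
    dos[i, miss] <- NA_integer_
  }
  gm <- genotype_matrix(dos, map$snp_id, sample_ids)
  ph <- NULL
  phe <- suppressWarnings(as.integer(ped[[6L]]))
  if (all(phe %in% c(1L, 2L)) && length(unique(phe)) == 2L)
    ph <- phenotype_labels(sample_ids, phe - 1L)
  ann <- data.frame(snp_id = map$snp_id, chrom = normalize_chrom(map$chrom),
                    pos = as.integer(map$pos), stringsAsFactors = FALSE)
  list(genotypes = gm, phenotypes = ph, snp_annotation = ann)
}

#' Read a phenotype file
#'
#' TSV with header columns \code{sample_id}, \code{status} and optionally
#' \code{cohort}. Status may be coded 0/1 or \code{control}/\code{case}.
#'
#' @param path input TSV path.
#' @return A \code{\link{phenotype_labels}} object.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(df)))
    stop("phenotype file needs columns sample_id and status")
  st <- df$status
  if (is.character(st)) {
    st <- match(tolower(st), c("control", "case")) - 1L
    if (anyNA(st)) stop("status must be 0/1 or control/case")
  }
  cohort <- if ("cohort" %in% names(df)) {
    co <- as.character(df$cohort)
    co[!nzchar(co) | is.na(co)] <- NA_character_
    co
  } else NULL
  phenotype_labels(df$sample_id, st, cohort)
}

#' Write phenotype labels to TSV
#' @param labels a \code{\link{phenotype_labels}} object.
#' @param path output path.
#' @export
write_phenotypes <- function(labels, path) {
  utils::write.table(as.data.frame(labels), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#' Gene identifiers repeated within one set are de-duplicated; the file order
#' of sets is preserved.
#'
#' @param path GMT file path.
#' @return An object of class \code{gene_set_collection}: a list with
#'   \code{sets} (named list of gene-id character vectors) and
#'   \code{descriptions} (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  nm <- vapply(fields, `[`, character(1L), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene set name: ", nm[anyDuplicated(nm)])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  desc <- vapply(fields, `[`, character(1L), 2L)
  names(desc) <- nm
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets, gene counts",
      paste(range(lengths(x$sets)), collapse = "-"), "\n")
  invisible(x)
}

#' Write a gene-set collection in GMT format
#' @param collection a \code{gene_set_collection}.
#' @param path output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(nm, genes) {
    paste(c(nm, collection$descriptions[[nm]], genes), collapse = "\t")
  }, names(collection$sets), collection$sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read SNP position annotation
#'
#' TSV with header columns \code{snp_id}, \code{chrom}, \code{pos} (1-based).
#' Rows with unparseable or sub-1 positions are dropped with a warning giving
#' the count; "chr1" and "1" style labels are normalized to one convention.
#'
#' @param path input TSV.
#' @return data.frame(snp_id, chrom, pos).
#' @export
read_snp_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("snp_id", "chrom", "pos") %in% names(df)))
    stop("SNP annotation needs columns snp_id, chrom, pos")
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- is.na(pos) | pos < 1L
  if (any(bad))
    warning(sum(bad), " SNP annotation row(s) with unparseable coordinates dropped")
  df <- data.frame(snp_id = df$snp_id[!bad],
                   chrom = normalize_chrom(df$chrom[!bad]),
                   pos = pos[!bad], stringsAsFactors = FALSE)
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id in annotation: ", df$snp_id[anyDuplicated(df$snp_id)])
  df
}

#' Read gene coordinate annotation
#'
#' TSV with header columns \code{gene_id}, \code{chrom}, \code{start},
#' \code{end}; coordinates 1-based inclusive. Rows violating
#' \code{start <= end} or with unparseable coordinates are dropped with a
#' warning giving the count.
#'
#' @param path input TSV.
#' @return data.frame(gene_id, chrom, start, end).
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "chrom", "start", "end") %in% names(df)))
    stop("gene annotation needs columns gene_id, chrom, start, end")
  start <- suppressWarnings(as.integer(df$start))
  end <- suppressWarnings(as.integer(df$end))
  bad <- is.na(start) | is.na(end) | start < 1L | start > end
  if (any(bad))
    warning(sum(bad), " gene annotation row(s) rejected (bad coordinates)")
  df <- data.frame(gene_id = df$gene_id[!bad],
                   chrom = normalize_chrom(df$chrom[!bad]),
                   start = start[!bad], end = end[!bad],
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id in annotation: ", df$gene_id[anyDuplicated(df$gene_id)])
  df
}

#' Align a genotype matrix with phenotype labels
#'
#' Samples present in the genotypes but absent from the phenotype file are
#' dropped with a warning (cohort-exclusion workflow); samples in the
#' phenotype file but not genotyped are an error. The returned labels are
#' reordered to the genotype column order.
#'
#' @param genotypes a \code{\link{genotype_matrix}}.
#' @param labels a \code{\link{phenotype_labels}} object.
#' @return list(genotypes, labels) with matching sample order.
#' @export
align_samples <- function(genotypes, labels) {
  keep <- genotypes$sample_ids %in% labels$sample_id
  if (!all(keep)) {
    warning(sum(!keep), " genotyped sample(s) absent from phenotype file; dropped")
    genotypes <- genotype_matrix(genotypes$dosages[, keep, drop = FALSE],
                                 genotypes$snp_ids,
                                 genotypes$sample_ids[keep])
  }
  if (!all(labels$sample_id %in% genotypes$sample_ids))
    stop("phenotype file contains samples with no genotypes")
  idx <- match(genotypes$sample_ids, labels$sample_id)
  labels <- phenotype_labels(labels$sample_id[idx], labels$status[idx],
                             labels$cohort[idx])
  list(genotypes = genotypes, labels = labels)
}

#' Write an enrichment report to TSV
#'
#' Columns: name, m_snps, y, d, z, p_value, FDR, FWER; rows sorted by
#' p-value, ties broken by decreasing z, then by name. The byte output is
#' deterministic for a fixed report.
#'
#' @param report an \code{enrichment_report} (see \code{\link{run_rs_snp}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_enrichment_report <- function(report, path) {
  stopifnot(inherits(report, "enrichment_report"))
  df <- as.data.frame(report)
  fmt <- function(x) sprintf("%.6g", x)
  out <- data.frame(name = df$name, m_snps = df$m_snps, y = df$y, d = df$d,
                    z = fmt(df$z), p_value = fmt(df$p_value),
                    FDR = fmt(df$FDR), FWER = fmt(df$FWER),
                    stringsAsFactors = FALSE)
  con <- file(path, "wb")  # binary mode: fixed "\n" line endings
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(out, sep = "\t")), con)
  invisible(path)
}
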