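# Resolve gene sets to SNP sets by positional mapping: a SNP belongs to a
# gene if it lies within a fixed window of the gene body; a gene set's SNP
# set is the union of the SNPs mapped to its member genes.

#' Map SNPs to genes by position
#'
#' A SNP maps to a gene when both lie on the same chromosome and the SNP
#' position falls in \code{[start - window, end + window]} (inclusive window,
#' 1-based coordinates). A SNP inside the shared region of two overlapping
#' genes maps to both. With \code{closest_gene = TRUE}, SNPs left unmapped by
#' the window rule are additionally assigned to the nearest gene(s) on their
#' chromosome (all genes at the minimal distance, in case of ties).
#'
#' @param snps SNP annotation data frame (snp_id, chrom, pos), as from
#'   \code{\link{read_snp_annotation}}.
#' @param genes gene annotation data frame (gene_id, chrom, start, end), as
#'   from \code{\link{read_gene_annotation}}.
#' @param window_kb mapping window in kilobases on each side of the gene
#'   (default 5).
#' @param closest_gene enable the nearest-gene fallback for unmapped SNPs.
#' @return Data frame (snp_id, gene_id), one row per mapped pair; zero rows
#'   if nothing maps.
#' @export
map_snps_to_genes <- function(snps, genes, window_kb = 5, closest_gene = FALSE) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  w <- as.integer(round(window_kb * 1000))
  snps$chrom <- normalize_chrom(snps$chrom)
  genes$chrom <- normalize_chrom(genes$chrom)
  pairs <- list()
  for (ch in intersect(unique(snps$chrom), unique(genes$chrom))) {
    si <- which(snps$chrom == ch)
    gi <- which(genes$chrom == ch)
    q <- IRanges::IRanges(start = snps$pos[si], width = 1L)
    s <- IRanges::IRanges(start = pmax(genes$start[gi] - w, 1L),
                          end = genes$end[gi] + w)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits) > 0L)
      pairs[[ch]] <- data.frame(
        snp_id = snps$snp_id[si[S4Vectors::queryHits(hits)]],
        gene_id = genes$gene_id[gi[S4Vectors::subjectHits(hits)]],
        stringsAsFactors = FALSE)
  }
  map <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(snp_id = character(), gene_id = character(),
                  stringsAsFactors = FALSE)
  rownames(map) <- NULL
  if (closest_gene) {
    unmapped <- setdiff(snps$snp_id, map$snp_id)
    extra <- list()
    for (sid in unmapped) {
      i <- match(sid, snps$snp_id)
      gi <- which(genes$chrom == snps$chrom[i])
      if (!length(gi)) next
      dist <- pmax(genes$start[gi] - snps$pos[i], snps$pos[i] - genes$end[gi], 0L)
      nearest <- gi[dist == min(dist)]
      extra[[sid]] <- data.frame(snp_id = sid, gene_id = genes$gene_id[nearest],
                                 stringsAsFactors = FALSE)
    }
    if (length(extra)) map <- rbind(map, do.call(rbind, extra))
    rownames(map) <- NULL
  }
  map
}

#' Resolve gene sets to SNP sets
#'
#' Each gene set becomes the union of the SNPs mapped to any of its member
#' genes (duplicates counted once), expressed as 1-based indices into the
#' supplied SNP universe. Sets falling outside the size bounds are excluded
#' with a logged reason; genes absent from the mapping are tallied as
#' unmatched.
#'
#' @param map SNP-to-gene map from \code{\link{map_snps_to_genes}}, built
#'   over the post-QC SNP universe.
#' @param collection a \code{gene_set_collection} from \code{\link{read_gmt}}.
#' @param universe_snp_ids character vector defining the SNP universe and its
#'   order (typically \code{genotypes$snp_ids} after QC).
#' @param min_snps,max_snps inclusive set-size bounds; defaults keep sets
#'   with at least 2 SNPs (a 1-SNP set makes the standardized score
#'   degenerate) and no upper bound.
#' @return An object of class \code{snp_set_list}: a named list of sets, each
#'   with elements name, snp_indices, m, genes_matched, genes_unmatched;
#'   excluded sets are recorded in \code{attr(, "excluded")}.
#' @export
build_snp_sets <- function(map, collection, universe_snp_ids,
                           min_snps = 2L, max_snps = Inf) {
  stopifnot(inherits(collection, "gene_set_collection"))
  in_universe <- map$snp_id %in% universe_snp_ids
  map <- map[in_universe, , drop = FALSE]
  gene2snp <- split(map$snp_id, map$gene_id)
  sets <- list()
  excluded <- data.frame(name = character(), m = integer(),
                         reason = character(), stringsAsFactors = FALSE)
  for (nm in names(collection$sets)) {
    genes <- collection$sets[[nm]]
    matched <- genes[genes %in% names(gene2snp)]
    snp_ids <- unique(unlist(gene2snp[matched], use.names = FALSE))
    idx <- sort(match(snp_ids, universe_snp_ids))
    m <- length(idx)
    if (m < min_snps || m > max_snps) {
      excluded <- rbind(excluded, data.frame(
        name = nm, m = m,
        reason = if (m < min_snps) "too_few_snps" else "too_many_snps",
        stringsAsFactors = FALSE))
      next
    }
    sets[[nm]] <- list(name = nm, snp_indices = idx, m = m,
                       genes_matched = length(matched),
                       genes_unmatched = length(genes) - length(matched))
  }
  if (!length(sets))
    stop("no gene set survived the size filter (min_snps = ", min_snps, ")")
  if (nrow(excluded))
    message(nrow(excluded), " gene set(s) excluded by size bounds")
  structure(sets, class = "snp_set_list", excluded = excluded)
}

#' Build a SNP set list directly from index vectors
#'
#' Bypasses the gene-mapping step: useful for simulations and diagnostics
#' where sets are defined directly over SNP indices.
#'
#' @param indices named list of 1-based integer index vectors into the SNP
#'   universe.
#' @param universe_size size n of the SNP universe.
#' @return A \code{snp_set_list}.
#' @export
snp_sets_from_indices <- function(indices, universe_size) {
  stopifnot(is.list(indices), !is.null(names(indices)),
            all(nzchar(names(indices))), !anyDuplicated(names(indices)))
  sets <- lapply(names(indices), function(nm) {
    idx <- sort(unique(as.integer(indices[[nm]])))
    if (length(idx) < 1L || any(idx < 1L) || any(idx > universe_size))
      stop("invalid indices for set ", nm)
    list(name = nm, snp_indices = idx, m = length(idx),
         genes_matched = NA_integer_, genes_unmatched = NA_integer_)
  })
  names(sets) <- names(indices)
  structure(sets, class = "snp_set_list",
            excluded = data.frame(name = character(), m = integer(),
                                  reason = character(), stringsAsFactors = FALSE))
}

#' @export
print.snp_set_list <- function(x, ...) {
  m <- vapply(x, `[[`, integer(1L), "m")
  cat("snp_set_list:", length(x), "sets, SNP counts",
      paste(range(m), collapse = "-"), "\n")
  invisible(x)
}

#' Summarize resolved SNP sets
#' @param sets a \code{snp_set_list}.
#' @return Data frame (set, m, genes_matched, genes_unmatched).
#' @export
snp_set_summary <- function(sets) {
  data.frame(set = vapply(sets, `[[`, character(1L), "name"),
             m = vapply(sets, `[[`, integer(1L), "m"),
             genes_matched = vapply(sets, `[[`, integer(1L), "genes_matched"),
             genes_unmatched = vapply(sets, `[[`, integer(1L), "genes_unmatched"),
             row.names = NULL, stringsAsFactors = FALSE)
}
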