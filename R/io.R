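#' Read a donor genotype panel from VCF
#'
#' Loads a multi-sample VCF (v4.x, plain or bgzipped) and keeps only the
#' records usable by the estimator: bi-allelic SNPs (single-base REF and
#' ALT) on whitelisted chromosomes with a complete diploid genotype for
#' every requested sample.  Genotypes map `0/0` to RR, `0/1` or `1/0` to
#' RA and `1/1` to AA; phased separators (`|`) are treated like `/`.
#' Records failing any filter are dropped and tallied by reason in the
#' `dropped` attribute (`multiallelic_or_indel`, `non_autosomal`,
#' `missing_gt`, `duplicate_position`).
#'
#' @param path VCF file path.
#' @param samples optional character vector restricting (and ordering) the
#'   donor columns; an absent sample is an error.
#' @param chroms chromosome whitelist applied after stripping a leading
#'   `"chr"`; defaults to the human autosomes `"1".."22"`.
#' @return a [donor_panel]; attribute `dropped` is a named integer tally
#'   of discarded records.
#' @export
read_panel_vcf <- function(path, samples = NULL, chroms = as.character(1:22)) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no genotype (GT) data")
  if (nrow(gt) != nrow(fix)) gt <- matrix(gt, nrow = nrow(fix))
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, colnames(gt))
    if (length(missing_s)) {
      stop("sample(s) not present in VCF: ", paste(missing_s, collapse = ", "))
    }
    gt <- gt[, samples, drop = FALSE]
  }

  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])
  bases <- c("A", "C", "G", "T")

  keep_snp <- ref %in% bases & alt %in% bases
  keep_auto <- norm_chrom(chrom) %in% norm_chrom(chroms)
  code <- gt_codes(gt)
  keep_gt <- !apply(is.na(code), 1L, any)
  keep <- keep_snp & keep_auto & keep_gt
  dup <- duplicated(paste(norm_chrom(chrom), pos)) & keep
  keep <- keep & !dup

  dropped <- c(
    multiallelic_or_indel = sum(!keep_snp),
    non_autosomal = sum(keep_snp & !keep_auto),
    missing_gt = sum(keep_snp & keep_auto & !keep_gt),
    duplicate_position = sum(dup)
  )
  if (!any(keep)) stop("no usable bi-allelic SNP records in ", path)
  if (dropped[["missing_gt"]] > 0L) {
    message(dropped[["missing_gt"]],
            " SNP(s) dropped for missing/partial genotypes")
  }

  panel <- donor_panel(
    matrix(as.raw(code[keep, , drop = FALSE]), sum(keep), ncol(gt)),
    donor_ids = colnames(gt),
    snps = data.frame(chrom = chrom[keep], pos = pos[keep],
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE))
  attr(panel, "dropped") <- dropped
  panel
}

# GT string -> R-allele count (2 = RR, 1 = RA, 0 = AA), NA for anything else
gt_codes <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 2L
  code[gt == "0/1" | gt == "1/0"] <- 1L
  code[gt == "1/1"] <- 0L
  code
}

#' Tally pooled allele counts from samtools mpileup text
#'
#' Reads default `samtools mpileup` output (chrom, 1-based pos, ref base,
#' depth, read bases, base qualities) and counts, at each requested SNP
#' site, reads supporting the reference allele (`.`/`,`) and the
#' alternate allele (its base letter, either case).  Read-start (`^` plus
#' mapping-quality character) and read-end (`$`) marks and indel spans
#' (`+n`/`-n` plus `n` inserted or deleted bases) are stripped first;
#' deletion placeholders (`*`), reference skips (`<`/`>`) and bases
#' matching neither allele are discarded and tallied.  Sites absent from
#' the pileup get zero counts.  No base-quality filter is applied unless
#' `min_base_quality` is set.
#'
#' @param path mpileup text file.
#' @param sites data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   defining the bi-allelic SNPs of interest (e.g. `panel$snps`).
#' @param min_base_quality optional Phred threshold; bases below it are
#'   discarded (qualities are read as ASCII - 33).
#' @return an [allele_counts] over `sites` (in the given order);
#'   attribute `discarded_reads` counts pileup bases not attributable to
#'   either allele.
#' @export
tally_pileup <- function(path, sites, min_base_quality = NULL) {
  sites <- validate_snps(as.data.frame(sites), nrow(as.data.frame(sites)))
  lines <- readLines(path)
  key <- paste(norm_chrom(sites$chrom), sites$pos)
  r <- integer(nrow(sites))
  a <- integer(nrow(sites))
  discarded <- 0L

  for (li in seq_along(lines)) {
    if (!nzchar(lines[li])) next
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) {
      stop("malformed pileup line ", li, ": expected >= 5 tab-separated fields")
    }
    pos <- suppressWarnings(as.integer(f[2]))
    depth <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos) || is.na(depth)) {
      stop("malformed pileup line ", li, ": non-numeric pos or depth")
    }
    i <- match(paste(norm_chrom(f[1]), pos), key)
    if (is.na(i)) next
    if (depth == 0L) next
    parsed <- parse_pileup_bases(f[5], li)
    quals <- if (length(f) >= 6L) utf8ToInt(f[6]) - 33L else NULL
    keep <- rep(TRUE, length(parsed))
    if (!is.null(min_base_quality) && !is.null(quals)) {
      if (length(quals) == length(parsed)) keep <- quals >= min_base_quality
    }
    bases <- parsed[keep]
    discarded <- discarded + sum(!keep)
    is_ref <- bases %in% c(".", ",") & toupper(f[3]) == toupper(sites$ref[i])
    is_alt <- toupper(bases) == toupper(sites$alt[i]) &
      !(bases %in% c(".", ","))
    r[i] <- r[i] + sum(is_ref)
    a[i] <- a[i] + sum(is_alt)
    discarded <- discarded + sum(!is_ref & !is_alt)
  }
  out <- allele_counts(r, a, snps = sites)
  attr(out, "discarded_reads") <- discarded
  out
}

# strip ^X/$ marks and indel spans, return one symbol per aligned read base
parse_pileup_bases <- function(s, line_no) {
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                     # caret + mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      if (j == i + 1L) {
        stop("malformed pileup line ", line_no, ": '", ch,
             "' not followed by an indel length")
      }
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len                    # skip the inserted/deleted bases
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

#' Read and write pooled counts tables
#'
#' The counts TSV dialect has a header row and columns `chrom`, `pos`
#' (1-based), `ref_allele`, `alt_allele`, `ref_count`, `alt_count`.
#' `read_counts_tsv(write_counts_tsv(x))` round-trips losslessly.
#'
#' @param path file path.
#' @return `read_counts_tsv` returns an [allele_counts].
#' @export
read_counts_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_allele", "alt_allele",
            "ref_count", "alt_count")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("counts table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  allele_counts(tab$ref_count, tab$alt_count,
                snps = data.frame(chrom = tab$chrom, pos = tab$pos,
                                  ref = tab$ref_allele, alt = tab$alt_allele,
                                  stringsAsFactors = FALSE))
}

#' @rdname read_counts_tsv
#' @param counts an [allele_counts].
#' @export
write_counts_tsv <- function(counts, path) {
  if (!inherits(counts, "allele_counts")) stop("`counts` must be allele_counts")
  tab <- data.frame(chrom = counts$snps$chrom, pos = counts$snps$pos,
                    ref_allele = counts$snps$ref, alt_allele = counts$snps$alt,
                    ref_count = counts$r_counts, alt_count = counts$a_counts)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a proportion estimate (and optional trace) as TSV
#'
#' The estimate file has columns `donor_id` and `proportion`, written at
#' full double precision.  With `trace_path` and a fit that recorded its
#' trace, a long-format per-iteration table (`iteration`, `donor_id`,
#' `proportion`) is written as well.
#'
#' @param fit a [pool_em()] object or a named proportion vector.
#' @param path output TSV path.
#' @param trace_path optional output path for the iteration trace.
#' @export
write_estimate <- function(fit, path, trace_path = NULL) {
  theta <- if (inherits(fit, "pool_em")) coef(fit) else fit
  ids <- names(theta)
  if (is.null(ids)) ids <- paste0("donor", seq_along(theta))
  tab <- data.frame(donor_id = ids,
                    proportion = sprintf("%.17g", theta))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trace_path)) {
    if (!inherits(fit, "pool_em") || is.null(fit$trace)) {
      stop("`trace_path` given but the fit has no recorded trace")
    }
    tr <- fit$trace
    long <- data.frame(
      iteration = rep(seq_len(nrow(tr)) - 1L, times = ncol(tr)),
      donor_id = rep(colnames(tr), each = nrow(tr)),
      proportion = sprintf("%.17g", as.vector(tr)))
    utils::write.table(long, trace_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
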