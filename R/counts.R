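#' Pooled allele counts at SNP sites
#'
#' Per-SNP read tallies from the pooled sample: the number of sequenced
#' reads carrying the R (reference) and A (alternate) allele at each
#' bi-allelic SNP.  These are the observations the EM algorithm works from.
#'
#' @param ref_count,alt_count non-negative integer vectors of equal length M.
#' @param snps optional data frame with columns `chrom`, `pos`, `ref`,
#'   `alt` (as in [donor_panel()]); defaults to placeholder sites.
#' @return an object of class `allele_counts`: a list with `snps`,
#'   `r_counts`, `a_counts`.
#' @seealso [read_counts_tsv()], [tally_pileup()], [align_counts()]
#' @examples
#' allele_counts(c(3L, 0L), c(1L, 2L))
#' @export
allele_counts <- function(ref_count, alt_count, snps = NULL) {
  r <- as.integer(ref_count)
  a <- as.integer(alt_count)
  if (length(r) != length(a)) stop("ref_count and alt_count lengths differ")
  if (length(r) < 1L) stop("counts need at least one SNP")
  if (anyNA(r) || anyNA(a) || any(r < 0L) || any(a < 0L)) {
    stop("counts must be non-negative integers")
  }
  if (is.null(snps)) {
    snps <- data.frame(chrom = "sim", pos = seq_along(r),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
  } else {
    snps <- validate_snps(snps, length(r))
  }
  structure(list(snps = snps, r_counts = r, a_counts = a),
            class = "allele_counts")
}

#' @export
#' @method print allele_counts
print.allele_counts <- function(x, ...) {
  cat("Pooled allele counts:", length(x$r_counts), "SNPs,",
      sum(x$r_counts) + sum(x$a_counts), "reads",
      sprintf("(mean depth %.3g)\n",
              mean(x$r_counts + x$a_counts)))
  invisible(x)
}

#' Align a counts table to a donor panel
#'
#' Inner join of panel SNPs and observed counts on (chrom, pos), requiring
#' ref/alt allele agreement.  Sites present in only one input, or with
#' swapped/mismatched alleles, are dropped (with a warning and a
#' reason-coded tally in the `dropped` attribute).  Output panel and
#' counts are in identical SNP order.
#'
#' @param panel a [donor_panel]
#' @param counts an [allele_counts]
#' @return list with elements `panel` and `counts`, aligned 1:1; attribute
#'   `dropped` is a named integer vector of drop reasons.
#' @export
align_counts <- function(panel, counts) {
  stopifnot_panel(panel)
  if (!inherits(counts, "allele_counts")) stop("`counts` must be allele_counts")
  pk <- paste(norm_chrom(panel$snps$chrom), panel$snps$pos)
  ck <- paste(norm_chrom(counts$snps$chrom), counts$snps$pos)
  idx <- match(pk, ck)
  shared <- which(!is.na(idx))
  if (!length(shared)) stop("panel and counts share no SNP sites")
  cidx <- idx[shared]
  ok <- panel$snps$ref[shared] == counts$snps$ref[cidx] &
    panel$snps$alt[shared] == counts$snps$alt[cidx]
  dropped <- c(
    panel_only = n_snps(panel) - length(shared),
    counts_only = length(ck) - length(unique(cidx)),
    allele_mismatch = sum(!ok)
  )
  shared <- shared[ok]
  cidx <- cidx[ok]
  if (!length(shared)) stop("no SNP sites left after requiring allele agreement")
  if (dropped[["allele_mismatch"]] > 0L) {
    warning(dropped[["allele_mismatch"]],
            " site(s) dropped for ref/alt disagreement with the panel")
  }
  out <- list(
    panel = donor_panel(panel$genotypes[shared, , drop = FALSE],
                        donor_ids = panel$donor_ids,
                        snps = panel$snps[shared, , drop = FALSE]),
    counts = allele_counts(counts$r_counts[cidx], counts$a_counts[cidx],
                           snps = counts$snps[cidx, , drop = FALSE])
  )
  attr(out, "dropped") <- dropped
  out
}

# "chr1" and "1" refer to the same chromosome in common dialects
norm_chrom <- function(x) sub("^chr", "", as.character(x))

check_aligned <- function(panel, counts) {
  if (length(counts$r_counts) != n_snps(panel)) {
    stop("panel and counts are not aligned: ", n_snps(panel), " panel SNPs vs ",
         length(counts$r_counts), " count rows; use align_counts()")
  }
  invisible(TRUE)
}
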