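#' Donor genotype panel
#'
#' Construct the genotype panel for a closed set of known donors at
#' bi-allelic SNPs.  Each donor's genotype at each SNP is one of three
#' states -- `RR` (homozygous for the R allele), `RA` (heterozygous), or
#' `AA` -- equivalently an R-allele dosage of 1, 0.5 or 0.  Missing
#' genotypes are not permitted: the panel is assumed to be accurately and
#' completely typed (drop incompletely typed SNPs before construction;
#' [read_panel_vcf()] does this for you).
#'
#' Internally genotypes are stored as a raw byte matrix of R-allele counts
#' (AA = 0, RA = 1, RR = 2) so that panels with hundreds of donors and a
#' million SNPs stay small in memory.
#'
#' @param genotypes an M x N matrix (SNPs in rows, donors in columns),
#'   either character with entries `"RR"`, `"RA"`, `"AA"`, numeric R-allele
#'   dosage in \{0, 0.5, 1\}, or integer R-allele count in \{0, 1, 2\}.
#' @param donor_ids character vector of N unique donor labels; defaults to
#'   the matrix column names, or `donor1..donorN`.
#' @param snps optional data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` identifying each SNP row; rows must be unique by
#'   (chrom, pos).  Defaults to placeholder positions `1..M` on chromosome
#'   `"sim"`.
#' @return an object of class `donor_panel`: a list with elements
#'   `genotypes` (raw M x N matrix of R-allele counts), `donor_ids`, and
#'   `snps`.
#' @seealso [read_panel_vcf()], [pool_em()], [simulate_pool()]
#' @examples
#' p <- donor_panel(matrix(c("RR", "AA", "RA", "RA"), nrow = 2),
#'                  donor_ids = c("d1", "d2"))
#' p
#' r_dosage(p)
#' @export
donor_panel <- function(genotypes, donor_ids = NULL, snps = NULL) {
  if (!is.matrix(genotypes)) stop("`genotypes` must be a matrix")
  M <- nrow(genotypes)
  N <- ncol(genotypes)
  if (M < 1L || N < 1L) stop("panel needs at least one SNP and one donor")

  if (is.raw(genotypes)) {
    g <- genotypes
    if (any(as.integer(g) > 2L)) stop("raw genotype codes must be 0, 1 or 2")
  } else if (is.character(genotypes)) {
    code <- match(genotypes, c("AA", "RA", "RR")) - 1L
    if (anyNA(code)) stop("character genotypes must be 'RR', 'RA' or 'AA'")
    g <- matrix(as.raw(code), M, N)
  } else if (is.numeric(genotypes)) {
    x <- as.numeric(genotypes)
    cnt <- if (all(x %in% c(0, 1, 2))) x else 2 * x
    if (!all(cnt %in% c(0, 1, 2))) {
      stop("numeric genotypes must be dosages in {0, 0.5, 1} or counts in {0, 1, 2}")
    }
    g <- matrix(as.raw(cnt), M, N)
  } else {
    stop("unsupported genotype matrix type: ", typeof(genotypes))
  }

  if (is.null(donor_ids)) donor_ids <- colnames(genotypes)
  if (is.null(donor_ids)) donor_ids <- paste0("donor", seq_len(N))
  donor_ids <- as.character(donor_ids)
  if (length(donor_ids) != N) stop("`donor_ids` length must equal ncol(genotypes)")
  if (anyDuplicated(donor_ids)) stop("`donor_ids` must be unique")

  if (is.null(snps)) {
    snps <- data.frame(chrom = "sim", pos = seq_len(M),
                       ref = "A", alt = "G", stringsAsFactors = FALSE)
  } else {
    snps <- validate_snps(snps, M)
  }

  structure(list(genotypes = g, donor_ids = donor_ids, snps = snps),
            class = "donor_panel")
}

validate_snps <- function(snps, M) {
  snps <- as.data.frame(snps)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("`snps` is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(snps) != M) stop("`snps` must have one row per SNP")
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (anyDuplicated(snps[c("chrom", "pos")])) {
    stop("`snps` rows must be unique by (chrom, pos)")
  }
  snps[c("chrom", "pos", "ref", "alt")]
}

#' @export
#' @method print donor_panel
print.donor_panel <- function(x, ...) {
  cat("Donor genotype panel:", n_snps(x), "SNPs x", n_donors(x), "donors\n")
  tab <- tabulate(as.integer(x$genotypes) + 1L, nbins = 3L)
  cat(sprintf("  genotype counts: AA=%d RA=%d RR=%d\n", tab[1], tab[2], tab[3]))
  cat("  donors:", paste(utils::head(x$donor_ids, 5L), collapse = ", "),
      if (n_donors(x) > 5L) "..." else "", "\n")
  invisible(x)
}

#' Panel dimensions and dosage
#'
#' `n_snps()` and `n_donors()` return the panel dimensions M and N.
#' `r_dosage()` returns the M x N numeric matrix of R-allele dosages
#' (RR = 1, RA = 0.5, AA = 0); intended for small panels, since the
#' expansion to double precision is 8x the internal storage.
#'
#' @param panel a [donor_panel]
#' @return integer scalar, or numeric matrix for `r_dosage()`.
#' @export
n_snps <- function(panel) nrow(panel$genotypes)

#' @rdname n_snps
#' @export
n_donors <- function(panel) ncol(panel$genotypes)

#' @rdname n_snps
#' @export
r_dosage <- function(panel) {
  d <- matrix(as.integer(panel$genotypes) / 2, n_snps(panel), n_donors(panel))
  dimnames(d) <- list(NULL, panel$donor_ids)
  d
}

stopifnot_panel <- function(panel) {
  if (!inherits(panel, "donor_panel")) stop("`panel` must be a donor_panel")
  invisible(panel)
}
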