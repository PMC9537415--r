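#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF (v4.2, plain or bgzipped) with `vcfR`, keeps biallelic SNP
#' records only, converts GT to alt-allele dosage (phased `|` and unphased
#' `/` separators both accepted; phase is not retained) and masks individual
#' genotype calls whose read depth is below `min_depth`. Counts of dropped
#' non-biallelic/non-SNP records and depth-masked calls are reported with
#' `message()`.
#'
#' @param path VCF file path.
#' @param min_depth genotype calls with FORMAT/DP below this are set missing
#'   (default 5). If the VCF carries no DP field a single warning is issued
#'   and no depth masking is applied.
#' @param groups optional sample-to-group assignment: a data.frame with
#'   `sample_id` and `group` columns, or the path of such a TSV. Samples not
#'   listed get group `"other"`.
#' @return A `genotype_matrix` (sample order as in the VCF header).
#' @export
read_vcf <- function(path, min_depth = 5, groups = NULL) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  bases <- c("A", "C", "G", "T")
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    fix$REF %in% bases & fix$ALT %in% bases
  n_drop <- sum(!keep)
  if (n_drop) {
    message("read_vcf: dropped ", n_drop, " non-biallelic/non-SNP record(s)")
  }
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt_chr <- vcfR::extract.gt(vcf, element = "GT")
  allele_sum <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) {
      if (length(x) != 2L || any(x == ".")) return(NA_integer_)
      sum(as.integer(x))
    }, integer(1))
  }
  gt_codes <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
                "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  dosage <- matrix(gt_codes[gt_chr], nrow = nrow(gt_chr))
  odd <- which(is.na(dosage) & !is.na(gt_chr) &
                 !gt_chr %in% c(".", "./.", ".|."))
  if (length(odd)) dosage[odd] <- allele_sum(gt_chr[odd])

  depth <- NULL
  has_dp <- any(grepl("\\bDP\\b", vcf@gt[, "FORMAT"]))
  if (has_dp) {
    depth <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    if (min_depth > 0) {
      masked <- !is.na(dosage) & (is.na(depth) | depth < min_depth)
      if (any(masked)) {
        message("read_vcf: masked ", sum(masked),
                " genotype call(s) with DP < ", min_depth)
      }
      dosage[masked] <- NA_integer_
    }
  } else if (min_depth > 0) {
    warning("VCF has no FORMAT/DP field; min_depth filter not applied")
  }

  samples <- colnames(vcf@gt)[-1]
  grp <- rep("other", length(samples))
  if (!is.null(groups)) {
    if (is.character(groups)) {
      groups <- utils::read.table(groups, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
    }
    stopifnot(all(c("sample_id", "group") %in% names(groups)))
    hit <- match(samples, groups$sample_id)
    grp[!is.na(hit)] <- groups$group[hit[!is.na(hit)]]
  }

  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  dup <- duplicated(sites[, c("chrom", "pos")])
  if (any(dup)) {
    message("read_vcf: dropped ", sum(dup), " duplicate-position record(s)")
    sites <- sites[!dup, , drop = FALSE]
    dosage <- dosage[!dup, , drop = FALSE]
    if (!is.null(depth)) depth <- depth[!dup, , drop = FALSE]
  }
  ord <- order(sites$chrom, sites$pos)
  genotype_matrix(
    t(dosage[ord, , drop = FALSE]),
    samples = data.frame(sample_id = samples, group = grp,
                         stringsAsFactors = FALSE),
    sites = sites[ord, , drop = FALSE],
    depth = if (is.null(depth)) NULL else t(depth[ord, , drop = FALSE])
  )
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits an uncompressed VCF with GT (and DP when depth is present); missing
#' dosages become `./.`. The file round-trips through [read_vcf()] with
#' identical dosages, coordinates, sample order and missingness.
#'
#' @param x a `genotype_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to '", path, "'")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=hyblineage",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (!is.null(x$depth))
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t")
  ), con)
  n_sites <- ncol(x$genotypes)
  if (n_sites > 0) {
    gt_str <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow(x$genotypes), n_sites)
    ok <- !is.na(x$genotypes)
    gt[ok] <- gt_str[x$genotypes[ok] + 1L]
    if (!is.null(x$depth)) {
      dp <- ifelse(is.na(x$depth), ".", as.character(x$depth))
      gt <- matrix(paste(gt, dp, sep = ":"), nrow(gt), ncol(gt))
      fmt <- "GT:DP"
    } else {
      fmt <- "GT"
    }
    body <- vapply(seq_len(n_sites), function(j) {
      paste(c(x$sites$chrom[j], x$sites$pos[j], ".", x$sites$ref[j],
              x$sites$alt[j], ".", "PASS", ".", fmt, gt[, j]),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}
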